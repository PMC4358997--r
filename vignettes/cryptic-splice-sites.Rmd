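---
title: "Detecting cryptic 3' splice sites in SF3B1-mutant transcriptomes"
author: "cryptsplice authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cryptic 3' splice sites in SF3B1-mutant transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The biological problem

SF3B1 is a core component of the U2 snRNP, the complex that recognizes the
branch point (BP) — the adenine attacked in the first catalytic step of
splicing, normally located about 21–34 bp upstream of the 3' splice site
(3'SS). Proteins bound around the BP sterically occlude a region of roughly
12–18 bp immediately downstream of it, so AG dinucleotides inside that
window cannot act as 3' splice sites. Recurrent missense mutations in the
HEAT 5–9 repeats of SF3B1, found in chronic lymphocytic leukemia, breast
cancer, uveal melanoma and other tumors, are associated with the use of
*cryptic* 3'SSs: intronic AG dinucleotides, typically 10–30 bp upstream of
the canonical 3'SS and just at the edge of the sterically protected region
(~13–17 bp downstream of the BP), that become acceptors in the mutant
background.

`cryptsplice` implements the computational pipeline for detecting such
sites from splice-junction count data and for characterizing their
sequence context, together with a synthetic-data generator that plants
this architecture with known ground truth so that every stage can be
validated end to end.

## Pipeline model

### Junction ingestion and filters

Junction coverage is read from STAR-style `SJ.out.tab` tables (1-based
inclusive intron coordinates; unique-read counts). Annotated introns are
derived from the gaps between consecutive exons of each GTF transcript. A
junction is retained when it

1. is covered by at least 20 reads summed over the samples of the current
   analysis (the filter is recomputed per analysis scope),
2. has one of the six spliceosomal motifs (GT/AG, CT/AC, GC/AG, CT/GC,
   AT/AC, GT/AT), and
3. is annotated or shares a donor and/or acceptor with an annotated
   junction.

Junctions contained in zero or several gene spans are removed; survivors
carry exactly one gene. A junction with unknown strand but an
orientation-resolving motif has its strand inferred from the motif. All
windows and distances are computed strand-aware in transcription
direction; a single coordinate convention (1-based inclusive intron
`[start, end]`) is used throughout.

### Differential usage test

Let $k_{ij}$ be the read count of junction $j$ in sample $i$ and $n_{ij}$
the summed count of all retained junctions of the same gene. Usage is the
share $k_{ij}/n_{ij}$, which separates a shift in splice-site choice from
a change in gene expression. We model $k_{ij} \sim
\mathrm{BetaBin}(n_{ij}, \pi_{ij}, \rho_j)$ with

$$\mathrm{logit}(\pi_{ij}) = \beta_0 + \sum_c \gamma_c \,\mathrm{cancer}_{ic}
\;(+\; \beta_1\,\mathrm{condition}_i),$$

and test $\beta_1 = 0$ with a 1-df likelihood-ratio test, adjusted with
Benjamini–Hochberg over all junctions tested in the run; significance is
called at $q < 0.1$. Genes retaining a single junction are untested
(usage is undefined there).

The intra-class correlation $\rho_j$ is estimated per junction by a
Kleinman-type method of moments on the usage fractions, residualized
within condition-by-cancer groups so that a genuine condition effect does
not inflate the dispersion. The estimate is shrunk with weight 0.1 toward
the trimmed mean over the gene's junctions and floored at $10^{-8}$. The
shrinkage weight was calibrated on null simulations (equal usage in both
conditions, $\rho = 0.02$, eight samples per condition): with it, the
fraction of raw $p < 0.05$ sits near the nominal 5% — stronger shrinkage
makes low-usage junctions conservative because their effective dispersion
is far below that of the gene's high-usage junctions, while no shrinkage
leaves the plug-in LRT slightly liberal.

Numerical safeguards: fitted probabilities are clamped to
$[1/(N+2),\,1-1/(N+2)]$ with $N = \sum_i n_{ij}$, avoiding boundary
likelihood failures when a junction has zero counts in one condition;
optimization is bounded quasi-Newton (L-BFGS-B, 200 iterations,
convergence tolerance ~$10^{-9}$ on the log-likelihood) with a BFGS
polish when the line search aborts at an already-optimal start;
non-convergent junctions are flagged untested rather than crashing the
run.

This explicit beta-binomial usage test is a fully specified replacement
for fitting the same usage-versus-expression contrast with an external
negative-binomial GLM tool; numerically matching any particular external
implementation is a non-goal.

### Associated canonical 3'SS, distance, frame and locality

Each significant novel acceptor is paired with the annotated junction
sharing its donor whose acceptor is nearest *downstream* (in
transcription direction); only if no annotated acceptor lies downstream
is the nearest upstream one used. Equidistant candidates are broken
toward downstream, then toward the smaller genomic coordinate (the
equidistant tie-break is an implementation choice; the downstream
preference is the defining rule). The signed distance $d$ is negative
when the cryptic site lies upstream of the canonical site; a site is
*proximal* when $-30 \le d \le -10$ and *in-frame* when $|d| \bmod 3 =
0$.

### Branch-point scoring

The published analysis used a trained support-vector BP predictor; its
exact model is not reproducible here, so the package ships a pluggable
position-weight-matrix scanner with the same interface: search the last
50 intron bases, require a minimum BP-to-3'SS distance of 8, and take the
highest-scoring adenine. The PWM spans seven bases with the BP adenine at
window position 6 and encodes the degenerate human yTnAy consensus:
pyrimidine-rich positions (C/T 0.4 each, A/G 0.1), a strongly conserved T
(0.90 — the U of the motif is the second-best-conserved base after the
adenine, and a weaker weight makes planted consensus motifs
indistinguishable from pyrimidine-tract adenines), the near-invariant
adenine (0.97), and uniform unconstrained positions, scored as
log2-odds against a uniform background. Candidate adenines must lie in
the last 50 bases but their 7-base context may extend further into the
intron (a BP 47 bp upstream of a long intron's end is still scorable).
Ties are resolved toward the smaller distance after rounding scores to
$10^{-9}$, so ranking does not depend on floating-point summation order.

Distances are measured to the *first exonic base* after the acceptor, so
a BP that is itself the adenine of the terminal AG has distance 2 — this
pins the convention to the small 2-bp spike seen when the cryptic AG's
adenine is called as the BP. When the top-ranked BP of the canonical
intron is not 13–17 bp upstream of the cryptic site, the second-ranked
call's distance is substituted (and the substitution recorded). When
several cryptic sites share one canonical 3'SS, one is chosen uniformly
at random under the run seed.

Control 3'SSs are annotated junctions with mean per-sample coverage
strictly above 100 whose donor has no surviving novel acceptor. Their
intronic AGs strictly downstream of the top BP, excluding the last 10
intron bases, provide the null AG-distance distribution; equality of the
cryptic and control distributions is tested with a two-sided
Mann–Whitney U test (normal approximation with tie correction; the
published analyses do not state sidedness, and two-sided is the
conservative choice).

The sufficiency screen lists introns whose canonical junction passes the
coverage cutoff and which contain an AG 10–30 bp upstream of the 3'SS
*and* 13–17 bp downstream of the top BP, flagging whether the implied
cryptic junction itself passes coverage and whether it is significant —
the three-tier bookkeeping that shows the sequence requirements are
necessary but not sufficient.

### Sequence composition

Nucleotide frequencies over the last 50 intron bases are computed on
3'SS-aligned, strand-corrected sequences. Adenine enrichment against the
control profile uses a per-position one-sided Fisher exact test
(enrichment is the stated direction of the comparison; a two-sided option
is exposed). No multiple-testing correction is applied across the 50
positions, matching a raw-p presentation with a 0.05 reference line.

### PSI and reporting

Percent spliced in is $\psi = c/(c+a)$, the cryptic junction's reads over
cryptic plus canonical reads, per sample; $\psi$ is missing (not zero)
when $c + a = 0$, because no coverage is not evidence of no usage. The
high-PSI screen keeps sites with median mutant $\psi > 0.5$, median
wild-type $\psi < 0.2$ (strict inequalities, medians over defined values
only), mean mutant coverage of at least 30 junction-spanning reads, and
— by default — an out-of-frame distance. Heatmap matrices use counts per
million of the sample's total junction-spanning reads, $\log_2(x+1)$,
and per-junction z-scores ("library-normalized" is not further specified
in the published description; CPM is the simplest size normalization
consistent with junction-level data and is exposed in the code).
Relative expression is the per-cancer mean divided by the gene's largest
mean, so each gene's maximum is exactly 1. Hierarchical clustering uses
Euclidean distance with complete or single linkage (only the linkage
choices are named in the published methods; Euclidean is fixed here).

## The synthetic-data generator

No generative model is published for these data, so the simulator is an
artifact design validated by parameter recovery. Each gene occupies its
own chromosome (alternating strands), with three exons and two introns;
the last intron is the analysis intron. Its tail follows, 5' to 3':
AG-free guanine filler, the BP heptamer, a polypyrimidine tract (C/T,
45/55), the optional planted cryptic AG, more tract, and the canonical
terminal AG. The filler is purine so no spurious AGs or BP-like adenines
arise upstream, and the tract cannot contain AG at all, so planted
signals are provably unique — which is what makes exact recovery testable.

Planted heptamers are drawn from the scoring PWM *conditioned on the
consensus yTnAy core* (pyrimidines at the y positions, T and A fixed;
free positions drawn from the full PWM columns). The generator's contract
is that the planted position is a consensus BP; unconditioned draws
occasionally produce purine-contaminated motifs that score below the
cryptic AG's own adenine context, which would make "the planted BP" an
ill-defined notion rather than a recoverable truth.

Gene classes: a configurable fraction carries a *differential* cryptic
site (PSI 0.08 in mutants vs 0.003 in wild-types by default); small
fractions (0.05 each) are *latent* (AG used equally at PSI 0.01 in both
conditions) and *silent* (AG present, never used), mirroring the
real-data observation that most introns with a geometrically eligible AG
show no cryptic usage — these populate the lower tiers of the
sufficiency screen and provide honest false-positive candidates.
Remaining genes are controls; 30% of them receive a longer BP spacing
(36–44 bp) plus one decoy AG placed 3–12 bp downstream of the BP and
more than 30 bp upstream of the intron end, supplying a null AG-distance
distribution clearly below the 13–17 bp cryptic window while respecting
the constraint that non-cryptic introns carry no AG in the 10–30 bp
window.

Counts: per intron and sample, total depth is negative-binomial (mean
200 by default, size 8) scaled by log-normal(0, 0.3) library-size
factors; the cryptic junction's count is beta-binomial given the intron
total with the condition's PSI and overdispersion $\rho = 0.02$; the
canonical junction receives the remainder. One SJ-format table per
sample is written with only the junctions that received reads, as an
aligner would report. A single global seed drives gene structure,
sequence, sample sheet and counts through independently derived streams,
so outputs are byte-identical across runs.

What the simulator does *not* emulate: read-level artifacts (alignment
errors, overhang filters, multimapping), the full degeneracy of real BP
motifs and polypyrimidine tracts, intron length variation, NMD-driven
count depletion of out-of-frame isoforms, and correlated gene expression
between cancers. Passing recovery tests therefore demonstrates that the
pipeline's logic is correct under the planted architecture — not that
its operating characteristics on real tumor data match the published
counts, which derive from protected-access data at far larger scale.

## Problem sizes and validation design

The validation suite uses: an end-to-end recovery run with 300 genes
(60 planted differential sites, 8+8 samples, depth 200); a null
calibration run with 2,000 genes whose cryptic junctions are equally
used in both conditions; a PSI-calibration run with 60 deep introns; and
a high-PSI screen run with 30 genes at planted PSI 0.7 vs 0.05. Oracle
checks compare the canonical-3'SS association against exhaustive search
on 1,000 random configurations, the junction filter against a
brute-force reimplementation, BH against a textbook step-up, the Fisher
enrichment p against exact hypergeometric enumeration, and the BP
scanner against an exhaustive scan of random 50-mers. The
`scripts/acceptance.R` script recomputes all headline quantities from
scratch under a caller-supplied seed.

## Known limitations

* The PWM scanner is a stand-in with the same interface as a trained BP
  predictor, not a reimplementation of one; an external predictions
  table can be substituted where available.
* The beta-binomial usage test will not numerically match external
  negative-binomial exon/junction-usage tools, by design.
* With small per-condition sample counts (&lt;4) the moment-based
  dispersion estimate is noisy and the test loses calibration; the
  simulator's default of eight samples per condition reflects the
  regime the test is built for.
* The published headline counts (hundreds of proximal sites, tens of
  thousands of controls) are functions of protected-access tumor data
  and are not reproducible from synthetic data; the pipeline reproduces
  the *properties* of those results, not the numbers.
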