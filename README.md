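# cryptsplice

Detection and sequence characterization of cryptic 3' splice sites (3'SSs)
in SF3B1-mutant transcriptomes, from splice-junction count tables.

Missense mutations in the HEAT 5–9 repeats of the splicing factor SF3B1
cause the spliceosome to accept intronic AG dinucleotides as 3'SSs when
they sit 10–30 bp upstream of the canonical 3'SS, at the edge of the
sterically protected region ~13–17 bp downstream of the branch point (BP).
`cryptsplice` is for computational biologists who want to detect such
sites from RNA-seq splice-junction output and characterize their sequence
context, and for method developers who need a fully synthetic, truth-known
test bed for differential splice-junction usage methods.

## What it computes

For junction *j* of gene *g* in sample *i*, with junction count
*k<sub>ij</sub>* and gene junction total *n<sub>ij</sub>*, differential
usage is tested with a beta-binomial likelihood-ratio test

&nbsp;&nbsp;*k<sub>ij</sub>* ~ BetaBin(*n<sub>ij</sub>*, *π<sub>ij</sub>*, *ρ<sub>j</sub>*),&nbsp;
logit(*π<sub>ij</sub>*) = *β*₀ + Σ<sub>c</sub> *γ*<sub>c</sub> cancer<sub>ic</sub> (+ *β*₁ condition<sub>i</sub>),

with BH adjustment and significance at *q* < 0.1. Novel acceptors are
paired with the nearest downstream annotated acceptor sharing their donor;
the signed distance *d* classifies sites as proximal (−30 ≤ *d* ≤ −10)
and in/out of frame (|*d*| mod 3). Branch points are scored with a
log-odds PWM over the yTnAy consensus (last 50 intron bases, minimum
BP→3'SS distance 8, highest score wins, second-best fallback outside
13–17 bp). Cryptic-site dosage is percent spliced in, PSI = *c*/(*c*+*a*).
A bundled simulator generates genome, GTF annotation, per-sample
SJ-format junction tables and a truth table with planted BP motifs,
polypyrimidine tracts, cryptic AGs and condition-dependent usage.

## Worked example

The `analysis/` directory is a numbered workflow over the package
functions; run it from the repository root:

```sh
Rscript analysis/01_simulate.R            # synthetic study data -> results/data/
Rscript analysis/02_differential_usage.R  # filters + usage test -> results/usage.tsv
Rscript analysis/03_cryptic_sites.R       # association, frame, composition
Rscript analysis/04_branchpoints.R        # BP distances, controls, screen
Rscript analysis/05_psi.R                 # PSI, high-PSI screen, heatmap matrices
```

On the default configuration (300 genes, 60 planted cryptic sites, 8
mutant + 8 wild-type samples over two cancer types, junction depth 200)
this prints:

```
simulated 300 genes on 300 chromosomes; 60 carry a differential cryptic 3'SS
668 junctions pass the filters; 668 tested; 81 significant at q < 0.1
60 significant novel 3'SSs
proximal (10-30 bp upstream): 60  distal: 0
out-of-frame fraction: 0.65
peak adenine enrichment at position -17 relative to the cryptic 3'SS (planted BPs sit 13-17 bp upstream)
60 cryptic sites with BP calls; 60 are 13-17 bp downstream of the top BP
cryptic vs control AG distances: Mann-Whitney p = 1.56e-13
90 introns have a potential cryptic AG ...; 68 potential sites pass coverage; 60 are significantly more used in mutants
60 proximal cryptic sites quantified; median mutant PSI 0.072 - 88 % are included in <10% of transcripts
two-cluster cut of the z-score columns separates mutants from wild-types with 100 % agreement
```

Reading: all 60 planted sites are recovered as significant novel 3'SSs,
every one classified proximal; the adenine-enrichment peak just upstream
of the cryptic sites is the planted BP adenine; the cryptic BP→3'SS
distances concentrate in the 13–17 bp window while control intronic AGs
do not; planted cryptic usage (PSI 0.08) is re-estimated at ≈0.07; and
read coverage of the cryptic sites alone separates mutant from wild-type
samples by hierarchical clustering — the synthetic analogue of the
published heatmap result.

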