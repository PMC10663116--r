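# paleodup

Duplication-centric genome analysis for plants: Ka/Ks estimation on codon
alignments, collinear (syntenic) block detection and syntenic depth ratios,
tandem-duplicate detection, Ks-peak-based whole-genome-duplication (WGD)
detection and molecular-clock dating, diagnostic-residue plus
diel-expression classification of C4- and CAM-specific gene copies, and
promoter motif-cluster enrichment — together with a synthetic-genome
simulator that plants all of these signals with known ground truth.

The package is aimed at comparative genomicists studying paleopolyploidy
and the evolution of CO2-concentrating photosynthesis (C4 and CAM), and at
method developers who need a fully testable desk-scale counterpart of the
standard WGD analysis stack (BLASTP/MCScanX/PAML-NG/FIMO-style workflows).

## The methods in brief

* **Ka/Ks (Nei-Gojobori 1986).** Per-codon synonymous site fractions
  (changes to stop codons excluded from the numerator), pathway-averaged
  difference counts over all orderings of multi-position codon changes
  (stop-passing pathways excluded), and Jukes-Cantor correction
  d = -(3/4) log(1 - 4p/3) applied to ps and pn. Codon alignments come
  from deterministic global protein alignment (BLOSUM62, affine gaps) with
  the nucleotide sequences forced onto the amino-acid alignment.
* **Synteny.** Shared-k-mer prefilter plus global alignment finds homolog
  pairs; an MCScanX-style longest-path chain DP (min_block = 5,
  max_gap = 25) extracts collinear blocks greedily best-first in both
  orientations; per-gene block coverage gives syntenic depth ratios
  (e.g. 4:1 after two retained WGDs); near-adjacent homolog components are
  tandem arrays; genes are classified WGD / TD / dispersed / singleton.
* **WGD dating.** Anchor-pair Ks values are fitted on the log scale with
  Gaussian mixtures (BIC-selected, post-processed into peaks), and each
  peak mode Ks is dated as T = Ks / (2r); with the Caryophyllales rate
  r = 7.54e-9 substitutions/site/year, peaks at Ks = 1.0 and 0.113 date
  to 66.3 and 7.5 Mya.
* **C4/CAM classification.** A gene copy is C4-specific when it carries
  the functional serine at maize-PEPC position 780 and is day-phased under
  control conditions but repressed under stress; CAM-specific when it
  carries S780 and is strongly night-induced under drought.
* **Motif enrichment.** FIMO-style PWM scanning with exact DP p-values
  (both strands, p <= 1e-4), gene-level one-sided Fisher tests of a
  coexpression module against all expressed genes, BH FDR (enriched at
  q < 0.1), log2 enrichment scores, and highlighting of motif clusters
  with more than 3 enriched members.

## Worked example

Simulate a genome that underwent two WGDs (target Ks 1.0 and 0.113,
retentions 0.6 and 0.4; 2 x 500 ancestral genes) and recover the events:

```r
library(paleodup)

cfg <- simulation_config(seed = 1, emit_sequences = FALSE)
sim <- simulate_genome(cfg)

cds  <- setNames(sim$genome$genes$cds, sim$genome$genes$gene_id)
prot <- setNames(translate_cds(cds), names(cds))

pairs  <- find_homolog_pairs(prot)
blocks <- chain_anchors(as_anchors(pairs, sim$genome))
apairs <- unique(do.call(rbind, lapply(blocks, function(b)
  b$anchors[, c("gene_a", "gene_b")])))
kaks   <- kaks_table(apairs, cds)
dist   <- anchor_ks_distribution(blocks, kaks)
fit_ks_peaks(dist$ks, seed = 1)
#> <ks_peak_model: 2 component(s); modes 0.111 (w=0.34), 0.999 (w=0.66)>

date_wgd(0.111, clock_params(7.54e-9))
#> <wgd_event: Ks mode 0.1110 -> 7.36 Mya at r=7.54e-09>
date_wgd(0.999, clock_params(7.54e-9))
#> <wgd_event: Ks mode 0.9990 -> 66.25 Mya at r=7.54e-09>
```

The mixture recovers the two planted Ks modes (0.113 and 1.0) and the
clock converts them to event ages of roughly 7.5 and 66 million years —
the recent lineage-specific WGD and the ancient shared one. Origin
classification (`classify_duplicates()`) labels the surviving duplicates
WGD/TD/singleton, and `syntenic_depth()` of the simulated pre-WGD ancestor
against this genome has modal depth 4 (the 4:1 paleopolyploidy signature).

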