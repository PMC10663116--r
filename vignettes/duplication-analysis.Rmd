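---
title: "Models and methods behind paleodup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind paleodup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

paleodup analyses gene duplications in plant genomes: it estimates
synonymous (Ks) and nonsynonymous (Ka) divergence between gene copies,
chains homologous gene pairs into collinear (syntenic) blocks, detects
tandem arrays, dates whole-genome duplications (WGDs) from Ks peak modes
under a molecular clock, classifies C4- and CAM-recruited gene copies from
diagnostic residues plus diel expression, and tests promoter motif
enrichment of coexpression modules. This vignette documents the models, the
tunable parameters, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## Ka/Ks: the Nei-Gojobori (1986) estimator

For each codon, every position contributes a synonymous-site fraction equal
to the number of the three possible single-nucleotide changes that preserve
the amino acid divided by 3; changes to stop codons are excluded from the
numerator but kept in the denominator, so a codon always contributes
exactly 3 sites split between synonymous (S) and nonsynonymous (N). For a
codon pair differing at k positions, the synonymous/nonsynonymous
difference counts (Sd, Nd) are averaged over all k! single-step pathways;
pathways passing through a stop codon are excluded from the average, and in
the (rare) case that every pathway is blocked the differing positions are
split half synonymous, half nonsynonymous. Both proportions ps = Sd/S and
pn = Nd/N are corrected for multiple hits with the Jukes-Cantor formula
d = -(3/4) log(1 - 4p/3), undefined (flagged saturated) at p >= 0.75.

Pairs are aligned at the protein level (deterministic Needleman-Wunsch with
affine gaps over BLOSUM62, `gap_open = 10`, `gap_extend = 0.5`) and the
nucleotide sequences are then forced onto the amino-acid alignment, one
codon per residue column; columns containing gaps, Ns or stop codons are
excluded and counted. All 61 x 61 pathway-averaged codon-pair counts are
precomputed once per session, so a pair of 10,000 codons costs a table
lookup.

Two details are deliberate choices rather than consequences of the
published counting scheme, which is silent on them: stop-blocked pathways
are excluded from the average (with the half/half fallback), and codons
containing N are dropped rather than imputed. The standard genetic code is
assumed throughout.

## The synthetic genome generator

The simulator builds an ancestral genome of unlinked random coding genes
(default 2 chromosomes x 500 genes of 200 codons), then applies WGD events
oldest first. Each event duplicates every chromosome and deletes each gene
on the duplicated copy independently with probability 1 - retention_rate;
ranks are recomputed so the surviving gene order stays contiguous, which is
what rank-based chaining consumes. Between events, all lineages evolve
independently, so a duplicate pair created at an event with target Ks t
ends up at pairwise divergence ~t regardless of how many later events and
lineage splits intervene. Tandem arrays are inserted at the present as
adjacent, near-identical copies (Ks 0.02 by default). The default two
events sit at Ks 1.0 and 0.113 with retentions 0.6 and 0.4 - the Ks modes
implied by WGD ages of roughly 66.3 and 7.5 My under the Caryophyllales
clock rate r = 7.54e-9 substitutions per synonymous site per year, and
retention levels that leave a clear 4:1 syntenic depth signal against the
retained pre-WGD ancestor snapshot.

### Calibrated substitution process

The generator is designed around the estimator: its contract is that the
NG86 + Jukes-Cantor estimate of a planted divergence is asymptotically
unbiased, and that divergence is additive along lineage trees. Each codon
position with k synonymous alternatives forms a closed (k+1)-state set
(changing within the set preserves the amino acid). The position receives a
Poisson number of jumps, each uniform over the alternatives; multiple hits,
including reversions, arise naturally. The jump intensity for a pair at
divergence d is obtained by inverting the uniform-chain hitting
probability so that the expected fraction of observed synonymous
differences per synonymous site equals the Jukes-Cantor curve
p = (3/4)(1 - exp(-4d/3)) exactly; for four-fold degenerate sites the
intensity reduces to d itself (the process is literally Jukes-Cantor
there). Lineage segments between WGD events receive intensity differences
of this calibrated map, which makes the planted pairwise divergence exact
for every leaf pair no matter where its split sits in the duplication
tree. The same construction with the nonsynonymous (non-stop) alternatives
drives amino-acid divergence; the nonsynonymous process runs first and all
site classes are re-evaluated on the current codon before each pass, so a
planted synonymous change always preserves the amino acid and stop codons
can never be assembled.

Two site-class subtleties remain and are handled by construction:

* Amino-acid change re-classifies synonymous sites. When a codon carries
  both a nonsynonymous and a synonymous difference, pathway averaging
  counts the synonymous change only partially, biasing Ks down at high
  divergence (about -0.09 at Ks = 1 for Ka/Ks = 0.2 in our measurements).
  The simulator therefore defaults to a mild purifying-selection regime,
  `ka_ks_ratio = 0.02`, and `evolve_pair()` defaults to a pure synonymous
  clock (`target_ka = 0`).
* The leucine and arginine six-fold boxes have first-position degeneracy
  that couples site classes across codon positions; independently evolving
  lineages can land on same-amino-acid codon pairs whose NG86 pathways
  pass through other amino acids, again deflating Ks (sequences of AGA
  alone recover ~0.85 for a true 1.0). Ancestral genes therefore draw
  codons from a degeneracy-stable pool - the sense codons minus those two
  families - within which synonymous families are closed at the third
  position. With this pool, split-lineage recovery at Ks = 1 is unbiased
  to well under 0.01. `evolve_pair()` itself accepts any sense codon.

These are generator design choices, not post-hoc corrections: the biased
configurations simply correspond to regimes where the counting method
itself, applied to real data, carries the same deficit.

### What the generator does not emulate

No rate heterogeneity across sites or genes, no codon-usage bias (the
optional transition bias only reweights which alternative base is drawn),
no gene conversion between duplicates, no chromosomal rearrangement beyond
whole-chromosome duplication, and intergenic sequence is uniform random
DNA. Passing tests therefore demonstrate correctness of the estimators and
of the recovery machinery under the stated statistical structure, not
robustness to every property of real genomes.

## Collinear blocks, depth and duplicate origins

Homolog pairs are found by a shared 6-mer prefilter followed by global
alignment of the candidates (at most `top_n = 5` partners per gene with
score >= 50; self-hits removed and unordered pairs counted once in
self-comparison). Chaining follows the MCScanX-style defaults the field
uses: per chromosome pair, a longest-path dynamic programme over anchors
allows an edge when both rank deltas lie in [1, max_gap = 25] with strict
monotonicity (same or inverted orientation), maximising anchor score minus
`gap_penalty = 1` per skipped rank. Chains are extracted greedily
best-score-first - both orientations compete for the same anchors, and
used anchors are removed - and chains shorter than `min_block = 5` are
discarded. This greedy extraction reproduces the behaviour of the standard
collinearity tools rather than a globally optimal disjoint chain cover;
the exhaustive-enumeration oracle in the test suite therefore checks
single-best-chain optimality only.

Syntenic depth counts, for every reference gene, the blocks whose anchor
span on its chromosome covers the gene's rank; the modal nonzero depth
summarises the comparison (4:1 after two retained WGDs). Tandem arrays are
connected components of same-chromosome homolog pairs separated by at most
`max_intervening = 1` genes. Origin classification applies TD-first
precedence: tandem membership wins over WGD anchorhood, then a gene is WGD
when it anchors at least one self-synteny block and its family retains at
least `min_copies` syntenic copies. The default `min_copies = 3` encodes
the "at least 3 copies after 2 WGD rounds" reading; the
simulation-recovery tests use 2, since a single surviving duplicate pair
is exactly 2 syntenic copies and the published criterion is ambiguous
about whether the focal gene counts. Both readings are one argument away.

## Ks peaks and WGD dating

Anchor-pair Ks values (0 < Ks <= `ks_cap = 3`, saturated pairs dropped)
are fitted on the log scale with Gaussian mixtures of 1..4 components
(unequal variances) and the component count chosen by BIC; log-Ks is used
because Ks distributions are right-skewed. The fit uses mclust's
deterministic hierarchical initialisation, which we prefer to random
restarts for reproducibility; a standard-deviation floor of 1e-3 guards
degenerate inputs, and fewer than 50 values is an error rather than a
silent fit. Because one skewed empirical peak often demands two Gaussians,
the BIC-selected mixture is then condensed into peaks: components holding
less than 5% of the weight are set aside as noise, and components whose
log-means sit within 0.5 of each other (closer than a ~1.6-fold Ks ratio,
below what Ks peak analysis resolves in practice) are merged at their
weight-averaged log-mean; the untouched mixture stays available in the
returned object. Component means are reported back-transformed (exp of the
log-scale mean, i.e. the component median on the Ks scale). Noise in
per-pair Ks estimates enters the log-scale mean convexly, shifting
recovered modes down by about CV^2/2 - roughly 1% for 200-codon genes at
Ks = 1 - which is well inside the +/-0.05 recovery band the tests assert.

Dating is the closed form T = Ks / (2 r): with the Caryophyllales rate
r = 7.54e-9/site/year, a peak at Ks = 1.0 dates to 66.3 My and one at
0.113 to 7.5 My. `estimate_rate()` inverts the same formula from an
ortholog Ks peak with a known divergence date (the published calibration:
an ortholog peak of 0.28 against a split at ~18.6 My yields this r), and
round-trips with `date_wgd()` exactly.

## C4/CAM classification

The residue call uses reference-anchored numbering (maize PEPC,
Zm00001d046170): serine at position 780 marks a
photosynthesis-functional PEPC, alanine the non-photosynthetic form, and
anything else (including alignment gaps) is ambiguous. Positions 890
(arginine = tight inhibitor binding; methionine/glycine = low affinity)
and 519 (the D509 malate-sensitivity position in Kalanchoe numbering,
taken as given) are recorded as evidence but do not drive the call, since
the S/A rule itself is known not to be absolute.

Diel phasing is rule-based on group means with a 0.1 pseudocount in
denominators. C4-like: control day >= 4x control night, day expression at
least 1 TPM, and day expression under some stress condition at most a
quarter of the control day level. CAM-like: night expression under some
stress condition >= 10x control night, >= 4x that stress condition's day
level, and at least 1 TPM. When both fire, CAM wins - stress-night
induction is the discriminating CAM signature. The fold thresholds
(4, 4, 10) are this package's operationalisation of patterns that the
literature reports qualitatively ("highly expressed during the day",
induction "hundreds to thousands of times"); they are deliberately far
below the simulated effect sizes (the generator's CAM induction is 150x)
and exposed as arguments. The final class is a conjunction: C4-specific =
functional residue AND C4-like phasing; CAM-specific = functional AND
CAM-like. Expression filtering keeps genes with TPM > 1 in at least 2
replicates of at least one condition/time group.

## Promoter motif enrichment

Promoters are the 2,000 bp upstream of the annotated gene start (TSS =
gene start; no UTR model), truncated at chromosome ends and never masked
for overlap with upstream genes - the masking question is left open
deliberately, matching common practice. PWMs are normalised with a total
pseudocount of 0.1 distributed by background composition and scored as
log-odds in bits against a 0-order background estimated from the scanned
promoters (or supplied). The p-value of a window score is exact under
that background: a dynamic programme convolves the per-position score
distributions discretised at 1e-3 bits, and a window's p-value is the tail
of that distribution at its own discretised score - the FIMO approach.
Both strands are scanned (threshold p <= 1e-4 per window), windows
containing N are skipped, overlapping hits are allowed.

Enrichment counts genes, not hits: a promoter with three occurrences
counts once. The module set is the module's genes with membership > 0.8
among expressed genes; the background is all expressed genes including the
module (module vs genome, not module vs complement). The test is the
one-sided (enrichment) Fisher exact upper tail, computed as the closed
hypergeometric form, with a Haldane 0.5 correction on the sample odds
ratio when a cell is zero; q-values are Benjamini-Hochberg, a motif is
enriched at q < 0.1, the enrichment score is
log2((module frequency)/(background frequency)), and a motif cluster is
highlighted when more than 3 of its members are enriched. Hit-level
totals are reported alongside for inspection, since "frequency of
occurrence" is ambiguous between the two conventions.

## Pipeline and problem sizes

`run_all()` executes simulate -> homolog search -> chaining -> Ka/Ks ->
Ks peaks -> clock dating -> tandem/origin classification -> CCM
classification -> motif enrichment, writes one TSV per stage plus a JSON
summary, and is a pure function of its config (fixed seed = byte-identical
outputs; any stage is re-runnable from the saved intermediates). Stage
errors abort with the stage name. The packaged defaults run a 2 x 500-gene
ancestor (two WGDs, ~2,200 genes after retention) in under a minute on one
core; the test suite uses smaller genomes (120-500 ancestral genes,
120-200 codons) and a motif study of 300-5,000 promoters, sizes at which
every recovery property asserted is comfortably identifiable yet the whole
suite stays quick. The acceptance script reports the same quantities at
the default study scale.

## Known limitations

NG86 is the counting method the analysis is defined on; it is not a
maximum-likelihood codon model, and no transition/transversion or
codon-frequency correction is applied to the distances. Greedy chain
extraction can split one true block in pathological anchor layouts.
Mixture-based peak counting can merge WGD peaks closer than roughly a
factor of two in Ks at realistic noise. The diel phasing rules are
thresholded means, not a statistical test with replicates (differential
expression machinery is intentionally out of scope), and the residue call
keys on a single position. Promoter extraction assumes the annotated gene
start is the TSS.
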