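---
title: "Methods: scoring, backgrounds, and fine-mapping in vpchic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, backgrounds, and fine-mapping in vpchic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vpchic)
```

# The analysis problem

Genome-wide association studies of breast cancer have resolved risk
regions into independent signals, each carrying a set of credible causal
variants (CCVs) that are statistically indistinguishable from the lead
variant. Most CCVs fall in distal regulatory DNA, so connecting them to
the genes they regulate requires chromatin-contact evidence. A dual
Capture Hi-C design addresses this from both directions: a Variant
Capture (VC) arm baits every HindIII restriction fragment containing a
CCV, and a Promoter Capture (PC) arm baits fragments containing annotated
promoters within 1 Mb of CCVs. `vpchic` implements the post-capture
analysis of such an experiment: interaction thresholding, enrichment of
interacting regions for chromatin features, an eQTL-loop co-occurrence
test, sequential fine-mapping of CCVs, and rule-based candidate target
gene calling — together with a seeded synthetic-data generator that
provides ground truth for every stage.

The resolution unit throughout is the restriction fragment. Every bait,
prey, CCV and promoter resolves to a fragment of an in silico HindIII
digest (`A^AGCTT`, so `digest_sequence()` cuts one base after the match
start). All coordinates are 0-based half-open, BED-native; the readers
for 1-based inputs document the conversion. Ambiguous bases (`N`) never
match the recognition site, which leaves masked regions uncut — the
conservative choice for a digest model.

# Two scoring schemes and their combination

Each bait–prey pair in each cell line carries two scores:

* a **CHiCAGO-style score**, a frequentist confidence score whose
  high-confidence threshold is **score ≥ 5**, applied together with an
  intrachromosomal requirement and an interaction distance of at most
  2 Mb (`filter_chicago()`; thresholds inclusive);
* an **MPPC** (marginal posterior probability of contact), a Bayesian
  fine-mapping quantity thresholded at **MPPC ≥ 0.1**
  (`filter_peaky()`; pairs with no MPPC are dropped).

CHiCAGO-style calls tend to come in long *stretches* of contiguous
significant fragments around a true contact (collateral signal from
cross-linking and bait mobility). The MPPC concentrates on the direct
contacts inside those stretches. The package therefore combines them
sequentially in `prioritize_ccvs()`: a signal first needs a
CHiCAGO-passing promoter–CCV interaction (the *detectability gate*),
and a CCV is then prioritized only if its fragment reaches the MPPC
threshold from such a gated promoter bait in the same cell line. The
pure-union alternative was considered and rejected because it cannot
shrink a stretch: refinement is the point of the second scorer.

Interaction distance is the absolute difference of fragment midpoints
(`floor((start + end) / 2)`). The anchors are not specified by any
convention we could adopt from the assay itself; midpoints are symmetric
and robust to fragment-size variation. One deliberate asymmetry follows
the two analysis descriptions that motivated it: interaction *sets* use
distance ≤ 2 Mb, while the clustering and PCA inputs use < 2 Mb.

Cross-capture concordance (`capture_concordance()`) matches interactions
by **unordered fragment pair** and cell line, because the two arms bait
different fragment sets, so the same physical contact appears with its
roles reversed. Pearson correlation is reported for raw and
asinh-transformed scores; asinh is monotone, so rank structure is
unchanged and the transform only tames the score tail.

Cell-line structure is summarised two ways, matching standard practice:
unit-variance PCA over interactions with positive scores
(`pca_cell_lines()`), and average-linkage hierarchical clustering on
Euclidean distances over the 1000 most variable interactions
(`cluster_cell_lines()`, deterministic lexicographic tie-breaks). On
synthetic data the top-level split recovers the latent ER-status
grouping of the cell lines.

# Distance-matched permutation background

Feature enrichment of interacting regions cannot be assessed against the
whole genome: interacting fragments sit at characteristic distances from
baits, and chromatin features are themselves distance-structured.
`build_background_sets()` therefore builds, for each observed region set,
`n_sets = 100` surrogate sets that preserve **per bait** both the region
count and the multiset of 50-kb distance bins (`floor(d / 50000)`).
Surrogates are drawn uniformly from same-chromosome fragments in the
matched bin, excluding every baited fragment; sampling is without
replacement within a set and independent across sets. A bin with too few
candidates falls back to the nearest non-empty bins (logged). Per-bait
matching is the strictest reading of count preservation "relative to
baits"; a pooled alternative would preserve the marginal distance
distribution only.

`enrichment_z()` reports `z = (observed − null_mean) / null_sd`, where
the counting unit is the unique bait–prey region whose prey fragment
overlaps ≥ 1 peak (binary, fragment-level overlap — the fragment is the
assay's resolution unit, so base-pair coverage would suggest precision
the data do not have). Counting regions rather than distinct fragments
keeps every background set exactly size-matched to the observed set, so
a feature covering the whole genome gives observed = null in every set
and `z = 0` under the sd-zero convention (saturated features are
uninformative, and ±∞ would poison downstream summaries). Calibration is
tested, not assumed: with no planted enrichment, z over 200 independent
simulations has |mean| ≤ 0.2 and variance within [0.7, 1.4].

The conditional co-factor question ("are regions bound by factor A
enriched for factor B?") is a 2×2 table of region fragments by
`hasA`/`hasB`, tested with two-sided Fisher's exact
(`conditional_cofactor_test()`); the odds ratio uses a Haldane 0.5
correction when a cell is empty, and degenerate margins return missing
statistics rather than a fabricated p. Fisher's exact is a package
decision — the underlying study prints only a p-value floor for this
comparison, not a test name.

# eQTL–loop co-occurrence

`eqtl_supported_interactions()` flags an interaction when one end
fragment contains an eSNP (FDR < 0.05, strict) and the other end is a
promoter fragment of the matching eGene, in either orientation. The null
for "do eQTLs loop to their own genes more than chance?" must preserve
everything about the interaction network except the promoter identities.
`permute_promoter_assignment()` therefore relabels every baited promoter
fragment by a promoter fragment drawn uniformly from the same
chromosome's promoter pool — without replacement, so distinct baits keep
distinct identities when the pool allows — and retallies the supported
count per distance bin. 10,000 permutations is the default;
calibration and power tests use fewer (299–499) because the add-one
empirical p, `p = (1 + #\{null ≥ obs\}) / (1 + n_perm)`, only needs
resolution near the tested α. The default binning is a single global
bin; distance-binned output takes custom `breaks` since no canonical
edges exist for this display. The counting unit is one interaction per
bait–prey pair per cell line.

# Candidate target genes and summaries

`ccv_promoter_interactions()` emits one evidence row per filtered
interaction joining a CCV fragment of a known signal and a promoter
fragment of a known gene, in either orientation, labelled by capture arm
and scoring scheme. `define_candidate_genes()` keeps (signal, gene)
pairs supported in **at least 2 distinct cell lines**, pooling evidence
across arms and schemes — a cell line counts once however it is
supported, the literal "and/or … or" reading; a `both_methods` flag
marks genes with both CHiCAGO and Peaky support for stricter downstream
use. Skipped promoters are counted as distinct *genes* with a promoter
fragment strictly between the interaction's end fragments (fragment-id
order), excluding the pair's own gene. `summarize_targets()` reports the
headline tallies (signals with 1–2 coding candidates, multi-signal
genes, the promoter-skipping fraction, both-scheme genes). Signals with
zero coding candidates are excluded from the "≤ 2 coding genes" tally:
the tally describes signals *prioritized to* one or two genes.

Motif consequences of a prioritized CCV are scored with
`pwm_allele_delta()`: a position weight matrix (rows sum to 1 within
1e-6; count matrices normalised with a 0.01 pseudocount), log2-odds
scores against a uniform background, zero probabilities floored at 1e-4
with a warning, and a direction label (increase / decrease / neutral at
a 1e-9 tolerance on the risk-minus-protective delta).

# Bait design rules

`qc_bait()` applies the capture-array acceptance rules to candidate
120-mers: GC content within [25%, 65%] (inclusive — boundary behaviour
is argument-exposed), longest homopolymer run ≤ 2, and the nearer bait
boundary within 330 bp of the nearer fragment end (the most permissive
consistent reading of the end rule). The homopolymer rule is read
literally, so `"AAA"` rejects; that is unusually strict for real DNA —
random sequence almost always contains a 3-run — and a vendor tool may
well have enforced something looser, so the threshold is an argument
(`max_homopolymer`). Masked bases (lowercase or `N`) fail QC as
ambiguous. `design_baits()` slides candidates in 1-bp steps from each
fragment end inward and keeps the accepted candidate closest to the end,
matching the end-proximal intent of capture chemistry; fragments with no
acceptable candidate are reported with the reason codes of their
end-most rejection.

# The synthetic-data generator

`simulate_dataset()` emits score-level data only. Simulating reads would
add nothing the pipeline can see: it consumes scores, so the generator
plants structure directly in score space.

* **Fragments**: Poisson-process HindIII sites at `site_density`
  0.25/kb (≈ 4 kb fragments, the enzyme's genome-wide scale), two 3-Mb
  chromosomes by default.
* **Signals**: 6 regions × 2 signals (12 signals), deterministically
  spaced ≥ 200 kb apart within a region so their collateral stretches
  stay distinct; each signal has 8 CCVs — one causal variant in the
  anchor fragment and distractors spread over the neighbouring
  fragments, which places them inside the CHiCAGO stretch but outside
  the MPPC-boosted fragment, enabling the stretch-refinement tests.
* **Scores**: baseline mean `3 · exp(−d / 300 kb)` plus N(0, 1) noise,
  truncated at zero. A direct contact adds a boost of 8 and draws MPPC
  from U(0.2, 0.95) with probability 0.95 (else U(0.02, 0.08));
  fragments within ±5 of the prey receive a linearly tapering
  CHiCAGO-only boost — the collateral stretch. Background MPPC is
  Beta(1, 100) (near zero), rank-coupled to the score noise through a
  Gaussian copula with ρ = 0.4 because both real scorers read the same
  counts; the realised Spearman ρ ≈ 0.29 sits inside the positively
  correlated range reported for the two scorers.
* **Cell-type specificity**: six cell lines in two latent groups
  (ER-positive: MCF7, T47D; the rest); half the contacts are shared,
  half specific to one group, which drives both PCA separation and
  dendrogram recovery.
* **TADs**: non-overlapping 0.4–0.9-Mb blocks; 70% of direct contacts
  are constrained within the bait's TAD (`tad_fraction = 0.7`, used as a
  generator default mirroring the ~70% within-TAD share of observed
  contacts, not as a claim about real data).
* **Peaks**: per-fragment Bernoulli at `peak_background_rate = 0.1`
  genome-wide and `rate × 5` on direct-contact prey fragments for the
  enriched features (ATAC, H3K27ac); H3K27me3 stays at background as a
  negative control.
* **eQTLs**: a fraction 0.5 of true CCV–promoter loops receives a
  supporting record (eSNP at the causal CCV, eGene = looped gene,
  FDR < 0.05); spurious records appear at 0.01 expected records per
  fragment (Poisson) with a random same-chromosome eGene.

Everything is seeded (`withr::with_seed`); a fixed seed gives
byte-identical emitted files, and `write_dataset()` records MD5
checksums in a manifest. Ground truth (true contacts, causal CCVs, true
target pairs, enriched features) is written alongside but never read by
the pipeline.

**What the generator does not emulate**: read counts and their
overdispersion, GC and mappability bias, trans-chromosomal contacts,
replicate structure and replicate-weight merging, bait efficiency
differences, and realistic gene density. Passing tests therefore show
that the pipeline's logic and statistics behave correctly under the
assumed score model — not that the thresholds would have the same
operating characteristics on a real library.

# Problem sizes and test design

Test problem sizes are package choices balancing statistical resolution
against a comfortable desk-scale run:

* null calibration uses 200 independent single-chromosome simulations
  for the enrichment z (two cell lines, no planted enrichment) and 200
  for the eQTL p (no eQTL–loop structure, dense spurious records so the
  supported count has enough spread for a meaningful KS comparison —
  permutation p-values are discrete, and a count with small support
  fails uniformity for discreteness alone);
* power and recovery use the default simulation size: 100 replicates
  for planted feature enrichment (z > 2 in ≥ 95%), 50 for planted eQTL
  looping (p < 0.01 in ≥ 90%), and 20 seeds for candidate-gene
  precision/recall (≥ 0.8) and causal-CCV recall (≥ 0.9). Enrichment
  power is measured on the Peaky-refined region set: the generator
  plants features at direct contacts, and the collateral stretch
  fragments in the CHiCAGO set dilute a fragment-level overlap count —
  which is precisely the dilution the sequential design exists to
  remove;
* oracle-equivalence tests compare every counting operation (fragment
  location, peak overlap, evidence joins, skipped promoters) against
  independent brute-force implementations on randomized fixtures.

# Degenerate inputs and numerical conventions

Empty region sets give missing fractions, not zeros; fewer than three
matched pairs give a missing correlation; constant vectors give missing
ρ; a zero null SD gives z = 0 with a warning; empty eQTL inputs give
p = 1 through the add-one rule; a signal failing the CHiCAGO gate yields
an empty prioritized set with a logged reason. BED records with
`start ≥ end` are rejected with a warning and a count; malformed lines
error with their line number; overlapping TADs and duplicate interaction
keys are load-time errors. All thresholds printed with a "≥"/"≤" are
implemented inclusively.

# Known limitations

The permutation machinery assumes one promoter pool per chromosome and a
fixed network; it does not model bait dropout. The enrichment background
matches distance and count but not chromatin state, GC, or fragment
length. Candidate-gene precision on synthetic data benefits from the
generator's deliberate separation of signals and promoters; real loci
with interleaved signals will show chance evidence chains that only
orthogonal data can break. None of the outputs imply causality: an
interaction between a CCV and a promoter nominates a gene, it does not
demonstrate regulation.
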