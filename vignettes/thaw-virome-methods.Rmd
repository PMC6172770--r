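---
title: "Methods: viral population ecology along a permafrost thaw gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: viral population ecology along a permafrost thaw gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thawvir)
```

`thawvir` implements the inference chain of particle-enriched soil
viromics: assembled contigs are dereplicated into species-level viral
populations (vOTUs), quantified and detected by read recruitment,
grouped into approximately genus-level viral clusters (VCs) through a
hypergeometric gene-sharing network, linked to microbial hosts by
CRISPR spacers and nucleotide similarity, and summarized with
community-ecology statistics. This vignette describes the models, the
parameters that matter, the synthetic data the package validates
itself against, and the numerical choices made where the design was
genuinely open.

## Viral populations (vOTUs)

Two contigs belong to the same population when they align at ≥95%
average nucleotide identity (ANI) over ≥80% of the contig length —
the now-standard species-level boundary for dsDNA phage genomes.

**ANI engine.** `compute_ani()` anchors shared k-mers (default
k = 13), lets them vote for an alignment diagonal, and on the winning
diagonal takes the maximum-scoring local segment under match +1 /
mismatch −2 (a prefix-scan ungapped Smith–Waterman). ANI is identities
over that segment; N never counts as a match. Because the package's
synthetic sequences diverge by substitutions only (see below), a
single diagonal carries the whole homologous stretch, and the engine
agrees with a full dynamic-programming alignment oracle to within 0.01
on the scales the test suite exercises. Real indel-rich data should be
pre-aligned with a production aligner and imported via `read_sam()`.

**Coverage denominator.** The 80% aligned-length threshold is taken
over the *shorter* contig of the pair (`cov_denominator = "shorter"`,
configurable). This is the permissive convention of standard
dereplication practice: a fragment wholly contained in a longer genome
at ≥95% identity is a fragment of that population, not a new one.

**Clustering scheme.** `cluster_contigs()` is one-pass greedy,
longest-first: contigs sorted by length (ties lexicographic by id)
seed clusters, and each contig joins the first representative it
matches. Greedy longest-first was chosen over average-linkage because
it is deterministic, has an obvious representative (the longest
member), and is what the field's dereplication tools do; the choice is
documented rather than hidden since either scheme defends the same
thresholds. Re-clustering the representatives returns singletons
(idempotence), which the suite asserts.

## Detection and abundance

A read counts toward a contig when its identity — matches over aligned
columns, the convention of aligner identity fields (a full-read
denominator is available) — is ≥90%; multi-mapped reads count once at
their best hit (most matched bases, first record on ties), a
conservative choice where fractional assignment was the alternative.
A vOTU is *detected* in a virome when reads cover ≥75% of its length;
breadth is the union of covered intervals, never double-counted.
Abundance is

\[ A = \frac{\text{mapped bp} / L_{\text{contig}}}{\text{library bp}}
  \times 10^9, \]

i.e. per Gbp of library. The 10⁹ constant keeps values O(1–100) at
realistic library sizes; only ratios of abundances are interpreted, so
the constant is cosmetic. Undetected cells are reported as 0.
Total-sum scaling (`total_sum_scale()`) divides each virome row by its
sum; all-zero rows pass through with a warning. Diversity statistics
are computed on detection-masked, total-sum-scaled values — raw versus
scaled input was an open choice, resolved in favour of the masked,
scaled version because detection is the package's unit of evidence and
Shannon/Pielou are scale-invariant anyway (asserted in the suite).

The built-in mapper (`map_reads()`) is a minimal k-mer-seeded,
ungapped, uniform-read-length mapper for the synthetic path only; it
discards candidate placements below 50% identity so host reads grazing
a planted protospacer never produce alignments.

## Gene-sharing network and viral clusters

Protein clusters (PCs) come from Markov clustering of the all-vs-all
protein similarity graph after discarding edges under 50 bits or above
E = 1e-4; PCs represented in fewer than two genomes are demoted to
singleton proteins, since a family seen in one genome says nothing
about sharing. For genomes carrying \(a\) and \(b\) PCs that share
\(c\) of a universe of \(n\), the tail probability

\[ P = \sum_{i=c}^{\min(a,b)} \frac{\binom{a}{i}\binom{n-a}{b-i}}
     {\binom{n}{b}} \]

is computed in log space (`phyper(..., log.p = TRUE)`), so tails that
underflow a double never become literal zeros. The similarity score is
read as \(S = -\log_{10}(P \cdot T)\) with \(T = N(N-1)\) ordered
genome comparisons — a Bonferroni-style correction under which the
field's \(S \ge 1\) edge threshold means "P below 0.1 after
multiple-comparison correction". The grammatically possible
alternative reading \((-\log_{10} P)\cdot T\) would make that
threshold vacuous, but it is exposed behind
`formula = "logp_times_t"` for comparability. \(N\) defaults to the
number of genomes with a non-empty PC profile, so adding a genome
without proteins perturbs no existing score.

**MCL.** `mcl()` is a dense, deterministic implementation: add
self-loops, column-normalize, then alternate expansion (matrix
squaring) and inflation (elementwise power, renormalize), pruning
entries below 1e-5, until the maximum elementwise change falls under
1e-8 (cap 100 iterations); clusters are the connected components of
the converged attractor structure. Self-loops use the reference
implementation's convention — per node, the maximum incident edge
weight (at least 1) — rather than a fixed weight 1: with strong edge
weights a two-node system under unit loops alternates between a
near-permutation matrix and its square, and inflation then collapses
the pair into two singletons, misclassifying every weighted doubleton.
The suite pits this implementation against an independently coded
dense reference on random two-block graphs.

**Inflation scan.** `assign_viral_clusters()` builds the \(S \ge 1\)
network, runs MCL at all 21 inflations 1.0–5.0 (step 0.2), and
reports every partition. The selected optimum maximizes weighted
modularity of the partition on the thresholded network (smallest
inflation on ties) — the selection criterion was not fixed by the
method the package follows, and modularity is the standard
partition-quality functional that needs no ground truth. Users can
pin any inflation (e.g. 1.6) via `pin_inflation`. Genomes in MCL
clusters of ≥3 members get VC ids; two-member components are
doubletons; isolated or unclustered genomes are singletons.

## Host prediction

`find_crispr_arrays()` seeds on exactly repeated k-mers (k = minimum
repeat length, default 23), keeps position runs whose periods lie in
the repeat+spacer window, extends to the maximal common repeat, and
rejects runs whose implied spacers leave the 26–50 bp range — so
tandem repeats with 10-bp gaps are not arrays. Exact repeat copies are
required: the genome-level stand-in favours precision over the
read-level tools it replaces, and a mismatch allowance is left to
configuration. Spacer matching (`match_spacers()`) is exhaustive on
both strands with 0 mismatches by default — whether looser candidate
matching was ever useful is unresolved in the literature the package
follows, and the confident-link convention is 0 — with a `max_mismatch`
flag and a low-specificity warning under 20 bp.

`similarity_link()` requires all four thresholds — ≥50 bits,
E ≤ 1e-3, ≥70% ANI, ≥2,500 aligned bp — on the best ungapped local
segment (diagonal-anchored, Kadane max-subsegment, both strands). Bit
scores and E-values use ungapped Karlin–Altschul statistics for the
match +1 / mismatch −2 dialect (λ = 1.28, K = 0.46), with
`E = m·n·2^{-bits}`; both are reported in the link table so the
thresholds are auditable against any external aligner.

## Community ecology

Shannon diversity uses the natural log (H′ in nats; base
configurable), Pielou J = H′/ln S with J defined 0 for S ≤ 1.
Bray–Curtis is computed from its definition and cross-checked against
`vegan::vegdist()` in the suite; a pair of all-zero samples is defined
as dissimilarity 0 with a warning. PCoA is classical scaling
(`cmdscale`): double-center −D²/2, eigendecompose, scale eigenvectors
by √λ. Axes follow a fixed sign convention (first non-negligible
loading positive) so runs are comparable. Negative eigenvalues —
expected for non-Euclidean dissimilarities like Bray–Curtis — are
excluded from coordinates and variance fractions and reported
separately; no Cailliez-style correction is applied, because the
package interprets only leading-axis structure, and a constant added
to every dissimilarity would dilute exactly that. Collector curves
permute sample order (seeded), accumulate distinct detected taxa, and
average; habitat sharing collapses per-sample detection to per-habitat
presence and reports Euler regions that partition the detected taxa.
Codon-usage profiles are pooled codon frequencies over in-frame CDSs
(64-vector summing to 1), suitable input for Bray–Curtis + PCoA.

## The synthetic scenario: what it emulates, and what not

`community_config()` defaults define the package's study conditions:

* **Three habitats** (palsa, bog, fen) with 10 vOTUs each and partial
  pool overlap — palsa∩bog = 1, bog∩fen = 2, palsa∩fen = 0 — so 27
  distinct genomes, 3/27 ≈ 11% of them multi-habitat and none shared
  between the gradient's end members, mirroring the habitat
  specificity such gradients show.
* **Genome lengths** uniform on 9.5–10.5 kb: the scale of
  well-sampled soil phage populations, kept narrow so that
  length-weighting noise in habitat-level abundance sums stays small
  relative to the configured gradient (a variance consideration, not a
  fit to data).
* **Abundances** log-normal (meanlog 0, sdlog 0.5) per habitat,
  total-sum scaled — a modest realistic rank-abundance spread whose
  least-abundant member still attains ~2× coverage at the default
  depth, comfortably above the ~1.4× that 75% breadth requires.
* **Viral load gradient** 1×/3×/12× (palsa/bog/fen), realized through
  the viral fraction of each library (0.07/0.21/0.84 of reads; the
  remainder is host-genome background). Particle-enriched viromes are
  genuinely virus-dominated, and per-Gbp abundances then recover the
  configured fold factors.
* **Libraries**: 2 replicate viromes per habitat, 100,000 reads of
  200 bp each (20 Mbp), 1% uniform substitution error, strand drawn
  with probability 0.5. Half the vOTUs carry a second contig variant
  (2% divergence, ≥85% length) to exercise dereplication.
* **Hosts**: five 20-kb genomes, four carrying one CRISPR array
  (repeat 30 bp, five 35-bp spacers sampled verbatim from viral
  genomes, strand recorded), one link-free.
* **Gene content**: planned VCs of about five genomes; members share
  10 core protein families of their cluster plus 5 private singletons
  (15 per genome), zero inter-cluster sharing by default.

All randomness flows from one master seed through per-operation
streams (seed, operation name), so stages are independently
reproducible and a rerun is byte-identical — the suite checks output
checksums.

What the generator deliberately does **not** model: indels and
quality-score error profiles (reads carry substitutions only), GC and
k-mer composition bias (genomes are i.i.d. uniform, maximizing ANI
contrast between unrelated genomes), assembly artefacts (contigs are
planted, not assembled), within-population structural variation beyond
truncation + substitution, temperate/lytic dynamics, and taxonomy.
Passing the end-to-end suite therefore demonstrates that the inference
chain is correct and well-calibrated under its stated assumptions — it
does not certify performance on real soil viromes, where divergence
includes indels, abundance distributions are heavier-tailed, and
contaminants (e.g. gene transfer agents) blur the viral signal.

## Problem sizes and runtime

The default end-to-end scenario (27 genomes, 43 contigs, 6 × 100k
reads, 21-inflation scan) runs in about a minute on one core; unit
tests use scaled-down variants (3–5 kb genomes, thousands of reads).
These sizes were chosen as the smallest at which every detection and
recovery property is statistically comfortable, not as a model of real
sequencing depth.

## Known limitations

* The ANI and similarity engines are ungapped and diagonal-anchored;
  indel-rich homology needs an external aligner (import via
  `read_sam()`/`read_blast_tab()`).
* The mapper is for the synthetic path only (uniform read length,
  ungapped).
* Hypergeometric scoring treats PCs as exchangeable; shared-content
  biases (e.g. mosaicism) are not modelled.
* PCoA variance fractions are reported relative to the
  positive-eigenvalue total; with strongly non-Euclidean inputs the
  negative spectrum (reported) should be inspected.
* No significance testing of ordination groupings is provided; the
  package reports the ordination and leaves inference to the user.
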