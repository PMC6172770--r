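# thawvir

Viral population ecology for soil viromes along a permafrost thaw
gradient.

Permafrost peatlands store a large share of global soil carbon, and as
they thaw — from intact palsa mounds through *Sphagnum* bogs to sedge
fens — their microbial communities and carbon-gas emissions shift.
Viruses modulate those microbes from the top down (lysis) and the
bottom up (host metabolic reprogramming), but soil viromics has lacked
reusable, tested tooling for the inference chain that turns
particle-enriched virome reads into ecological statements. `thawvir`
implements that chain for dsDNA virome data, together with a fully
seeded synthetic-community generator so every step can be validated
against a known ground truth.

## What it computes

- **vOTU dereplication.** Contigs are greedily clustered
  (longest-first) into species-level viral populations at ≥95% average
  nucleotide identity (ANI) across ≥80% of the (shorter) contig
  length. ANI is identities over aligned columns of the best local
  alignment.
- **Detection and abundance by read recruitment.** A read counts if it
  maps at ≥90% identity; a vOTU is *detected* in a virome when mapped
  reads cover ≥75% of its length (breadth of coverage, union of
  intervals). Abundance is mapped bp, normalized by contig length and
  library size: `A = (bp_mapped / L_contig) / bp_library × 10⁹`
  (per Gbp).
- **Gene-sharing viral clusters (≈ genus level).** Proteins are
  clustered into protein clusters (PCs; ≥50 bits, E ≤ 1e-4, Markov
  clustering, PCs must span ≥2 genomes). Each genome pair sharing
  `c` of its `a` and `b` PCs from a universe of `n` PCs is scored with
  the hypergeometric tail
  `P = Σ_{i=c}^{min(a,b)} C(a,i)·C(n−a,b−i) / C(n,b)` and
  `S = −log10(P·T)`, `T = N(N−1)` ordered genome comparisons. Edges
  with `S ≥ 1` form the network, partitioned by Markov clustering
  across the 21-value inflation scan 1.0–5.0 (step 0.2); genomes end
  up clustered, in doubletons, or as singletons.
- **Host prediction.** CRISPR arrays (repeat–spacer–repeat runs) are
  detected in host genomes and their spacers matched exactly (0
  mismatches by default, either strand) against vOTUs; nucleotide
  similarity linkage requires ≥50 bits, E ≤ 1e-3, ≥70% ANI over
  ≥2,500 bp.
- **Community ecology.** Richness, Shannon `H′ = −Σ p ln p`, Pielou
  `J = H′/ln S`; Bray–Curtis dissimilarity
  `BC = Σ|xᵢ−yᵢ| / Σ(xᵢ+yᵢ)` with principal-coordinate analysis
  (classical scaling); habitat-sharing (Euler) regions; randomized
  collector curves; codon-usage frequency profiles; a ≥95%-ANI
  contaminant screen.
- **Synthetic truth.** `simulate_scenario()` builds habitat-structured
  communities (habitat-specific vOTU pools with configured overlaps,
  log-normal abundances, a 1×/3×/12× viral-load gradient), reads with
  substitution errors, CRISPR-bearing hosts, and planted
  protein-family content — all traceable to ground-truth tables.

## Worked example

```r
library(thawvir)

# Published per-virome read accounting for the seven thaw-gradient
# viromes (palsa/bog/fen, chilled/frozen storage)
vs <- summarize_viromes(stordalen_virome_counts())
vs
#> <virome_summary> 7 viromes; assembled % mean 18.5 (range 4.9-32.4);
#>   pooled vOTU reads: 10.0% of assembled, 53.8% of viral
fold_ratio(vs, "bog_chilled_B", "bog_frozen_B")
#> [1] 9.035608

# Full pipeline on the default synthetic thaw-gradient scenario
run <- run_pipeline(pipeline_config(seed = 1))
run
#> <thaw_pipeline> 43 contigs -> 27 vOTUs; 6 samples; 5 VCs;
#>   24 host links; 27 taxa detected

evaluate_recovery(run)$summary
#> # A tibble: 7 x 2
#>   metric              value
#> 1 votu_accuracy      1
#> 2 votu_ari           1
#> 3 vc_ari             1
#> 4 hostlink_recall    1
#> 5 hostlink_false     0
#> 6 overlap_exact      1
#> 7 max_fold_rel_error 0.0132
```

The accounting line says that on average 18.5% (range 4.9–32.4%) of
virome reads assembled, and that the 53 well-sampled vOTUs absorbed
10.0% of assembled reads (53.8% of reads recruited to putative viral
contigs); the chilled bog virome assembled 9.0× more reads than its
frozen replicate. The recovery table shows the pipeline returning the
planted truth exactly: every contig in its correct population, the
planned viral clusters recovered with adjusted Rand index 1, all
CRISPR host links found with none invented, habitat-overlap counts
exact, and the 1×/3×/12× abundance gradient recovered within 1.3%.

Plots: `autoplot(run$ecology$pcoa, ...)`,
`autoplot(run$ecology$collector)`,
`plot_abundance_heatmap(run$abundance)`.

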