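# ssuscan

Locus-centric analysis of convergent chromosomal translocations at a focal
gene promoter, modelled on the sulfite-efflux pump gene *SSU1* of wine
yeasts. Sulfite is the standard preservative of wine and cider musts, and
reciprocal translocations that rewire the *SSU1* promoter are a recurrent
route to sulfite tolerance. Given annotated genome assemblies (FASTA + GFF3
per strain) and an ortholog table, `ssuscan`:

* classifies each strain's focal-gene promoter as **ancestral** or
  **translocated** from its upstream gene neighbourhood, reporting the
  partner chromosome and the end-to-start / start-to-start intergenic
  distances;
* localises the translocation **breakpoint** to base-pair resolution by
  seed-anchored comparison of the recombinant promoter against both parental
  chromosomes, and delimits the **junction microhomology** (the interval
  within which both parents match the recombinant exactly, so the junction
  cannot be placed more precisely);
* scores retention of a transcription-factor binding motif (default the
  Fzf1p site `5'-CTATCA-3'`): a motif whose ancestral position lies beyond
  the junction has been replaced, hence **lost**;
* quantifies **shared haplotype blocks** between strains: per-ortholog
  pairwise distances under the Kimura (1981) three-substitution-type model,

  `d = -(1/4) [ ln(1-2P-2Q) + ln(1-2P-2R) + ln(1-2Q-2R) ]`,

  with `P` the proportion of sites differing by a transition and `Q`, `R`
  the two transversion classes; the maximal run of zero-mismatch orthologs
  around the focal gene is tested against a null of random 20-gene windows
  with a two-sided Mann–Whitney rank test;
* summarises sulfite-tolerance **drop tests** (max tolerated metabisulfite,
  g/L, Welch comparison between promoter classes) and **qPCR relative
  expression** (standard-curve efficiencies, normalisation to the average of
  two reference genes, ratios to a calibrator strain);
* ships a seeded **synthetic-genome generator** that plants translocations,
  junction microhomology, identical-by-state blocks, expression
  fold-changes and tolerance classes with known truth, so the whole pipeline
  is testable without external assemblies.

## Worked example

Simulate the default scenario (21 strains: 17 ancestral, 3 sharing a chrVII
translocation 339 bp upstream of the focal gene with 8 bp microhomology, 1
with an independent chrXI event at 393 bp) and run every stage:

```r
library(ssuscan)
res <- run_pipeline("all", out = "demo", seed = 1)
res$detect$summary
#>                 group  n
#>             ancestral 17
#>   translocated:chrVII  3
#>    translocated:chrXI  1
res$detect$calls[res$detect$calls$variant_class == "translocated",
                 c("strain", "partner_chromosome", "breakpoint_offset",
                   "microhomology_len", "motif_status")]
#>  strain partner_chromosome breakpoint_offset microhomology_len motif_status
#>   vii01             chrVII               339                 8         lost
#>   vii02             chrVII               339                 8         lost
#>   vii03             chrVII               339                 8         lost
#>    xi01              chrXI               393                 4         lost
res$haploshare$test
#> <permutation_result> focal n=20 (mean 0) vs 1000 windows of 20 genes
#>   Mann-Whitney U = 0.0, two-sided p = 9.63e-15; empirical window-mean p = 0.000999
```

Every planted breakpoint offset and microhomology is recovered exactly, the
motif is correctly called lost (its ancestral position, 500 bp upstream,
lies beyond both junctions), and the planted identical block shared by
`vii01`/`vii02` (33 genes left + 21 right, ~109 kb) is significantly tighter
than any random 20-gene window (Mann–Whitney p ≈ 1e-14). The phenotype stage
reports ancestral strains tolerating 0.18 ± 0.03 g/L metabisulfite against
0.36 ± 0.02 g/L for translocated strains (Welch p ≈ 2e-14), and the qPCR
stage recovers the planted ~10-fold overexpression of the translocated
strains relative to the ancestral calibrator.

The same stages run from the shell via the installed `exec/ssuscan` script:

```sh
ssuscan simulate --out demo --seed 1
ssuscan detect   --out demo
ssuscan all      --out demo --force
```

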