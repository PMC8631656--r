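# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk except files the tests themselves write.

# Hand-laid two-gene genome on one chromosome (plus-strand unless flipped).
toy_genome <- function(strain_id = "TOY", seq_len = 3000L) {
  chrom <- withr::with_seed(99, ssuscan:::random_seq(seq_len))
  genes <- data.frame(
    gene_id = paste0(strain_id, c("_g1", "_g2")),
    ortholog_id = c("OG1", "OG2"),
    chromosome = "chrI",
    start = c(501L, 1423L), end = c(1000L, 2222L),
    strand = c("+", "+"), stringsAsFactors = FALSE)
  annotated_genome(strain_id, list(chrI = chrom), genes)
}

# Ancestor plus two strains diverged by `branch` each, with an ortholog map.
make_pair <- function(seed, n_genes = 60L, branch = 0.025,
                      gene_length = 1000L, focal_index = 30L) {
  ref <- simulate_reference(
    seed = seed, chromosomes = c(chrI = n_genes),
    gene_length = gene_length,
    focal = list(chromosome = "chrI", index = focal_index), motif = NULL)
  A <- evolve_k81(ref, branch, seed = seed + 1L, strain_id = "A")
  B <- evolve_k81(ref, branch, seed = seed + 2L, strain_id = "B")
  list(ref = ref, A = A, B = B,
       orthologs = build_ortholog_map(list(A, B)),
       focal = ref$genes$ortholog_id[focal_index])
}

# Translocated strain scenario at configurable microhomology and divergence.
make_translocation <- function(seed, k = 8L, divergence = 0, offset = 339L,
                               n_genes = 20L) {
  ref <- simulate_reference(
    seed = seed, chromosomes = c(chrVII = n_genes, chrXVI = n_genes),
    focal = list(chromosome = "chrXVI", index = n_genes %/% 2L),
    motif = NULL)
  focal <- ref$genes$ortholog_id[ref$genes$chromosome == "chrXVI"][n_genes %/% 2L]
  tr <- apply_translocation(ref, focal, "chrVII", offset = offset,
                            microhomology_len = k,
                            partner_gene_index = n_genes %/% 2L,
                            derived_strain_id = "D", seed = seed + 1L)
  derived <- if (divergence > 0)
    evolve_k81(tr$derived, divergence, seed = seed + 2L, strain_id = "D")
  else tr$derived
  list(reference = tr$reference, derived = derived, truth = tr$truth,
       focal = focal)
}

expect_error_class <- function(expr, class) {
  expect_error(expr, class = class)
}
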