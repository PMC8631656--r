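test_that("reference simulation lays out genes deterministically", {
  g <- simulate_reference(seed = 5L, chromosomes = c(chrI = 50L, chrII = 50L),
                          gene_length = 300L, intergenic_length = 200L,
                          focal = list(chromosome = "chrII", index = 25L),
                          motif = NULL)
  expect_identical(nrow(g$genes), 100L)
  expect_identical(length(unique(g$genes$ortholog_id)), 100L)
  chr1 <- g$genes[g$genes$chromosome == "chrI", ]
  expect_identical(chr1$start, 200L + (0:49) * 500L + 1L)
  expect_identical(chr1$end, chr1$start + 299L)
  g2 <- simulate_reference(seed = 5L, chromosomes = c(chrI = 50L, chrII = 50L),
                           gene_length = 300L, intergenic_length = 200L,
                           focal = list(chromosome = "chrII", index = 25L),
                           motif = NULL)
  expect_identical(g2$chromosomes, g$chromosomes)
  expect_identical(g2$genes, g$genes)
  expect_error_class(
    simulate_reference(chromosomes = c(chrI = 0L),
                       focal = list(chromosome = "chrI", index = 1L)),
    "ssuscan_config_error")
})

test_that("the planted motif is the unique hit in the focal upstream window", {
  g <- simulate_reference(seed = 8L, chromosomes = c(chrI = 10L),
                          focal = list(chromosome = "chrI", index = 5L),
                          motif = "CTATCA", motif_offset = 500L)
  fg <- g$genes[5L, ]
  win <- ssuscan:::upstream_window(g, fg, 5000L)
  res <- motif_retention(win, "CTATCA")
  expect_identical(res$positions, 500L)
})

test_that("translocation conserves bases, remaps genes and refuses re-application", {
  tr <- make_translocation(seed = 700L, k = 8L)
  ref <- tr$reference; der <- tr$derived
  expect_identical(sum(nchar(unlist(der$chromosomes))),
                   sum(nchar(unlist(ref$chromosomes))))
  expect_setequal(der$genes$ortholog_id, ref$genes$ortholog_id)
  ## the focal gene keeps its ortholog but gains a new upstream neighbour
  nb <- extract_neighborhood(der, tr$focal)
  expect_identical(nb$upstream$ortholog_id[1], tr$truth$upstream_ortholog)
  expect_error_class(
    apply_translocation(der, tr$focal, "chrVII", offset = 339L,
                        microhomology_len = 8L, partner_gene_index = 10L),
    "ssuscan_config_error")
})

test_that("a breakpoint offset reaching into a gene is rejected", {
  ref <- simulate_reference(seed = 9L, chromosomes = c(chrA = 10L, chrB = 10L),
                            gene_length = 500L, intergenic_length = 400L,
                            focal = list(chromosome = "chrB", index = 5L),
                            motif = NULL)
  focal <- ref$genes$ortholog_id[ref$genes$chromosome == "chrB"][5L]
  expect_error_class(
    apply_translocation(ref, focal, "chrA", offset = 420L,
                        microhomology_len = 8L, partner_gene_index = 5L),
    "ssuscan_config_error")
})

test_that("K81 evolution is seeded, length-preserving and estimator-consistent", {
  g <- simulate_reference(seed = 12L, chromosomes = c(chrI = 50L),
                          gene_length = 1000L, intergenic_length = 1000L,
                          focal = list(chromosome = "chrI", index = 25L),
                          motif = NULL)
  e0 <- evolve_k81(g, 0, seed = 1L, strain_id = "E0")
  expect_identical(e0$chromosomes, g$chromosomes)
  e1 <- evolve_k81(g, 0.05, seed = 2L, strain_id = "E1")
  e1b <- evolve_k81(g, 0.05, seed = 2L, strain_id = "E1")
  expect_identical(e1$chromosomes, e1b$chromosomes)
  d <- k81_distance(g$chromosomes$chrI, e1$chromosomes$chrI)
  expect_lt(abs(d$distance - 0.05), 0.005)
  ## transition-only evolution produces no transversions
  et <- evolve_k81(g, 0.05, rate_fractions = c(1, 0, 0), seed = 3L,
                   strain_id = "ET")
  dt <- k81_distance(g$chromosomes$chrI, et$chromosomes$chrI)
  expect_identical(dt$Q, 0)
  expect_identical(dt$R, 0)
  expect_gt(dt$P, 0.03)
  expect_error_class(evolve_k81(g, -0.1, seed = 1L), "ssuscan_config_error")
})

test_that("planted shared blocks are identical inside and divergent just outside", {
  pair <- make_pair(seed = 70L, n_genes = 30L, branch = 0.025,
                    gene_length = 1000L, focal_index = 15L)
  pb <- plant_shared_block(pair$A, pair$B, pair$focal, left = 5L, right = 3L)
  prof <- gene_profile(pair$A, pb$genome, pair$orthologs, pair$focal,
                       flank = 7L)
  expect_true(all(prof$mismatches[abs(prof$rank) <= 3] == 0L))
  expect_true(all(prof$mismatches[prof$rank %in% c(-5, -4)] == 0L))
  expect_gt(prof$mismatches[prof$rank == -6], 0L)
  expect_gt(prof$mismatches[prof$rank == 4], 0L)
  expect_error_class(
    plant_shared_block(pair$A, pair$B, pair$focal, left = 20L, right = 3L),
    "ssuscan_config_error")
})

test_that("noise-free qPCR simulation recovers fold changes exactly", {
  sim <- simulate_qpcr(list(strains = c(cal = 1, up = 10), calibrator = "cal",
                            noise_sd = 0), seed = 31L)
  curves <- lapply(split(sim$curve_table, sim$curve_table$gene),
                   function(x) fit_standard_curve(x, gene = x$gene[1]))
  expr <- normalize_expression(sim$ct_table, curves, calibrator = "cal")
  expect_true(all(abs(expr$ratio[expr$strain == "up"] - 10) < 1e-9))
  expect_true(all(expr$ratio[expr$strain == "cal"] == 1))
  sim2 <- simulate_qpcr(list(strains = c(cal = 1, up = 10),
                             calibrator = "cal", noise_sd = 0), seed = 31L)
  expect_identical(sim$ct_table, sim2$ct_table)
})

test_that("noise-free drop tests sit exactly at their class means", {
  sim <- simulate_droptest(list(noise_sd = 0), seed = 41L)
  per <- tolerance_summary(sim$table)
  ## class means snap to the nearest grid point (ties resolve downward)
  expect_equal(unique(per$max_mbs[per$class == "ancestral"]), 0.15)
  expect_equal(unique(per$max_mbs[per$class == "VII^XVI"]), 0.35)
  expect_equal(unique(per$max_mbs[per$class == "XI^XVI"]), 0.40)
  expect_true(all(sim$table$scores >= 0L & sim$table$scores <= 6L))
  sim2 <- simulate_droptest(list(noise_sd = 0), seed = 41L)
  expect_identical(sim$table$scores, sim2$table$scores)
})

test_that("scenario simulation plants a consistent truth table", {
  cfg <- scenario_config(seed = 77L, n_ancestral = 2L, n_vii = 2L, n_xi = 1L)
  cfg$chromosomes <- c(chrVII = 40L, chrXI = 40L, chrXVI = 40L)
  cfg$focal <- list(chromosome = "chrXVI", index = 20L)
  cfg$events$vii$partner_gene_index <- 20L
  cfg$events$xi$partner_gene_index <- 20L
  cfg$shared_block <- list(strains = c("vii01", "vii02"), left = 8L,
                           right = 6L)
  scn <- simulate_scenario(cfg)
  expect_identical(sort(names(scn$genomes)),
                   sort(cfg$strains$strain_id))
  scan <- scan_collection(scn$genomes, scn$reference, scn$focal)
  got <- setNames(scan$calls$variant_class, scan$calls$strain)
  truth_class <- ifelse(scn$truth$classes == "ancestral", "ancestral",
                        "translocated")
  expect_identical(got[names(truth_class)], truth_class)
  hs <- haplotype_sharing_test(scn$genomes$vii01, scn$genomes$vii02,
                               scn$orthologs, scn$focal, window_size = 10L,
                               n_windows = 100L, seed = 5L)
  expect_identical(hs$block$left, 8L)
  expect_identical(hs$block$right, 6L)
})
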