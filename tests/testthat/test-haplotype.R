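# Test-local exact Mann-Whitney oracle: enumerate every assignment of the
# pooled values into groups of the observed sizes and recompute U from
# scratch (no ranks shared with the implementation).
oracle_mw_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  u_of <- function(xs, ys) {
    sum(vapply(xs, function(v) sum(v > ys) + 0.5 * sum(v == ys), numeric(1)))
  }
  u_obs <- u_of(x, y)
  mu <- n1 * n2 / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, function(ix) u_of(pool[ix], pool[-ix]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

test_that("distance profile of identical strains is all zero", {
  pair <- make_pair(seed = 10L, n_genes = 15L, branch = 0,
                    gene_length = 300L, focal_index = 8L)
  prof <- gene_profile(pair$A, pair$B, pair$orthologs, pair$focal, flank = 5L)
  expect_identical(nrow(prof), 11L)
  expect_identical(prof$rank, -5:5)
  expect_true(all(prof$k81 == 0))
  expect_true(all(prof$mismatches == 0L))
})

test_that("a planted identical block stands out against background divergence", {
  pair <- make_pair(seed = 20L, n_genes = 30L, branch = 0.025,
                    gene_length = 1000L, focal_index = 15L)
  pb <- plant_shared_block(pair$A, pair$B, pair$focal, left = 0L, right = 10L)
  prof <- gene_profile(pair$A, pb$genome, pair$orthologs, pair$focal,
                       flank = 12L)
  right <- prof[prof$rank >= 1 & prof$rank <= 10, ]
  expect_true(all(right$mismatches == 0L))
  left <- prof[prof$rank < 0, ]
  expect_true(all(left$mismatches > 0L))
  blk <- shared_block(prof)
  expect_identical(blk$left, 0L)
  expect_identical(blk$right, 10L)
})

test_that("profiles are invariant to annotation row order", {
  pair <- make_pair(seed = 30L, n_genes = 12L, branch = 0.02,
                    gene_length = 300L, focal_index = 6L)
  prof1 <- gene_profile(pair$A, pair$B, pair$orthologs, pair$focal, flank = 4L)
  perm <- withr::with_seed(2, sample(nrow(pair$A$genes)))
  A2 <- annotated_genome(pair$A$strain_id, pair$A$chromosomes,
                         pair$A$genes[perm, ])
  prof2 <- gene_profile(A2, pair$B, pair$orthologs, pair$focal, flank = 4L)
  expect_equal(as.data.frame(prof1), as.data.frame(prof2))
})

test_that("shared-block walks stop at gaps and non-identical focal genes", {
  prof <- data.frame(
    ortholog_id = sprintf("OG%d", 1:7), rank = -3:3,
    chromosome = "chrI", start = (0:6) * 1000 + 1, end = (0:6) * 1000 + 500,
    aligned_length = 500L, n_sites = 500L,
    mismatches = c(0L, 1L, 0L, 0L, 0L, NA, 0L),
    k81 = c(0, 0.002, 0, 0, 0, NA, 0), saturated = FALSE)
  blk <- shared_block(prof)
  expect_identical(blk$left, 1L)    # stops at the rank -2 mismatch
  expect_identical(blk$right, 1L)   # stops at the rank +2 gap
  expect_identical(blk$boundary_left, "OG3")
  expect_identical(blk$boundary_right, "OG5")
  expect_equal(blk$span_kb, 2.5)    # 1001 .. 3500 on strain A

  prof$mismatches[4] <- 2L          # focal gene itself differs
  expect_identical(shared_block(prof)$left, 0L)
  expect_identical(shared_block(prof)$right, 0L)
})

test_that("random windows respect size, exclusion and seeding", {
  pair <- make_pair(seed = 40L, n_genes = 60L, branch = 0.02,
                    gene_length = 300L, focal_index = 30L)
  fg <- ssuscan:::find_ortholog_gene(pair$A, pair$focal)
  excl <- list(chromosome = fg$chromosome, start = fg$start - 3000L,
               end = fg$end + 3000L)
  null1 <- random_window_null(pair$A, pair$B, pair$orthologs,
                              window_size = 10L, n_windows = 200L, seed = 7L,
                              exclusion = excl)
  expect_identical(length(null1$window_means), 200L)
  expect_identical(length(null1$pooled) + null1$n_saturated, 2000L)
  tab <- null1$gene_table
  for (i in null1$starts) {
    genes <- tab[i:(i + 9L), ]
    expect_true(all(genes$usable))
    expect_true(all(genes$end < excl$start | genes$start > excl$end))
  }
  null2 <- random_window_null(pair$A, pair$B, pair$orthologs,
                              window_size = 10L, n_windows = 200L, seed = 7L,
                              exclusion = excl)
  expect_identical(null1$starts, null2$starts)
  expect_identical(null1$pooled, null2$pooled)
  ## exclusion swallowing the whole chromosome leaves no valid windows
  expect_error_class(
    random_window_null(pair$A, pair$B, pair$orthologs, window_size = 10L,
                       n_windows = 10L, seed = 1L,
                       exclusion = list(chromosome = fg$chromosome,
                                        start = 1L, end = 10^9)),
    "ssuscan_config_error")
})

test_that("exact Mann-Whitney matches full-enumeration oracle for all n <= 5", {
  withr::with_seed(11, {
    for (n1 in 2:5) for (n2 in 2:5) {
      x <- sample(1:6, n1, replace = TRUE)     # ties likely
      y <- sample(1:6, n2, replace = TRUE)
      got <- mann_whitney(x, y, exact = TRUE)
      expect_equal(got$p_value, oracle_mw_exact(x, y), tolerance = 1e-12,
                   label = sprintf("n1=%d n2=%d", n1, n2))
    }
  })
})

test_that("exact Mann-Whitney agrees with wilcox.test in the tie-free case", {
  withr::with_seed(12, {
    for (i in 1:10) {
      x <- rnorm(6); y <- rnorm(7)
      got <- mann_whitney(x, y, exact = TRUE)
      ref <- stats::wilcox.test(x, y, exact = TRUE)
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
      expect_equal(got$U, unname(ref$statistic))
    }
  })
})

test_that("the normal approximation tracks the exact test at moderate n", {
  withr::with_seed(13, {
    for (i in 1:10) {
      x <- rnorm(8); y <- rnorm(8)
      pe <- mann_whitney(x, y, exact = TRUE)$p_value
      pn <- mann_whitney(x, y, exact = FALSE)$p_value
      expect_lt(abs(pe - pn), 0.03)
    }
  })
})

test_that("window significance handles degenerate and planted cases", {
  null <- list(pooled = rep(1, 50), window_means = rep(1, 5), seed = 1L,
               n_windows = 5L, window_size = 10L)
  res <- window_significance(rep(1, 10), null)
  expect_identical(res$p_value, 1)
  ## planted identical focal window against diverged null
  pair <- make_pair(seed = 50L, n_genes = 60L, branch = 0.025,
                    gene_length = 500L, focal_index = 30L)
  pb <- plant_shared_block(pair$A, pair$B, pair$focal, left = 10L, right = 9L)
  hs <- haplotype_sharing_test(pair$A, pb$genome, pair$orthologs, pair$focal,
                               window_size = 20L, n_windows = 200L, seed = 3L)
  expect_lt(hs$test$p_value, 0.05)
  expect_equal(hs$test$empirical_p, 1 / 201)
  expect_identical(hs$block$left, 10L)
  expect_identical(hs$block$right, 9L)
})

test_that("higher background divergence never weakens the focal-window signal", {
  ps <- vapply(c(0.005, 0.01, 0.025, 0.05), function(br) {
    pair <- make_pair(seed = 60L, n_genes = 60L, branch = br,
                      gene_length = 500L, focal_index = 30L)
    pb <- plant_shared_block(pair$A, pair$B, pair$focal, left = 10L,
                             right = 9L)
    hs <- haplotype_sharing_test(pair$A, pb$genome, pair$orthologs,
                                 pair$focal, window_size = 20L,
                                 n_windows = 200L, seed = 3L)
    hs$test$p_value
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})
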