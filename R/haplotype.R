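## Haplotype sharing around the focal gene: per-ortholog K81 distance
## profiles, delimitation of the maximal shared identical block, and a
## random-gene-window permutation test with a Mann-Whitney rank statistic.

## Coding-strand sequence of one gene.
gene_sequence <- function(genome, gene) {
  s <- substr(genome$chromosomes[[gene$chromosome]], gene$start, gene$end)
  if (gene$strand == "-") s <- revcomp(s) else s
}

## Distance record for one ortholog shared by two strains.
ortholog_distance <- function(genomeA, genomeB, geneA, geneB) {
  al <- align_pair(gene_sequence(genomeA, geneA), gene_sequence(genomeB, geneB))
  d <- k81_distance(al[[1L]], al[[2L]])
  list(aligned_length = nchar(al[[1L]]), n_sites = d$n_sites,
       mismatches = d$mismatches, k81 = d$distance, saturated = d$saturated)
}

#' Pairwise K81 distance profile around the focal gene
#'
#' For every ortholog within `flank` gene ranks of the focal gene on the
#' focal chromosome of strain A (chromosome coordinate order; the focal gene
#' is rank 0, lower coordinates negative), extracts both coding-strand gene
#' sequences, aligns them globally and records the K81 distance and raw
#' mismatch count. Orthologs absent from strain B appear as gap records with
#' `NA` distances.
#'
#' @param genomeA,genomeB `annotated_genome` objects.
#' @param orthologs ortholog map (see [read_ortholog_table()]).
#' @param focal focal ortholog ID (must be present in both strains).
#' @param flank gene ranks on each side.
#' @return data.frame of class `distance_profile`, ordered by rank.
#' @export
gene_profile <- function(genomeA, genomeB, orthologs, focal, flank = 5L) {
  fgA <- find_ortholog_gene(genomeA, focal)
  find_ortholog_gene(genomeB, focal)  # errors if absent
  chr <- genomeA$genes[genomeA$genes$chromosome == fgA$chromosome, ,
                       drop = FALSE]
  chr <- chr[order(chr$start), , drop = FALSE]
  f_idx <- which(chr$gene_id == fgA$gene_id)
  idx <- (f_idx - flank):(f_idx + flank)
  keep <- idx >= 1L & idx <= nrow(chr)
  ranks <- ((-flank):flank)[keep]
  idx <- idx[keep]
  rows <- lapply(seq_along(idx), function(j) {
    gA <- chr[idx[j], , drop = FALSE]
    rec <- data.frame(ortholog_id = gA$ortholog_id, rank = ranks[j],
                      chromosome = gA$chromosome, start = gA$start,
                      end = gA$end, aligned_length = NA_integer_,
                      n_sites = NA_integer_, mismatches = NA_integer_,
                      k81 = NA_real_, saturated = NA,
                      stringsAsFactors = FALSE)
    if (is.na(gA$ortholog_id)) return(rec)
    gB <- find_ortholog_gene(genomeB, gA$ortholog_id, required = FALSE)
    if (is.null(gB)) return(rec)
    d <- ortholog_distance(genomeA, genomeB, gA, gB)
    rec$aligned_length <- d$aligned_length
    rec$n_sites <- d$n_sites
    rec$mismatches <- d$mismatches
    rec$k81 <- d$k81
    rec$saturated <- d$saturated
    rec
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "strainA") <- genomeA$strain_id
  attr(out, "strainB") <- genomeB$strain_id
  attr(out, "focal") <- focal
  class(out) <- c("distance_profile", "data.frame")
  out
}

#' Delimit the maximal shared identical block around the focal gene
#'
#' Walks outward from rank 0 in each direction while the raw mismatch count
#' is exactly 0 (sequence identity, not model distance). A missing ortholog
#' or a saturated/absent record terminates the walk. Counts exclude the focal
#' gene; the span is the kb extent from the outermost identical gene on the
#' left to the outermost on the right, on strain A coordinates.
#'
#' @param profile `distance_profile` containing rank 0.
#' @return list with `left`, `right` (gene counts), `boundary_left`,
#'   `boundary_right` (outermost identical ortholog IDs, `NA` if none) and
#'   `span_kb`.
#' @export
shared_block <- function(profile) {
  f <- profile[profile$rank == 0L, , drop = FALSE]
  if (nrow(f) != 1L) stop_lookup("profile does not contain rank 0")
  identical_at <- function(rnk) {
    rec <- profile[profile$rank == rnk, , drop = FALSE]
    nrow(rec) == 1L && !is.na(rec$mismatches) && rec$mismatches == 0L
  }
  if (!identical_at(0L))
    return(list(left = 0L, right = 0L, boundary_left = NA_character_,
                boundary_right = NA_character_, span_kb = 0))
  walk <- function(dir) {
    n <- 0L
    repeat {
      if (!identical_at(dir * (n + 1L))) break
      n <- n + 1L
    }
    n
  }
  left <- walk(-1L)
  right <- walk(1L)
  inblock <- profile[profile$rank >= -left & profile$rank <= right, ,
                     drop = FALSE]
  span_kb <- (max(inblock$end) - min(inblock$start) + 1L) / 1000
  list(left = left, right = right,
       boundary_left = if (left > 0L)
         profile$ortholog_id[profile$rank == -left] else NA_character_,
       boundary_right = if (right > 0L)
         profile$ortholog_id[profile$rank == right] else NA_character_,
       span_kb = span_kb)
}

## Ordered table of orthologs shared by two strains, in strain-A gene order,
## with per-ortholog distances computed once (the cache behind the window
## sampler).
shared_ortholog_distances <- function(genomeA, genomeB, orthologs) {
  gA <- genomeA$genes[!is.na(genomeA$genes$ortholog_id), , drop = FALSE]
  gA <- gA[order(gA$chromosome, gA$start), , drop = FALSE]
  inmap <- gA$ortholog_id %in% orthologs$ortholog_id
  hitB <- match(gA$ortholog_id, genomeB$genes$ortholog_id)
  usable <- inmap & !is.na(hitB)
  k81 <- rep(NA_real_, nrow(gA))
  mism <- rep(NA_integer_, nrow(gA))
  sat <- rep(NA, nrow(gA))
  for (i in which(usable)) {
    d <- ortholog_distance(genomeA, genomeB, gA[i, , drop = FALSE],
                           genomeB$genes[hitB[i], , drop = FALSE])
    k81[i] <- d$k81; mism[i] <- d$mismatches; sat[i] <- d$saturated
  }
  data.frame(ortholog_id = gA$ortholog_id, chromosome = gA$chromosome,
             start = gA$start, end = gA$end, usable = usable, k81 = k81,
             mismatches = mism, saturated = sat, stringsAsFactors = FALSE)
}

#' Null distribution from random gene windows
#'
#' Samples `n_windows` windows of `window_size` consecutive shared orthologs
#' (uniformly over valid start positions, with replacement) from the strain-A
#' gene order. A window must lie on one chromosome, contain only orthologs
#' present in both strains (a missing ortholog breaks consecutiveness) and
#' fall entirely outside the exclusion interval. Saturated distances are
#' excluded from the pooled null with a recorded count. Deterministic given
#' `seed`.
#'
#' @param genomeA,genomeB `annotated_genome` objects.
#' @param orthologs ortholog map.
#' @param window_size genes per window.
#' @param n_windows number of windows.
#' @param seed integer seed.
#' @param exclusion `NULL` or list(chromosome, start, end) on strain-A
#'   coordinates; windows overlapping it are excluded.
#' @param cache optional precomputed [shared_ortholog_distances()] table.
#' @return list of class `permutation_null` with the pooled null distances,
#'   per-window means, window start indices and bookkeeping fields.
#' @export
random_window_null <- function(genomeA, genomeB, orthologs,
                               window_size = 20L, n_windows = 1000L, seed,
                               exclusion = NULL, cache = NULL) {
  tab <- cache %||% shared_ortholog_distances(genomeA, genomeB, orthologs)
  n <- nrow(tab)
  if (n < window_size) stop_config("fewer shared orthologs than window_size")
  excluded_gene <- rep(FALSE, n)
  if (!is.null(exclusion)) {
    excluded_gene <- tab$chromosome == exclusion$chromosome &
      tab$start <= exclusion$end & tab$end >= exclusion$start
  }
  ok_start <- vapply(seq_len(n - window_size + 1L), function(i) {
    j <- i + window_size - 1L
    all(tab$usable[i:j]) && tab$chromosome[i] == tab$chromosome[j] &&
      !any(excluded_gene[i:j])
  }, logical(1))
  starts_pool <- which(ok_start)
  if (length(starts_pool) == 0L)
    stop_config("no valid window start positions")
  starts <- with_seed(seed,
    starts_pool[sample.int(length(starts_pool), n_windows, replace = TRUE)])
  dist_mat <- vapply(starts, function(i) tab$k81[i:(i + window_size - 1L)],
                     numeric(window_size))
  sat_mat <- vapply(starts, function(i)
    tab$saturated[i:(i + window_size - 1L)], logical(window_size))
  pooled <- as.numeric(dist_mat)[!as.logical(sat_mat)]
  window_means <- colMeans(ifelse(sat_mat, NA, dist_mat), na.rm = TRUE)
  structure(list(pooled = pooled, window_means = window_means,
                 starts = starts, window_size = window_size,
                 n_windows = n_windows, seed = seed,
                 n_saturated = sum(sat_mat), gene_table = tab),
            class = "permutation_null")
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact permutation enumeration of the U distribution (valid under ties)
#' when the number of group assignments is small; otherwise the normal
#' approximation with tie correction and continuity correction. Identical
#' samples give p = 1.
#'
#' @param x,y numeric samples.
#' @param exact `TRUE`, `FALSE`, or `NULL` to decide by enumeration size.
#' @return list with `U`, `p_value`, `method`.
#' @export
mann_whitney <- function(x, y, exact = NULL) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (n1 == 0L || n2 == 0L) stop_config("both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (is.null(exact)) exact <- choose(N, n1) <= 20000
  if (exact) {
    idx <- utils::combn(N, n1)
    us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
    return(list(U = U, p_value = p, method = "exact"))
  }
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) *
    ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p_value = 1, method = "normal"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(U = U, p_value = p, method = "normal")
}

#' Test the focal window against the random-window null
#'
#' Primary statistic: two-sided Mann-Whitney U comparing the focal window's
#' per-gene distances with the pooled null distances. Additionally reports
#' the empirical window-mean p-value
#' `(1 + #\{null window means <= focal mean\}) / (n_windows + 1)`.
#'
#' @param focal numeric vector of focal-window per-gene distances.
#' @param null `permutation_null` object (or list with `pooled`,
#'   `window_means`, `seed`, `window_size`, `n_windows`).
#' @return list of class `permutation_result`.
#' @export
window_significance <- function(focal, null) {
  if (length(focal) == 0L) stop_config("empty focal window")
  mw <- mann_whitney(focal, null$pooled, exact = FALSE)
  emp <- (1 + sum(null$window_means <= mean(focal))) /
    (length(null$window_means) + 1)
  structure(list(focal = focal, null = null$pooled,
                 window_means = null$window_means,
                 U = mw$U, p_value = mw$p_value, empirical_p = emp,
                 seed = null$seed, n_windows = null$n_windows,
                 window_size = null$window_size),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> focal n=%d (mean %.4g) vs %d windows of %d genes\n",
    length(x$focal), mean(x$focal), x$n_windows, x$window_size))
  cat(sprintf("  Mann-Whitney U = %.1f, two-sided p = %.3g; empirical window-mean p = %.3g\n",
              x$U, x$p_value, x$empirical_p))
  invisible(x)
}

#' Full haplotype-sharing analysis for one strain pair
#'
#' Computes the distance profile around the focal gene, delimits the shared
#' identical block, builds the random-window null excluding the focal region,
#' and tests the focal window (the focal gene plus its nearest shared
#' orthologs by rank, `window_size` genes in total) against it.
#'
#' @inheritParams random_window_null
#' @param focal focal ortholog ID.
#' @param flank profile half-width in gene ranks.
#' @return list with `profile`, `block`, `null`, `test`.
#' @export
haplotype_sharing_test <- function(genomeA, genomeB, orthologs, focal,
                                   window_size = 20L, n_windows = 1000L,
                                   seed = 1L, flank = 40L) {
  cache <- shared_ortholog_distances(genomeA, genomeB, orthologs)
  profile <- gene_profile(genomeA, genomeB, orthologs, focal, flank = flank)
  block <- shared_block(profile)
  shared <- profile[!is.na(profile$k81), , drop = FALSE]
  shared <- shared[order(abs(shared$rank), shared$rank), , drop = FALSE]
  focal_set <- utils::head(shared, window_size)
  if (nrow(focal_set) < window_size)
    stop_config("fewer than window_size shared orthologs around the focal gene")
  block_rows <- profile[profile$rank >= -block$left &
                          profile$rank <= block$right, , drop = FALSE]
  excl_rows <- rbind(focal_set[, c("chromosome", "start", "end")],
                     block_rows[, c("chromosome", "start", "end")])
  exclusion <- list(chromosome = excl_rows$chromosome[1L],
                    start = min(excl_rows$start), end = max(excl_rows$end))
  null <- random_window_null(genomeA, genomeB, orthologs,
                             window_size = window_size,
                             n_windows = n_windows, seed = seed,
                             exclusion = exclusion, cache = cache)
  test <- window_significance(focal_set$k81, null)
  list(profile = profile, block = block, null = null, test = test)
}
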