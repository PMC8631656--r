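## Sulfite-tolerance drop tests: parse growth-score tables, derive per-strain
## maximum tolerated MBS, and compare promoter classes.

DROPTEST_CLASSES <- c("ancestral", "VII^XVI", "XI^XVI")

#' Parse a drop-test growth table
#'
#' TSV with header `strain`, `class`, then one column per MBS concentration
#' (g/L, strictly increasing grid). Scores are integers 0-6: 0 = no growth at
#' any dilution, 6 = growth at the most dilute spot.
#'
#' @param path TSV path.
#' @return list of class `droptest_table` with `scores` (strains x
#'   concentrations matrix), `strain`, `class`, `grid`.
#' @export
parse_droptest <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!identical(names(tab)[1:2], c("strain", "class")))
    stop_format("drop-test table must start with 'strain' and 'class' columns")
  grid <- suppressWarnings(as.numeric(names(tab)[-(1:2)]))
  if (anyNA(grid) || length(grid) < 2L || any(diff(grid) <= 0))
    stop_format("concentration grid must be numeric and strictly increasing")
  bad_class <- setdiff(unique(tab$class), DROPTEST_CLASSES)
  if (length(bad_class) > 0L)
    stop_format("unknown promoter class label(s): %s",
                paste(bad_class, collapse = ", "))
  scores <- as.matrix(tab[, -(1:2), drop = FALSE])
  storage.mode(scores) <- "integer"
  if (anyNA(scores) || any(scores < 0L) || any(scores > 6L))
    stop_format("growth scores must be integers in 0..6")
  rownames(scores) <- tab$strain
  structure(list(scores = scores, strain = tab$strain, class = tab$class,
                 grid = grid),
            class = "droptest_table")
}

#' Write a drop-test table
#'
#' @param table `droptest_table`.
#' @param path output TSV path.
#' @export
write_droptest <- function(table, path) {
  out <- data.frame(strain = table$strain, class = table$class,
                    table$scores, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out)[-(1:2)] <- format(table$grid, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Maximum tolerated MBS concentration of one strain
#'
#' The highest grid concentration with a growth score of at least 1; `NA`
#' when nothing grew anywhere.
#'
#' @param scores integer vector of growth scores along the grid.
#' @param grid concentration grid (g/L).
#' @return concentration in g/L or `NA`.
#' @export
max_tolerated <- function(scores, grid) {
  grew <- which(scores >= 1L)
  if (length(grew) == 0L) return(NA_real_)
  grid[max(grew)]
}

#' Per-strain tolerance summary
#'
#' @param table `droptest_table`.
#' @return data.frame with `strain`, `class`, `max_mbs` (g/L).
#' @export
tolerance_summary <- function(table) {
  data.frame(strain = table$strain, class = table$class,
             max_mbs = apply(table$scores, 1L, max_tolerated,
                             grid = table$grid),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare maximum tolerated MBS between two promoter classes
#'
#' Two-sample t-test (Welch by default, pooled-variance Student optionally)
#' on the per-strain maximum tolerated concentrations. Strains with no growth
#' anywhere are excluded with a recorded count. A class with fewer than 2
#' strains yields descriptive statistics only (`t`, `df`, `p_value` = `NA`).
#'
#' @param table `droptest_table`.
#' @param classA,classB promoter class labels.
#' @param pooled use the pooled-variance Student t-test instead of Welch.
#' @return list with per-class `mean`, `sd`, `n`, the test statistics and
#'   `n_excluded`.
#' @export
class_comparison <- function(table, classA = "ancestral",
                             classB = "VII^XVI", pooled = FALSE) {
  per <- tolerance_summary(table)
  n_excluded <- sum(is.na(per$max_mbs))
  per <- per[!is.na(per$max_mbs), , drop = FALSE]
  a <- per$max_mbs[per$class == classA]
  b <- per$max_mbs[per$class == classB]
  out <- list(classA = classA, classB = classB,
              mean_A = mean(a), sd_A = stats::sd(a), n_A = length(a),
              mean_B = mean(b), sd_B = stats::sd(b), n_B = length(b),
              t = NA_real_, df = NA_real_, p_value = NA_real_,
              n_excluded = n_excluded)
  if (length(a) < 2L || length(b) < 2L) return(out)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    out$t <- if (eq) 0 else Inf
    out$p_value <- if (eq) 1 else 0
    return(out)
  }
  tt <- stats::t.test(a, b, var.equal = pooled)
  out$t <- unname(tt$statistic)
  out$df <- unname(tt$parameter)
  out$p_value <- tt$p.value
  out
}
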