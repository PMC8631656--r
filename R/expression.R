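## qPCR relative-expression quantification: standard-curve calibration,
## reference-gene normalisation and ratios to a calibrator strain.

#' Read a qPCR Ct table
#'
#' TSV with columns `strain`, `condition`, `hours`, `gene`, `replicate`,
#' `ct`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_qpcr_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("strain", "condition", "hours", "gene", "replicate", "ct")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L)
    stop_format("qPCR table lacks column(s): %s",
                paste(missing_cols, collapse = ", "))
  if (any(tab$ct <= 0)) stop_format("Ct values must be positive")
  tab
}

#' Read a standard-curve table
#'
#' TSV with columns `gene`, `dilution`, `ct`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_curve_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "dilution", "ct")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L)
    stop_format("standard-curve table lacks column(s): %s",
                paste(missing_cols, collapse = ", "))
  if (any(tab$dilution <= 0)) stop_format("dilution factors must be positive")
  tab
}

#' Fit a qPCR standard curve
#'
#' Least-squares fit of Ct against log10(dilution); the amplification
#' efficiency is `E = 10^(-1/slope)` (E = 2 for perfect doubling,
#' slope -3.3219). Curves with a non-negative slope or an efficiency outside
#' (1, 2.2] are flagged invalid.
#'
#' @param points data.frame with columns `dilution` and `ct` (>= 3 points,
#'   distinct dilutions).
#' @param gene optional gene label carried in the result.
#' @return list of class `standard_curve` with `slope`, `intercept`,
#'   `efficiency`, `r_squared`, `valid`.
#' @export
fit_standard_curve <- function(points, gene = NA_character_) {
  if (nrow(points) < 3L || length(unique(points$dilution)) < 3L)
    stop_format("standard curve needs at least 3 distinct dilution points")
  fit <- stats::lm(ct ~ log10(dilution), data = points)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  eff <- 10^(-1 / slope)
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((points$ct - mean(points$ct))^2)
  valid <- slope < 0 && eff > 1 && eff <= 2.2
  if (!valid)
    warning(sprintf("standard curve for %s flagged invalid (slope %.3f, E %.3f)",
                    gene, slope, eff))
  structure(list(gene = gene, slope = slope, intercept = intercept,
                 efficiency = eff, r_squared = r2, valid = valid),
            class = "standard_curve")
}

## Ideal curve assumed when no dilution series is available: E = 2
## (slope -1/log10(2)), warning emitted by the caller.
default_curve <- function(gene) {
  structure(list(gene = gene, slope = -1 / log10(2), intercept = 20,
                 efficiency = 2, r_squared = NA_real_, valid = TRUE),
            class = "standard_curve")
}

#' Relative quantity from a Ct value
#'
#' `quantity = 10^((ct - intercept) / slope)`; monotone decreasing in Ct for
#' a valid (negative-slope) curve.
#'
#' @param ct quantification cycle(s).
#' @param curve `standard_curve`.
#' @return numeric quantity (same units as the curve's dilution scale).
#' @export
quantify <- function(ct, curve) {
  if (!inherits(curve, "standard_curve") || !isTRUE(curve$valid))
    stop_config("invalid standard curve")
  10^((ct - curve$intercept) / curve$slope)
}

#' Normalise qPCR expression and relativise to a calibrator strain
#'
#' Per replicate, the normalised value is the target quantity divided by the
#' average of the two reference-gene quantities (arithmetic by default,
#' geometric optionally). Per (strain, condition, timepoint) cell the
#' replicate mean and sd are reported, and the ratio is the cell mean divided
#' by the calibrator strain's cell mean at the same (condition, timepoint).
#' Cells missing a reference measurement are flagged and excluded.
#'
#' @param dataset Ct table (see [read_qpcr_table()]).
#' @param curves named list of `standard_curve` objects, one per gene; genes
#'   without a curve assume perfect doubling (E = 2) with a warning.
#' @param calibrator calibrator strain ID (its ratio is 1 by construction).
#' @param target target gene name.
#' @param references character vector of the two reference genes.
#' @param ref_average `"arithmetic"` (default) or `"geometric"`.
#' @return data.frame of class `relative_expression` with one row per cell:
#'   `strain`, `condition`, `hours`, `normalized`, `sd`, `n`, `ratio`,
#'   `flagged`.
#' @export
normalize_expression <- function(dataset, curves = NULL, calibrator,
                                 target = "SSU1",
                                 references = c("ACT1", "RDN18"),
                                 ref_average = c("arithmetic", "geometric")) {
  ref_average <- match.arg(ref_average)
  genes <- c(target, references)
  if (is.null(curves)) curves <- list()
  for (g in genes) {
    if (is.null(curves[[g]])) {
      warning(sprintf("no standard curve for %s; assuming efficiency 2", g))
      curves[[g]] <- default_curve(g)
    }
  }
  if (!calibrator %in% dataset$strain)
    stop_lookup("calibrator strain %s absent from dataset", calibrator)
  dataset <- dataset[dataset$gene %in% genes, , drop = FALSE]
  dataset$quantity <- NA_real_
  for (g in genes) {
    sel <- dataset$gene == g
    dataset$quantity[sel] <- quantify(dataset$ct[sel], curves[[g]])
  }
  cells <- unique(dataset[, c("strain", "condition", "hours")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    sub <- dataset[dataset$strain == cell$strain &
                     dataset$condition == cell$condition &
                     dataset$hours == cell$hours, , drop = FALSE]
    reps <- sort(unique(sub$replicate))
    norm <- vapply(reps, function(r) {
      qt <- sub$quantity[sub$gene == target & sub$replicate == r]
      qr <- vapply(references, function(g)
        mean(sub$quantity[sub$gene == g & sub$replicate == r]), numeric(1))
      if (length(qt) != 1L || anyNA(qr)) return(NA_real_)
      denom <- if (ref_average == "arithmetic") mean(qr)
               else exp(mean(log(qr)))
      qt / denom
    }, numeric(1))
    norm <- norm[!is.na(norm)]
    data.frame(strain = cell$strain, condition = cell$condition,
               hours = cell$hours,
               normalized = if (length(norm) > 0L) mean(norm) else NA_real_,
               sd = if (length(norm) > 1L) stats::sd(norm) else NA_real_,
               n = length(norm), flagged = length(norm) == 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$ratio <- NA_real_
  for (i in seq_len(nrow(out))) {
    cal <- out[out$strain == calibrator & out$condition == out$condition[i] &
                 out$hours == out$hours[i], , drop = FALSE]
    if (nrow(cal) == 1L && !cal$flagged && !out$flagged[i])
      out$ratio[i] <- out$normalized[i] / cal$normalized
  }
  attr(out, "calibrator") <- calibrator
  attr(out, "target") <- target
  class(out) <- c("relative_expression", "data.frame")
  out
}

#' Welch two-sample comparison of normalised expression values
#'
#' Welch t-test with Welch-Satterthwaite degrees of freedom. When both groups
#' have zero variance: p = 1 if the means are equal, 0 otherwise.
#'
#' @param groupA,groupB numeric vectors of replicate normalised values
#'   (length >= 2 each).
#' @return list with `t`, `df`, `p_value`, `mean_A`, `mean_B`.
#' @export
compare_expression <- function(groupA, groupB) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop_config("each group needs at least 2 replicates")
  if (stats::sd(groupA) == 0 && stats::sd(groupB) == 0) {
    eq <- isTRUE(all.equal(mean(groupA), mean(groupB)))
    return(list(t = if (eq) 0 else Inf, df = NA_real_,
                p_value = if (eq) 1 else 0,
                mean_A = mean(groupA), mean_B = mean(groupB)))
  }
  tt <- stats::t.test(groupA, groupB, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_A = mean(groupA), mean_B = mean(groupB))
}

#' Write a relative-expression table and test results
#'
#' @param expr `relative_expression` data.frame.
#' @param tsv,json output paths (either may be `NULL`).
#' @param tests optional list of test results for the JSON report.
#' @export
write_expression <- function(expr, tsv = NULL, json = NULL, tests = NULL) {
  if (!is.null(tsv))
    utils::write.table(expr, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  if (!is.null(json))
    jsonlite::write_json(list(calibrator = attr(expr, "calibrator"),
                              target = attr(expr, "target"),
                              cells = expr, tests = tests),
                         json, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(expr)
}
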