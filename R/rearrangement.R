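## Promoter-rearrangement scan: classify each strain's focal-gene promoter
## configuration against a reference gene neighbourhood, localise the
## translocation junction to base-pair resolution, delimit junction
## microhomology, and score retention of a TF-binding motif.

#' Extract the gene neighbourhood of a focal ortholog
#'
#' Upstream/downstream are defined on the focal gene's coding strand.
#' The intergenic distance is the end-to-start gap (bp strictly between the
#' previous gene's nearest end and the focal gene start); the start-to-start
#' distance uses strand-aware gene starts. Overlapping genes give a gap of 0
#' with a warning.
#'
#' @param genome `annotated_genome`.
#' @param focal ortholog ID of the focal gene.
#' @param k number of flanking genes to report on each side.
#' @return list of class `gene_neighborhood`.
#' @export
extract_neighborhood <- function(genome, focal, k = 5L) {
  fg <- find_ortholog_gene(genome, focal)
  chr_genes <- genome$genes[genome$genes$chromosome == fg$chromosome, ,
                            drop = FALSE]
  chr_genes <- chr_genes[order(chr_genes$start), , drop = FALSE]
  idx <- which(chr_genes$gene_id == fg$gene_id)
  if (fg$strand == "+") {
    up <- chr_genes[rev(seq_len(idx - 1L)), , drop = FALSE]        # nearest first
    down <- chr_genes[seq(idx + 1L, length.out = nrow(chr_genes) - idx), ,
                      drop = FALSE]
  } else {
    up <- chr_genes[seq(idx + 1L, length.out = nrow(chr_genes) - idx), ,
                    drop = FALSE]
    down <- chr_genes[rev(seq_len(idx - 1L)), , drop = FALSE]
  }
  up <- utils::head(up, k); down <- utils::head(down, k)
  intergenic <- NA_integer_; s2s <- NA_integer_
  if (nrow(up) > 0L) {
    prev <- up[1L, , drop = FALSE]
    gap <- if (fg$strand == "+") fg$start - prev$end - 1L
           else prev$start - fg$end - 1L
    if (gap < 0L) {
      warning(sprintf("focal gene overlaps its upstream neighbour in %s; gap set to 0",
                      genome$strain_id))
      gap <- 0L
    }
    intergenic <- gap
    s2s <- abs(gene_start_coord(fg) - gene_start_coord(prev))
  }
  structure(list(strain_id = genome$strain_id,
                 focal_ortholog = focal,
                 focal_gene = fg,
                 upstream = up,
                 downstream = down,
                 intergenic_bp = intergenic,
                 start_to_start_bp = s2s),
            class = "gene_neighborhood")
}

#' Classify a promoter configuration against a reference neighbourhood
#'
#' The call is `ancestral` iff the nearest upstream ortholog equals the
#' reference's nearest upstream ortholog; otherwise `translocated`, with the
#' partner chromosome taken from the reference location of the observed
#' upstream ortholog (or `"unknown"` when it is absent from the reference).
#'
#' @param neighborhood,reference_neighborhood `gene_neighborhood` objects
#'   sharing the focal ortholog.
#' @param reference optional reference `annotated_genome`, used to look up the
#'   partner chromosome.
#' @return list with `variant_class`, `partner_chromosome`,
#'   `upstream_ortholog`.
#' @export
classify_promoter <- function(neighborhood, reference_neighborhood,
                              reference = NULL) {
  if (!identical(neighborhood$focal_ortholog,
                 reference_neighborhood$focal_ortholog))
    stop_lookup("neighbourhoods refer to different focal orthologs")
  obs_up <- if (nrow(neighborhood$upstream) > 0L)
    neighborhood$upstream$ortholog_id[1L] else NA_character_
  ref_up <- if (nrow(reference_neighborhood$upstream) > 0L)
    reference_neighborhood$upstream$ortholog_id[1L] else NA_character_
  if (identical(obs_up, ref_up)) {
    return(list(variant_class = "ancestral", partner_chromosome = NA_character_,
                upstream_ortholog = obs_up))
  }
  partner <- "unknown"
  if (!is.null(reference) && !is.na(obs_up)) {
    hit <- find_ortholog_gene(reference, obs_up, required = FALSE)
    if (!is.null(hit)) partner <- hit$chromosome
  }
  list(variant_class = "translocated", partner_chromosome = partner,
       upstream_ortholog = obs_up)
}

## Promoter window: up to W bp immediately 5' of the strand-aware gene start,
## returned in coding orientation with the gene-proximal base last.
upstream_window <- function(genome, gene, W) {
  chr <- genome$chromosomes[[gene$chromosome]]
  if (gene$strand == "+") {
    lo <- max(1L, gene$start - W)
    substr(chr, lo, gene$start - 1L)
  } else {
    hi <- min(nchar(chr), gene$end + W)
    revcomp(substr(chr, gene$end + 1L, hi))
  }
}

## Seed-and-extend anchoring: find a unique exact seed of `seed_len` bp from
## one end of the recombinant window inside `parent`, stepping further into
## the window until a unique hit is found. Returns the offset delta such that
## parent[i + delta] aligns with window[i], or NULL.
anchor_offset <- function(window, parent_dna, from = c("proximal", "distal"),
                          seed_len = 20L, max_tries = 50L) {
  from <- match.arg(from)
  W <- nchar(window)
  for (t in seq_len(max_tries) - 1L) {
    stt <- if (from == "proximal") W - seed_len + 1L - t * seed_len
           else 1L + t * seed_len
    if (stt < 1L || stt + seed_len - 1L > W) break
    seed <- substr(window, stt, stt + seed_len - 1L)
    if (grepl("N", seed, fixed = TRUE)) next
    hits <- Biostrings::matchPattern(seed, parent_dna)
    if (length(hits) == 1L) return(Biostrings::start(hits)[1L] - stt)
  }
  NULL
}

#' Localise a translocation breakpoint and its junction microhomology
#'
#' Anchors the gene-proximal end of the recombinant promoter window on the
#' ancestral focal chromosome (`parentA`) and the distal end on the partner
#' chromosome (`parentB`) by exact 20-bp seeds, scores per-base agreement with
#' each parent, and places the junction at the changepoint that maximises
#' (distal bases explained by B) + (proximal bases explained by A).
#' The ambiguity interval is the maximal junction-spanning interval within
#' which both parents match the recombinant exactly (the junction
#' microhomology), widened to include any single-site conflict immediately at
#' the changepoint; the breakpoint offset is its focal-proximal edge, in bp
#' upstream of the strand-aware gene start.
#'
#' @param rec_window recombinant promoter window in coding orientation, the
#'   gene-proximal base last (see `upstream_window`).
#' @param parentA ancestral focal-chromosome sequence, coding orientation.
#' @param parentB partner-chromosome sequence (either orientation; both are
#'   tried).
#' @param seed_len exact-seed length for anchoring.
#' @return list with `status` (`resolved`, `unresolved` or `complex`),
#'   `breakpoint_offset`, `ambiguity_interval`, `microhomology_seq`,
#'   `microhomology_len`, `parentB_orientation`.
#' @export
locate_breakpoint <- function(rec_window, parentA, parentB, seed_len = 20L) {
  W <- nchar(rec_window)
  unresolved <- list(status = "unresolved", breakpoint_offset = NA_integer_,
                     ambiguity_interval = c(NA_integer_, NA_integer_),
                     microhomology_seq = NA_character_,
                     microhomology_len = NA_integer_,
                     parentB_orientation = NA_character_)
  if (W < 2L * seed_len) return(unresolved)
  dA <- anchor_offset(rec_window, Biostrings::DNAString(parentA), "proximal",
                      seed_len)
  if (is.null(dA)) return(unresolved)
  orientation <- "forward"
  pB <- parentB
  dB <- anchor_offset(rec_window, Biostrings::DNAString(pB), "distal", seed_len)
  if (is.null(dB)) {
    pB <- revcomp(parentB)
    dB <- anchor_offset(rec_window, Biostrings::DNAString(pB), "distal",
                        seed_len)
    orientation <- "reverse"
  }
  if (is.null(dB)) return(unresolved)

  recv <- seq_to_int(rec_window)
  pav <- seq_to_int(parentA)
  pbv <- seq_to_int(pB)
  idxA <- seq_len(W) + dA
  idxB <- seq_len(W) + dB
  okA <- idxA >= 1L & idxA <= length(pav)
  okB <- idxB >= 1L & idxB <= length(pbv)
  matchA <- okA & !is.na(recv) & recv == ifelse(okA, pav[pmax(idxA, 1L)], NA)
  matchB <- okB & !is.na(recv) & recv == ifelse(okB, pbv[pmax(idxB, 1L)], NA)
  matchA[is.na(matchA)] <- FALSE
  matchB[is.na(matchB)] <- FALSE

  cumA <- c(0L, cumsum(matchA))
  cumB <- c(0L, cumsum(matchB))
  fc <- cumB + cumA[W + 1L] - cumA            # objective at c = 0..W
  chat <- max(which(fc == max(fc))) - 1L
  if (chat == 0L) return(unresolved)

  ## mismatch-rate sanity on each side (over positions the parents cover)
  b_side <- which(okB & seq_len(W) <= chat)
  a_side <- which(okA & seq_len(W) > chat)
  rateB <- if (length(b_side) > 0L) 1 - mean(matchB[b_side]) else 1
  rateA <- if (length(a_side) > 0L) 1 - mean(matchA[a_side]) else 1
  if (rateB > 0.10 || rateA > 0.10) {
    out <- unresolved; out$status <- "complex"; return(out)
  }

  ## maximal exact tripartite (both-parent) run adjacent to the changepoint
  both <- matchA & matchB
  r <- rle(both)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ## a run is junction-relevant if it covers the changepoint (or abuts it on
  ## the proximal side); a run ending just distal of the changepoint is only
  ## trusted when long enough (>= 4 bp) not to be a chance match, covering
  ## the case where a point substitution at the first parent-A base mimics a
  ## shifted junction
  sel <- which(r$values &
                 ((starts <= chat + 1L & ends >= chat) |
                    (ends == chat - 1L & r$lengths >= 4L) |
                    (starts == chat + 2L & r$lengths >= 4L)))
  if (length(sel) > 0L) {
    c_run <- c(min(starts[sel]) - 1L, max(ends[sel]))
  } else {
    c_run <- c(chat, chat)
  }
  ## discriminating-site bounds: the junction cannot lie proximal of an
  ## A-only-matching base nor distal of a B-only-matching base
  bvote <- which(matchB & !matchA & seq_len(W) <= chat)
  avote <- which(matchA & !matchB & seq_len(W) > chat)
  c_vote <- c(if (length(bvote) > 0L) max(bvote) else c_run[1L],
              if (length(avote) > 0L) min(avote) - 1L else c_run[2L])
  if (c_vote[1L] > c_vote[2L]) c_vote <- c(chat, chat)
  cmin <- min(c_run[1L], c_vote[1L])
  cmax <- max(c_run[2L], c_vote[2L])

  lo <- W - cmax
  hi <- W - cmin
  mh <- if (cmax > cmin) substr(rec_window, cmin + 1L, cmax) else ""
  list(status = "resolved",
       breakpoint_offset = lo,
       ambiguity_interval = c(lo, hi),
       microhomology_seq = mh,
       microhomology_len = hi - lo,
       parentB_orientation = orientation)
}

#' Scan a promoter window for a TF-binding motif and score its retention
#'
#' Exact IUPAC matching on both strands (unless `both_strands = FALSE`).
#' Positions are reported as bp upstream of the focal gene start (distance of
#' the match's gene-proximal edge). With no match the status is `absent`;
#' with no breakpoint (ancestral configuration) a present motif is
#' `retained`; for a translocated promoter the motif is `lost` when its
#' nearest ancestral match lies farther from the gene start than the
#' breakpoint offset, i.e. on the replaced side of the junction.
#'
#' @param window ancestral promoter window in coding orientation (proximal
#'   base last).
#' @param motif IUPAC nucleotide string, length >= 4.
#' @param breakpoint_offset bp upstream of the gene start, or `NULL`/`NA` for
#'   an ancestral configuration.
#' @param both_strands search the reverse complement too.
#' @return list with `motif_status` and sorted `positions` (bp upstream).
#' @export
motif_retention <- function(window, motif, breakpoint_offset = NULL,
                            both_strands = TRUE) {
  if (nchar(motif) < 4L) stop_config("motif must be at least 4 bp")
  if (nchar(window) < nchar(motif))
    stop_config("window shorter than the motif")
  w <- Biostrings::DNAString(window)
  pat <- Biostrings::DNAString(motif)
  hits <- Biostrings::matchPattern(pat, w, fixed = FALSE)
  ends <- Biostrings::end(hits)
  if (both_strands) {
    rhits <- Biostrings::matchPattern(Biostrings::reverseComplement(pat), w,
                                      fixed = FALSE)
    ends <- c(ends, Biostrings::end(rhits))
  }
  W <- nchar(window)
  positions <- sort(unique(W - ends + 1L))
  if (length(positions) == 0L)
    return(list(motif_status = "absent", positions = integer(0)))
  if (is.null(breakpoint_offset) || is.na(breakpoint_offset))
    return(list(motif_status = "retained", positions = positions))
  status <- if (min(positions) > breakpoint_offset) "lost" else "retained"
  list(motif_status = status, positions = positions)
}

#' Scan a strain collection for focal-promoter rearrangements
#'
#' Runs neighbourhood extraction, promoter classification, breakpoint and
#' microhomology localisation, and motif-retention scoring for every strain,
#' and tabulates counts per (variant class, partner chromosome). Strains
#' lacking the focal ortholog are reported as `uncallable` and excluded from
#' the counts.
#'
#' @param genomes list of `annotated_genome` objects.
#' @param reference reference `annotated_genome` (ancestral configuration).
#' @param focal focal ortholog ID.
#' @param motif IUPAC motif scanned in the ancestral promoter (default the
#'   Fzf1p binding site `CTATCA`).
#' @param k flanking genes per side in neighbourhoods.
#' @param W promoter window width in bp.
#' @return list of class `rearrangement_scan` with `calls` (one row per
#'   strain) and `summary` (counts per class/partner).
#' @export
scan_collection <- function(genomes, reference, focal, motif = "CTATCA",
                            k = 5L, W = 5000L) {
  ref_nb <- extract_neighborhood(reference, focal, k)
  ref_window <- upstream_window(reference, ref_nb$focal_gene, W)
  parentA <- reference$chromosomes[[ref_nb$focal_gene$chromosome]]
  if (ref_nb$focal_gene$strand == "-") parentA <- revcomp(parentA)

  rows <- lapply(genomes, function(g) {
    base <- data.frame(strain = g$strain_id, variant_class = "uncallable",
                       partner_chromosome = NA_character_,
                       upstream_ortholog = NA_character_,
                       intergenic_bp = NA_integer_,
                       start_to_start_bp = NA_integer_,
                       breakpoint_offset = NA_integer_,
                       ambiguity_lo = NA_integer_, ambiguity_hi = NA_integer_,
                       microhomology_len = NA_integer_,
                       microhomology_seq = NA_character_,
                       motif_status = NA_character_,
                       breakpoint_status = NA_character_,
                       stringsAsFactors = FALSE)
    fg <- find_ortholog_gene(g, focal, required = FALSE)
    if (is.null(fg)) return(base)
    nb <- extract_neighborhood(g, focal, k)
    cl <- classify_promoter(nb, ref_nb, reference)
    base$variant_class <- cl$variant_class
    base$partner_chromosome <- cl$partner_chromosome
    base$upstream_ortholog <- cl$upstream_ortholog
    base$intergenic_bp <- nb$intergenic_bp
    base$start_to_start_bp <- nb$start_to_start_bp
    if (cl$variant_class == "ancestral") {
      base$motif_status <- motif_retention(ref_window, motif, NULL)$motif_status
      return(base)
    }
    rec <- upstream_window(g, nb$focal_gene, W)
    candidates <- if (!identical(cl$partner_chromosome, "unknown"))
      cl$partner_chromosome else names(reference$chromosomes)
    bp <- list(status = "unresolved")
    for (chrom in candidates) {
      bp <- locate_breakpoint(rec, parentA, reference$chromosomes[[chrom]])
      if (bp$status == "resolved") {
        if (identical(cl$partner_chromosome, "unknown"))
          base$partner_chromosome <- chrom
        break
      }
    }
    base$breakpoint_status <- bp$status
    if (bp$status == "resolved") {
      base$breakpoint_offset <- bp$breakpoint_offset
      base$ambiguity_lo <- bp$ambiguity_interval[1L]
      base$ambiguity_hi <- bp$ambiguity_interval[2L]
      base$microhomology_len <- bp$microhomology_len
      base$microhomology_seq <- bp$microhomology_seq
      base$motif_status <- motif_retention(ref_window, motif,
                                           bp$breakpoint_offset)$motif_status
    }
    base
  })
  calls <- do.call(rbind, rows)
  rownames(calls) <- NULL
  callable <- calls[calls$variant_class != "uncallable", , drop = FALSE]
  grp <- ifelse(callable$variant_class == "ancestral", "ancestral",
                paste0("translocated:",
                       ifelse(is.na(callable$partner_chromosome), "unknown",
                              callable$partner_chromosome)))
  summary <- as.data.frame(table(group = grp), stringsAsFactors = FALSE)
  names(summary) <- c("group", "n")
  structure(list(calls = calls, summary = summary, focal = focal,
                 motif = motif),
            class = "rearrangement_scan")
}

#' @export
print.rearrangement_scan <- function(x, ...) {
  cat(sprintf("<rearrangement_scan> focal ortholog %s, %d strain(s)\n",
              x$focal, nrow(x$calls)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write rearrangement calls to TSV and JSON
#'
#' @param scan `rearrangement_scan` object.
#' @param tsv,json output paths (either may be `NULL`).
#' @export
write_scan <- function(scan, tsv = NULL, json = NULL) {
  if (!is.null(tsv))
    utils::write.table(scan$calls, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  if (!is.null(json))
    jsonlite::write_json(list(focal = scan$focal, motif = scan$motif,
                              summary = scan$summary, calls = scan$calls),
                         json, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(scan)
}
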