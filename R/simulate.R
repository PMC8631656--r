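## Synthetic-genome generator with planted ground truth. Every generator is a
## pure function of (configuration, seed); regenerating with the same inputs
## gives byte-identical output. The generator emulates the study design the
## pipeline analyses: multi-chromosome genomes of uniformly spaced orthologous
## genes, a reciprocal translocation planted a configurable distance upstream
## of the focal gene with k-bp junction microhomology, K81 sequence
## divergence between strains, an identical-by-state gene block shared by two
## strains, noisy qPCR Ct tables and ordinal drop-test scores.

#' Simulate an ancestral reference genome
#'
#' Chromosomes carry `genes_per_chromosome` genes of `gene_length` bp
#' separated by `intergenic_length` bp of uniform-composition random
#' sequence, all on the + strand; every gene receives a sequential ortholog
#' ID. Accidental occurrences of the configured motif in the focal upstream
#' window are scrubbed and a single motif copy is planted `motif_offset` bp
#' upstream of the focal gene start, so motif-retention truth is
#' deterministic.
#'
#' @param seed integer seed.
#' @param chromosomes named integer vector: genes per chromosome.
#' @param gene_length,intergenic_length sizes in bp.
#' @param focal list(chromosome, index): which gene is the focal gene.
#' @param motif IUPAC motif planted upstream of the focal gene (`NULL` to
#'   skip planting).
#' @param motif_offset bp upstream of the focal gene start for the planted
#'   motif's proximal edge.
#' @param strain_id strain label of the ancestor.
#' @return `annotated_genome`.
#' @export
simulate_reference <- function(seed = 1L,
                               chromosomes = c(chrVII = 80L, chrXI = 80L,
                                               chrXVI = 80L),
                               gene_length = 1000L,
                               intergenic_length = 1000L,
                               focal = list(chromosome = "chrXVI",
                                            index = 40L),
                               motif = "CTATCA",
                               motif_offset = 500L,
                               strain_id = "ANC") {
  if (any(chromosomes < 1L)) stop_config("each chromosome needs >= 1 gene")
  if (!focal$chromosome %in% names(chromosomes))
    stop_config("focal chromosome %s not configured", focal$chromosome)
  with_seed(seed, {
    og <- 0L
    seqs <- list(); genes <- list()
    for (chrom in names(chromosomes)) {
      n <- chromosomes[[chrom]]
      len <- n * (gene_length + intergenic_length) + intergenic_length
      seqs[[chrom]] <- random_seq(len)
      starts <- intergenic_length + (seq_len(n) - 1L) *
        (gene_length + intergenic_length) + 1L
      ids <- sprintf("OG%04d", og + seq_len(n))
      og <- og + n
      genes[[chrom]] <- data.frame(
        gene_id = paste0(strain_id, "_", ids), ortholog_id = ids,
        chromosome = chrom, start = starts, end = starts + gene_length - 1L,
        strand = "+", stringsAsFactors = FALSE)
    }
    gtab <- do.call(rbind, genes)
    if (!is.null(motif)) {
      fg <- gtab[gtab$chromosome == focal$chromosome, ][focal$index, ]
      if (motif_offset + nchar(motif) >= intergenic_length)
        stop_config("motif_offset too large for the intergenic spacing")
      seqs[[focal$chromosome]] <- plant_motif(seqs[[focal$chromosome]],
                                              fg$start, motif, motif_offset)
    }
    annotated_genome(strain_id, seqs, gtab)
  })
}

## Scrub chance motif hits from the focal upstream window (within 5 kb) and
## plant one copy with its proximal edge motif_offset bp upstream of the
## gene start at position `gene_start`.
plant_motif <- function(chrom_seq, gene_start, motif, motif_offset,
                        window = 5000L) {
  m <- nchar(motif)
  lo <- max(1L, gene_start - window)
  target <- gene_start - motif_offset - m + 1L  # motif occupies target..target+m-1
  substr(chrom_seq, target, target + m - 1L) <- motif
  pats <- c(motif, revcomp(motif))
  for (iter in 1:50) {
    win <- substr(chrom_seq, lo, gene_start - 1L)
    hits <- unlist(lapply(pats, function(p) {
      s <- Biostrings::start(Biostrings::matchPattern(
        Biostrings::DNAString(p), Biostrings::DNAString(win), fixed = FALSE))
      s + lo - 1L
    }))
    extra <- setdiff(hits, target)
    if (length(extra) == 0L) break
    ## mutate one base of the first chance hit, outside the planted copy
    p <- extra[1L]
    cand <- setdiff(seq(p, p + m - 1L), seq(target, target + m - 1L))
    pos <- cand[ceiling(length(cand) / 2)]
    old <- substr(chrom_seq, pos, pos)
    substr(chrom_seq, pos, pos) <- BASES[(match(old, BASES) %% 4L) + 1L]
  }
  chrom_seq
}

#' Apply a reciprocal translocation upstream of the focal gene
#'
#' Plants an identical `microhomology_len`-bp sequence immediately 5' of both
#' parental breakpoints (forcing the flanking bases to differ between the
#' parents, so the junction ambiguity is exactly `microhomology_len` bp at
#' zero divergence), then swaps the distal chromosome arms reciprocally and
#' remaps all gene annotations. Total base content is conserved. Returns the
#' (possibly microhomology-edited) parental genome alongside the derived one,
#' plus the ground-truth record.
#'
#' @param genome parental `annotated_genome` (focal gene on the + strand).
#' @param focal focal ortholog ID.
#' @param partner_chromosome chromosome exchanged with the focal chromosome.
#' @param offset breakpoint position, bp upstream of the focal gene start
#'   (must fall in the upstream intergenic region).
#' @param microhomology_len junction microhomology length in bp.
#' @param partner_gene_index the partner breakpoint falls in the intergenic
#'   gap after this gene (by position) on the partner chromosome.
#' @param derived_strain_id strain label of the derived genome.
#' @param seed seed for the planted microhomology sequence.
#' @return list with `reference`, `derived`, `truth`.
#' @export
apply_translocation <- function(genome, focal, partner_chromosome,
                                offset = 339L, microhomology_len = 8L,
                                partner_gene_index = NULL,
                                derived_strain_id = "DERIVED", seed = 0L) {
  if (!is.null(attr(genome, "translocated")))
    stop_config("genome already carries a translocation at the focal junction")
  fg <- find_ortholog_gene(genome, focal)
  if (fg$strand != "+")
    stop_config("generator requires the focal gene on the + strand")
  fchr <- fg$chromosome
  if (identical(fchr, partner_chromosome))
    stop_config("partner chromosome must differ from the focal chromosome")
  k <- microhomology_len
  s <- fg$start
  Fseq <- genome$chromosomes[[fchr]]
  Pseq <- genome$chromosomes[[partner_chromosome]]
  ## junction and microhomology must sit in the focal upstream intergenic gap
  fchr_genes <- genome$genes[genome$genes$chromosome == fchr, , drop = FALSE]
  prev_end <- suppressWarnings(max(fchr_genes$end[fchr_genes$end < s]))
  if (!is.finite(prev_end)) prev_end <- 0L
  if (s - offset - k - 2L <= prev_end)
    stop_config("breakpoint offset %d (+%d bp microhomology) falls inside or against a gene",
                offset, k)
  p_genes <- genome$genes[genome$genes$chromosome == partner_chromosome, ,
                          drop = FALSE]
  p_genes <- p_genes[order(p_genes$start), , drop = FALSE]
  if (is.null(partner_gene_index))
    partner_gene_index <- floor(nrow(p_genes) / 2)
  if (partner_gene_index < 1L || partner_gene_index >= nrow(p_genes))
    stop_config("partner_gene_index out of range")
  e_p <- p_genes$end[partner_gene_index]
  s_n <- p_genes$start[partner_gene_index + 1L]
  q <- as.integer(floor((e_p + s_n) / 2))
  if (q - k - 1L <= e_p || q + 2L >= s_n)
    stop_config("partner intergenic gap too small for the microhomology")

  mh <- if (k > 0L) with_seed(seed, random_seq(k)) else ""
  if (k > 0L) {
    substr(Fseq, s - offset - k, s - offset - 1L) <- mh
    substr(Pseq, q - k + 1L, q) <- mh
  }
  ## force the bases flanking the microhomology to differ between parents, so
  ## the planted junction ambiguity is maximal by construction
  fix_flank <- function(a, b) if (a == b) BASES[(match(a, BASES) %% 4L) + 1L]
                              else b
  substr(Pseq, q + 1L, q + 1L) <-
    fix_flank(substr(Fseq, s - offset, s - offset), substr(Pseq, q + 1L, q + 1L))
  substr(Pseq, q - k, q - k) <-
    fix_flank(substr(Fseq, s - offset - k - 1L, s - offset - k - 1L),
              substr(Pseq, q - k, q - k))

  reference <- genome
  reference$chromosomes[[fchr]] <- Fseq
  reference$chromosomes[[partner_chromosome]] <- Pseq

  ## reciprocal swap of the distal arms
  cut_f <- s - offset - 1L   # F[1..cut_f] is distal, F[cut_f+1..] proximal
  new_F <- paste0(substr(Pseq, 1L, q), substr(Fseq, cut_f + 1L, nchar(Fseq)))
  new_P <- paste0(substr(Fseq, 1L, cut_f), substr(Pseq, q + 1L, nchar(Pseq)))

  genes <- reference$genes
  on_f <- genes$chromosome == fchr
  on_p <- genes$chromosome == partner_chromosome
  if (any(on_f & genes$start <= cut_f & genes$end > cut_f) ||
      any(on_p & genes$start <= q & genes$end > q))
    stop_config("a breakpoint falls inside a gene")
  move_fp <- on_f & genes$end <= cut_f       # focal-chromosome distal arm
  keep_f <- on_f & genes$start > cut_f
  move_pf <- on_p & genes$end <= q           # partner distal arm
  keep_p <- on_p & genes$start > q
  genes$chromosome[move_fp] <- partner_chromosome
  genes$chromosome[move_pf] <- fchr
  shift_f <- q - cut_f
  genes$start[keep_f] <- genes$start[keep_f] + shift_f
  genes$end[keep_f] <- genes$end[keep_f] + shift_f
  genes$start[keep_p] <- genes$start[keep_p] - shift_f
  genes$end[keep_p] <- genes$end[keep_p] - shift_f

  chroms <- reference$chromosomes
  chroms[[fchr]] <- new_F
  chroms[[partner_chromosome]] <- new_P
  genes$gene_id <- ifelse(is.na(genes$ortholog_id), genes$gene_id,
                          paste0(derived_strain_id, "_", genes$ortholog_id))
  derived <- annotated_genome(derived_strain_id, chroms, genes)
  upstream_og <- p_genes$ortholog_id[partner_gene_index]
  truth <- list(partner_chromosome = partner_chromosome, offset = offset,
                microhomology_len = k, microhomology_seq = mh,
                upstream_ortholog = upstream_og, focal = focal)
  attr(derived, "translocated") <- truth
  list(reference = reference, derived = derived, truth = truth)
}

#' Evolve a genome under the K81 substitution model
#'
#' Per-site independent substitutions with expected `branch_length`
#' substitutions/site, partitioned into the three K81 classes (transitions,
#' A/T-G/C transversions, A/C-G/T transversions) according to
#' `rate_fractions`. Uses the exact finite-time K81 transition probabilities,
#' so multiple hits are modelled and the K81 distance estimator recovers
#' `branch_length` consistently. N sites are left untouched. Deterministic
#' given `seed`.
#'
#' @param genome `annotated_genome`.
#' @param branch_length expected substitutions per site (>= 0).
#' @param rate_fractions length-3 non-negative weights for the three
#'   substitution classes (normalised to sum 1).
#' @param seed integer seed.
#' @param strain_id label of the evolved strain.
#' @return `annotated_genome`.
#' @export
evolve_k81 <- function(genome, branch_length, rate_fractions = rep(1, 3) / 3,
                       seed, strain_id = genome$strain_id) {
  if (branch_length < 0) stop_config("branch length must be >= 0")
  if (length(rate_fractions) != 3L || any(rate_fractions < 0) ||
      sum(rate_fractions) <= 0)
    stop_config("rate_fractions must be 3 non-negative weights")
  fr <- rate_fractions / sum(rate_fractions)
  a <- fr[1L] * branch_length
  b <- fr[2L] * branch_length
  cc <- fr[3L] * branch_length
  e10 <- exp(-2 * (a + cc)); e01 <- exp(-2 * (b + cc)); e11 <- exp(-2 * (a + b))
  p_ts <- (1 - e10 + e01 - e11) / 4
  p_q <- (1 + e10 - e01 - e11) / 4
  p_r <- (1 - e10 - e01 + e11) / 4
  probs <- c(1 - p_ts - p_q - p_r, p_ts, p_q, p_r)
  ## displacement table: rows = origin base, cols = event class
  MUT <- matrix(c(1L, 3L, 4L, 2L,
                  2L, 4L, 3L, 1L,
                  3L, 1L, 2L, 4L,
                  4L, 2L, 1L, 3L), 4L, 4L, byrow = TRUE)
  out <- genome
  out$strain_id <- strain_id
  out$genes$gene_id <- ifelse(is.na(out$genes$ortholog_id),
                              out$genes$gene_id,
                              paste0(strain_id, "_", out$genes$ortholog_id))
  tr <- attr(genome, "translocated")
  out$chromosomes <- with_seed(seed, lapply(genome$chromosomes, function(s) {
    v <- seq_to_int(s)
    cat <- sample.int(4L, length(v), replace = TRUE, prob = probs)
    nv <- MUT[cbind(v, cat)]
    int_to_seq(nv)
  }))
  out <- annotated_genome(out$strain_id, out$chromosomes, out$genes)
  attr(out, "translocated") <- tr
  out
}

#' Plant an identical-by-state gene block shared by two strains
#'
#' Copies strain A's coding sequences for the focal gene and `left`/`right`
#' flanking genes (by position on A's focal chromosome) into strain B, making
#' the raw mismatch count exactly 0 there.
#'
#' @param strainA,strainB `annotated_genome` objects with the same gene
#'   arrangement around the focal gene.
#' @param focal focal ortholog ID.
#' @param left,right flanking gene counts on each side (0 plants only the
#'   focal gene).
#' @return list with the modified `genome` (strain B) and `truth`.
#' @export
plant_shared_block <- function(strainA, strainB, focal, left = 33L,
                               right = 21L) {
  fgA <- find_ortholog_gene(strainA, focal)
  chr <- strainA$genes[strainA$genes$chromosome == fgA$chromosome, ,
                      drop = FALSE]
  chr <- chr[order(chr$start), , drop = FALSE]
  f_idx <- which(chr$gene_id == fgA$gene_id)
  if (f_idx - left < 1L || f_idx + right > nrow(chr))
    stop_config("block extent (%d left, %d right) exceeds the available flank",
                left, right)
  sel <- chr[(f_idx - left):(f_idx + right), , drop = FALSE]
  g <- strainB
  for (i in seq_len(nrow(sel))) {
    gA <- sel[i, , drop = FALSE]
    gB <- find_ortholog_gene(strainB, gA$ortholog_id)
    if (gA$end - gA$start != gB$end - gB$start)
      stop_config("ortholog %s has unequal gene lengths", gA$ortholog_id)
    seqA <- substr(strainA$chromosomes[[gA$chromosome]], gA$start, gA$end)
    if (gA$strand != gB$strand) seqA <- revcomp(seqA)
    substr(g$chromosomes[[gB$chromosome]], gB$start, gB$end) <- seqA
  }
  list(genome = g,
       truth = list(left = left, right = right,
                    orthologs = sel$ortholog_id, focal = focal))
}

#' Simulate a qPCR experiment with planted fold-changes
#'
#' Target-gene quantities carry per-strain fold-changes relative to the
#' calibrator; reference-gene quantities are constant across strains. Ct
#' values follow each gene's standard curve
#' (`ct = intercept + slope * log10(quantity)`, slope `-1/log10(E)`) plus
#' Gaussian noise; a dilution series (10^-1 .. 10^-5) is emitted per gene.
#'
#' @param spec list overriding any of: `strains` (named fold-changes),
#'   `calibrator`, `conditions`, `timepoints`, `target`, `references`,
#'   `efficiencies`, `intercepts` (both named per gene), `noise_sd`
#'   (cycles), `n_replicates`, `dilutions`, `base_quantity`.
#' @param seed integer seed.
#' @return list with `ct_table`, `curve_table`, `truth`.
#' @export
simulate_qpcr <- function(spec = list(), seed = 1L) {
  d <- list(strains = c(anc01 = 1, anc02 = 1, vii01 = 10, vii02 = 10),
            calibrator = "anc01",
            conditions = c("MBS", "noMBS"),
            timepoints = c(24, 48, 72, 96),
            target = "SSU1", references = c("ACT1", "RDN18"),
            efficiencies = NULL, intercepts = NULL,
            noise_sd = 0.2, n_replicates = 3L,
            dilutions = 10^-(1:5), base_quantity = 0.01)
  d[names(spec)] <- spec
  genes <- c(d$target, d$references)
  eff <- d$efficiencies %||% stats::setNames(rep(2, length(genes)), genes)
  icpt <- d$intercepts %||% stats::setNames(c(24, 18, 14)[seq_along(genes)],
                                            genes)
  slope <- -1 / log10(eff)
  if (!d$calibrator %in% names(d$strains))
    stop_config("calibrator must be among the simulated strains")
  grid <- expand.grid(strain = names(d$strains), condition = d$conditions,
                      hours = d$timepoints, gene = genes,
                      replicate = seq_len(d$n_replicates),
                      stringsAsFactors = FALSE)
  with_seed(seed, {
    q <- ifelse(grid$gene == d$target,
                d$strains[grid$strain] * d$base_quantity, d$base_quantity)
    grid$ct <- icpt[grid$gene] + slope[grid$gene] * log10(q) +
      stats::rnorm(nrow(grid), 0, d$noise_sd)
    curve <- expand.grid(gene = genes, dilution = d$dilutions,
                         stringsAsFactors = FALSE)
    curve$ct <- icpt[curve$gene] + slope[curve$gene] * log10(curve$dilution) +
      stats::rnorm(nrow(curve), 0, d$noise_sd)
    list(ct_table = grid, curve_table = curve,
         truth = list(fold_changes = d$strains, calibrator = d$calibrator,
                      efficiencies = eff))
  })
}

#' Simulate a drop-test growth table
#'
#' Each strain's maximum tolerated concentration is drawn around its
#' promoter-class mean (Gaussian, then snapped to the concentration grid);
#' growth scores decay linearly from 6 at 0 g/L to 1 at the tolerated
#' maximum and are 0 above it.
#'
#' @param spec list overriding any of: `classes` (data.frame with `class`,
#'   `n`, `mean`), `noise_sd` (g/L), `grid`.
#' @param seed integer seed.
#' @return list with `table` (`droptest_table`) and `truth`.
#' @export
simulate_droptest <- function(spec = list(), seed = 1L) {
  d <- list(classes = data.frame(class = DROPTEST_CLASSES,
                                 n = c(52L, 10L, 1L),
                                 mean = c(0.175, 0.375, 0.4),
                                 stringsAsFactors = FALSE),
            noise_sd = 0.025,
            grid = seq(0, 0.4, by = 0.05))
  d[names(spec)] <- spec
  if (any(d$classes$mean < min(d$grid) | d$classes$mean > max(d$grid)))
    stop_config("class means must lie within the concentration grid")
  with_seed(seed, {
    rows <- list(); strains <- character(0); classes <- character(0)
    for (i in seq_len(nrow(d$classes))) {
      cl <- d$classes[i, ]
      for (j in seq_len(cl$n)) {
        draw <- stats::rnorm(1, cl$mean, d$noise_sd)
        dist <- abs(d$grid - draw)
        maxc <- d$grid[which(dist - min(dist) < 1e-9)][1L]  # ties snap down
        sc <- integer(length(d$grid))
        grew <- d$grid <= maxc
        sc[grew] <- if (maxc > 0) pmax(1L, as.integer(round(
          6 - 5 * d$grid[grew] / maxc))) else 6L
        rows[[length(rows) + 1L]] <- sc
        strains <- c(strains, sprintf("%s_%02d", gsub("\\^", "", cl$class), j))
        classes <- c(classes, cl$class)
      }
    }
    scores <- do.call(rbind, rows)
    rownames(scores) <- strains
    colnames(scores) <- format(d$grid, trim = TRUE)
    tab <- structure(list(scores = scores, strain = strains,
                          class = classes, grid = d$grid),
                     class = "droptest_table")
    list(table = tab,
         truth = list(class_means = stats::setNames(d$classes$mean,
                                                    d$classes$class)))
  })
}

#' Default scenario configuration
#'
#' The study design the generator emulates: a reference ancestor with three
#' chromosomes of 80 one-kb genes; 17 ancestral-promoter strains, 3 strains
#' carrying a shared chrVII translocation 339 bp upstream of the focal gene
#' with 8 bp microhomology, and 1 strain with an independent chrXI
#' translocation at 393 bp with 4 bp microhomology; intraspecific divergence
#' 0.005 substitutions/site per branch; an identical-by-state block of 33 +
#' 21 genes shared by the first two translocated strains; qPCR fold-changes
#' and a 64-strain drop-test collection.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param n_ancestral,n_vii,n_xi strain counts per promoter class.
#' @param branch_length per-strain branch length (substitutions/site).
#' @return configuration list for [simulate_scenario()].
#' @export
scenario_config <- function(seed = 1L, n_ancestral = 17L, n_vii = 3L,
                            n_xi = 1L, branch_length = 0.005) {
  strains <- data.frame(
    strain_id = c(sprintf("anc%02d", seq_len(n_ancestral)),
                  sprintf("vii%02d", seq_len(n_vii)),
                  if (n_xi > 0L) sprintf("xi%02d", seq_len(n_xi))),
    class = c(rep("ancestral", n_ancestral), rep("VII^XVI", n_vii),
              rep("XI^XVI", n_xi)),
    branch = branch_length, stringsAsFactors = FALSE)
  qpcr_strains <- c(1, 1, 1, 10, 10, 5)
  names(qpcr_strains) <- c("anc01", "anc02", "anc03", "vii01", "vii02", "xi01")
  qpcr_strains <- qpcr_strains[names(qpcr_strains) %in% strains$strain_id]
  list(seed = seed,
       chromosomes = c(chrVII = 80L, chrXI = 80L, chrXVI = 80L),
       gene_length = 1000L, intergenic_length = 1000L,
       focal = list(chromosome = "chrXVI", index = 40L),
       motif = "CTATCA", motif_offset = 500L,
       events = list(vii = list(partner = "chrVII", partner_gene_index = 40L,
                                offset = 339L, microhomology = 8L),
                     xi = list(partner = "chrXI", partner_gene_index = 40L,
                               offset = 393L, microhomology = 4L)),
       strains = strains,
       shared_block = list(strains = c("vii01", "vii02"), left = 33L,
                           right = 21L),
       qpcr = list(strains = qpcr_strains, calibrator = "anc01"),
       droptest = list(),
       window_size = 20L, n_windows = 1000L)
}

#' Simulate a complete study scenario with planted ground truth
#'
#' Builds the reference ancestor, plants the translocation events (the
#' reference keeps the junction microhomology sequences), evolves each strain
#' from its class's base genome, plants the shared identical block, and
#' simulates the qPCR and drop-test tables. Deterministic given the config's
#' seed.
#'
#' @param config list from [scenario_config()].
#' @return list with `reference`, `genomes` (named list), `orthologs`,
#'   `focal` (ortholog ID), `qpcr`, `droptest`, `truth`, `config`.
#' @export
simulate_scenario <- function(config = scenario_config()) {
  seed <- config$seed
  anc <- simulate_reference(seed = derive_seed(seed, "reference"),
                            chromosomes = config$chromosomes,
                            gene_length = config$gene_length,
                            intergenic_length = config$intergenic_length,
                            focal = config$focal, motif = config$motif,
                            motif_offset = config$motif_offset)
  focal_og <- anc$genes$ortholog_id[anc$genes$chromosome ==
                                      config$focal$chromosome][config$focal$index]
  ev <- config$events
  r1 <- apply_translocation(anc, focal_og, ev$vii$partner,
                            offset = ev$vii$offset,
                            microhomology_len = ev$vii$microhomology,
                            partner_gene_index = ev$vii$partner_gene_index,
                            derived_strain_id = "vii_base",
                            seed = derive_seed(seed, "mh_vii"))
  has_xi <- !is.null(ev$xi)
  if (has_xi) {
    r2 <- apply_translocation(r1$reference, focal_og, ev$xi$partner,
                              offset = ev$xi$offset,
                              microhomology_len = ev$xi$microhomology,
                              partner_gene_index = ev$xi$partner_gene_index,
                              derived_strain_id = "xi_base",
                              seed = derive_seed(seed, "mh_xi"))
    reference <- r2$reference
    ## re-derive the chrVII event from the final reference so every base
    ## genome carries both planted microhomologies
    r1 <- apply_translocation(reference, focal_og, ev$vii$partner,
                              offset = ev$vii$offset,
                              microhomology_len = ev$vii$microhomology,
                              partner_gene_index = ev$vii$partner_gene_index,
                              derived_strain_id = "vii_base",
                              seed = derive_seed(seed, "mh_vii"))
    stopifnot(identical(r1$reference$chromosomes, reference$chromosomes))
  } else {
    reference <- r1$reference
  }
  bases <- list(ancestral = reference, `VII^XVI` = r1$derived)
  truth_events <- list(`VII^XVI` = r1$truth)
  if (has_xi) {
    bases$`XI^XVI` <- r2$derived
    truth_events$`XI^XVI` <- r2$truth
  }
  genomes <- list()
  for (i in seq_len(nrow(config$strains))) {
    st <- config$strains[i, ]
    genomes[[st$strain_id]] <- evolve_k81(
      bases[[st$class]], st$branch,
      seed = derive_seed(seed, paste0("evolve_", st$strain_id)),
      strain_id = st$strain_id)
  }
  block_truth <- NULL
  sb <- config$shared_block
  if (!is.null(sb)) {
    pb <- plant_shared_block(genomes[[sb$strains[1L]]],
                             genomes[[sb$strains[2L]]], focal_og,
                             left = sb$left, right = sb$right)
    genomes[[sb$strains[2L]]] <- pb$genome
    block_truth <- c(pb$truth, list(strains = sb$strains))
  }
  orthologs <- build_ortholog_map(c(list(reference), genomes))
  qpcr <- simulate_qpcr(config$qpcr, seed = derive_seed(seed, "qpcr"))
  droptest <- simulate_droptest(config$droptest,
                                seed = derive_seed(seed, "droptest"))
  truth <- list(
    focal = focal_og,
    classes = stats::setNames(config$strains$class, config$strains$strain_id),
    events = truth_events,
    motif_offset = config$motif_offset,
    shared_block = block_truth,
    qpcr = qpcr$truth,
    droptest = droptest$truth)
  list(reference = reference, genomes = genomes, orthologs = orthologs,
       focal = focal_og, qpcr = qpcr, droptest = droptest, truth = truth,
       config = config)
}
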