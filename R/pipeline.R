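## Pipeline orchestration: a directory-based workflow over the analysis
## stages, driven by a flat key=value configuration and a manifest written at
## simulation time. The `ssuscan` script under exec/ is a thin command-line
## wrapper over run_pipeline().

#' Write a scenario configuration as a flat key=value file
#'
#' @param config list from [scenario_config()].
#' @param path output path.
#' @export
write_sim_config <- function(config, path) {
  kv <- c(
    seed = config$seed,
    chromosomes = paste(sprintf("%s:%d", names(config$chromosomes),
                                config$chromosomes), collapse = ","),
    gene_length = config$gene_length,
    intergenic_length = config$intergenic_length,
    focal_chromosome = config$focal$chromosome,
    focal_index = config$focal$index,
    motif = config$motif,
    motif_offset = config$motif_offset,
    window_size = config$window_size,
    n_windows = config$n_windows,
    strains = paste(sprintf("%s:%s:%g", config$strains$strain_id,
                            config$strains$class, config$strains$branch),
                    collapse = ","))
  for (nm in names(config$events)) {
    e <- config$events[[nm]]
    kv[paste0("event_", nm)] <- sprintf("%s:%d:%d:%d", e$partner,
                                        e$partner_gene_index, e$offset,
                                        e$microhomology)
  }
  if (!is.null(config$shared_block))
    kv["shared_block"] <- sprintf("%s:%s:%d:%d",
                                  config$shared_block$strains[1L],
                                  config$shared_block$strains[2L],
                                  config$shared_block$left,
                                  config$shared_block$right)
  if (!is.null(config$qpcr$strains))
    kv["qpcr_strains"] <- paste(sprintf("%s:%g", names(config$qpcr$strains),
                                        config$qpcr$strains), collapse = ",")
  if (!is.null(config$qpcr$calibrator))
    kv["qpcr_calibrator"] <- config$qpcr$calibrator
  writeLines(sprintf("%s=%s", names(kv), kv), path)
  invisible(path)
}

#' Read a flat key=value scenario configuration
#'
#' @param path file written by [write_sim_config()].
#' @return configuration list (see [scenario_config()]).
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop_format("config file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, function(x)
    paste(x[-1L], collapse = "="), character(1)),
    vapply(kv, `[[`, character(1), 1L))
  split_fields <- function(s) strsplit(strsplit(s, ",", fixed = TRUE)[[1L]],
                                       ":", fixed = TRUE)
  chrom <- split_fields(vals[["chromosomes"]])
  chromosomes <- stats::setNames(vapply(chrom, function(x)
    as.integer(x[2L]), integer(1)), vapply(chrom, `[[`, character(1), 1L))
  strains <- split_fields(vals[["strains"]])
  strains <- data.frame(
    strain_id = vapply(strains, `[[`, character(1), 1L),
    class = vapply(strains, `[[`, character(1), 2L),
    branch = vapply(strains, function(x) as.numeric(x[3L]), numeric(1)),
    stringsAsFactors = FALSE)
  events <- list()
  for (nm in grep("^event_", names(vals), value = TRUE)) {
    f <- strsplit(vals[[nm]], ":", fixed = TRUE)[[1L]]
    events[[sub("^event_", "", nm)]] <-
      list(partner = f[1L], partner_gene_index = as.integer(f[2L]),
           offset = as.integer(f[3L]), microhomology = as.integer(f[4L]))
  }
  config <- list(seed = as.integer(vals[["seed"]]),
                 chromosomes = chromosomes,
                 gene_length = as.integer(vals[["gene_length"]]),
                 intergenic_length = as.integer(vals[["intergenic_length"]]),
                 focal = list(chromosome = vals[["focal_chromosome"]],
                              index = as.integer(vals[["focal_index"]])),
                 motif = vals[["motif"]],
                 motif_offset = as.integer(vals[["motif_offset"]]),
                 events = events, strains = strains,
                 window_size = as.integer(vals[["window_size"]]),
                 n_windows = as.integer(vals[["n_windows"]]),
                 qpcr = list(), droptest = list())
  if ("shared_block" %in% names(vals)) {
    f <- strsplit(vals[["shared_block"]], ":", fixed = TRUE)[[1L]]
    config$shared_block <- list(strains = f[1:2], left = as.integer(f[3L]),
                                right = as.integer(f[4L]))
  }
  if ("qpcr_strains" %in% names(vals)) {
    f <- split_fields(vals[["qpcr_strains"]])
    config$qpcr$strains <- stats::setNames(
      vapply(f, function(x) as.numeric(x[2L]), numeric(1)),
      vapply(f, `[[`, character(1), 1L))
  }
  if ("qpcr_calibrator" %in% names(vals))
    config$qpcr$calibrator <- vals[["qpcr_calibrator"]]
  config
}

## Refuse to clobber stage outputs unless forced.
check_overwrite <- function(paths, force) {
  existing <- paths[file.exists(paths)]
  if (length(existing) > 0L && !force)
    stop_config("output file(s) already exist (use force = TRUE): %s",
                paste(existing, collapse = ", "))
  invisible(TRUE)
}

#' Write a simulated scenario to a pipeline directory
#'
#' Emits FASTA + GFF3 per strain (and the reference), the ortholog TSV, the
#' qPCR and drop-test tables, the ground-truth JSON and a manifest consumed
#' by the downstream stages.
#'
#' @param scenario list from [simulate_scenario()].
#' @param dir output directory (created if needed).
#' @param force overwrite existing outputs.
#' @return the directory, invisibly.
#' @export
write_scenario <- function(scenario, dir, force = FALSE) {
  gdir <- file.path(dir, "genomes")
  dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
  all_genomes <- c(list(scenario$reference), unname(scenario$genomes))
  paths <- c(file.path(dir, c("orthologs.tsv", "qpcr_ct.tsv",
                              "qpcr_curves.tsv", "droptest.tsv",
                              "truth.json", "manifest.json")),
             unlist(lapply(all_genomes, function(g)
               file.path(gdir, paste0(g$strain_id, c(".fa", ".gff3"))))))
  check_overwrite(paths, force)
  for (g in all_genomes)
    write_annotated_genome(g, file.path(gdir, paste0(g$strain_id, ".fa")),
                           file.path(gdir, paste0(g$strain_id, ".gff3")))
  write_ortholog_table(scenario$orthologs, file.path(dir, "orthologs.tsv"))
  utils::write.table(scenario$qpcr$ct_table, file.path(dir, "qpcr_ct.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(scenario$qpcr$curve_table,
                     file.path(dir, "qpcr_curves.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_droptest(scenario$droptest$table, file.path(dir, "droptest.tsv"))
  jsonlite::write_json(scenario$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  manifest <- list(
    reference = scenario$reference$strain_id,
    strains = names(scenario$genomes),
    focal = scenario$focal,
    motif = scenario$config$motif,
    window_size = scenario$config$window_size,
    n_windows = scenario$config$n_windows,
    seed = scenario$config$seed,
    pair = if (!is.null(scenario$config$shared_block))
      scenario$config$shared_block$strains else names(scenario$genomes)[1:2],
    qpcr = list(calibrator = scenario$qpcr$truth$calibrator,
                target = "SSU1", references = c("ACT1", "RDN18")),
    versions = list(ssuscan = as.character(utils::packageVersion("ssuscan")),
                    R = paste(R.version$major, R.version$minor, sep = ".")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) stop_format("missing manifest: %s", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

load_scenario_genome <- function(dir, strain) {
  fa <- file.path(dir, "genomes", paste0(strain, ".fa"))
  gff <- file.path(dir, "genomes", paste0(strain, ".gff3"))
  for (p in c(fa, gff))
    if (!file.exists(p)) stop_format("missing input file: %s", p)
  load_annotated_genome(fa, gff, strain)
}

#' Run a pipeline stage
#'
#' Subcommands: `simulate` (generate a scenario into `out`), `detect`
#' (rearrangement scan), `haploshare` (distance profile, shared block and
#' permutation test for the manifest's strain pair), `qpcr` (relative
#' expression), `phenotype` (drop-test summary), `all` (everything plus a
#' combined report). All stages other than `simulate` read the files a prior
#' `simulate` wrote into `out`.
#'
#' @param subcommand one of `simulate`, `detect`, `haploshare`, `qpcr`,
#'   `phenotype`, `all`.
#' @param out pipeline directory.
#' @param config `NULL`, a configuration list, or the path of a flat
#'   key=value file (see [read_sim_config()]).
#' @param seed master seed used when `config` is `NULL` (and recorded in the
#'   manifest).
#' @param force overwrite existing stage outputs.
#' @return list of stage results, invisibly.
#' @export
run_pipeline <- function(subcommand = c("all", "simulate", "detect",
                                        "haploshare", "qpcr", "phenotype"),
                         out, config = NULL, seed = 1L, force = FALSE) {
  subcommand <- match.arg(subcommand)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  if (subcommand %in% c("simulate", "all")) {
    cfg <- if (is.null(config)) scenario_config(seed = seed)
           else if (is.character(config)) read_sim_config(config)
           else config
    scenario <- simulate_scenario(cfg)
    write_scenario(scenario, out, force = force)
    results$simulate <- scenario
  }
  if (subcommand %in% c("detect", "all")) {
    man <- read_manifest(out)
    reference <- load_scenario_genome(out, man$reference)
    genomes <- lapply(man$strains, load_scenario_genome, dir = out)
    scan <- scan_collection(genomes, reference, man$focal, motif = man$motif)
    check_overwrite(file.path(out, c("rearrangement_calls.tsv",
                                     "rearrangement_calls.json")), force)
    write_scan(scan, file.path(out, "rearrangement_calls.tsv"),
               file.path(out, "rearrangement_calls.json"))
    results$detect <- scan
  }
  if (subcommand %in% c("haploshare", "all")) {
    man <- read_manifest(out)
    gA <- load_scenario_genome(out, man$pair[1L])
    gB <- load_scenario_genome(out, man$pair[2L])
    orth <- read_ortholog_table(file.path(out, "orthologs.tsv"))
    hs <- haplotype_sharing_test(gA, gB, orth, man$focal,
                                 window_size = man$window_size,
                                 n_windows = man$n_windows,
                                 seed = derive_seed(man$seed, "windows"))
    check_overwrite(file.path(out, c("distance_profile.tsv",
                                     "shared_block.json",
                                     "permutation.json")), force)
    utils::write.table(hs$profile, file.path(out, "distance_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    jsonlite::write_json(hs$block, file.path(out, "shared_block.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    perm <- hs$test
    jsonlite::write_json(
      list(U = perm$U, p_value = perm$p_value, empirical_p = perm$empirical_p,
           focal_mean = mean(perm$focal), null_mean = mean(perm$null),
           n_windows = perm$n_windows, window_size = perm$window_size,
           seed = perm$seed, n_saturated = hs$null$n_saturated),
      file.path(out, "permutation.json"), auto_unbox = TRUE, digits = NA)
    results$haploshare <- hs
  }
  if (subcommand %in% c("qpcr", "all")) {
    man <- read_manifest(out)
    for (f in file.path(out, c("qpcr_ct.tsv", "qpcr_curves.tsv")))
      if (!file.exists(f)) stop_format("missing input file: %s", f)
    ct <- read_qpcr_table(file.path(out, "qpcr_ct.tsv"))
    curves_tab <- read_curve_table(file.path(out, "qpcr_curves.tsv"))
    curves <- lapply(split(curves_tab, curves_tab$gene), function(x)
      fit_standard_curve(x, gene = x$gene[1L]))
    expr <- normalize_expression(ct, curves, calibrator = man$qpcr$calibrator,
                                 target = man$qpcr$target,
                                 references = man$qpcr$references)
    check_overwrite(file.path(out, c("relative_expression.tsv",
                                     "relative_expression.json")), force)
    write_expression(expr, file.path(out, "relative_expression.tsv"),
                     file.path(out, "relative_expression.json"))
    results$qpcr <- expr
  }
  if (subcommand %in% c("phenotype", "all")) {
    if (!file.exists(file.path(out, "droptest.tsv")))
      stop_format("missing input file: %s", file.path(out, "droptest.tsv"))
    tab <- parse_droptest(file.path(out, "droptest.tsv"))
    per <- tolerance_summary(tab)
    cmp <- class_comparison(tab, "ancestral", "VII^XVI")
    check_overwrite(file.path(out, c("tolerance.tsv",
                                     "tolerance_summary.json")), force)
    utils::write.table(per, file.path(out, "tolerance.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
    jsonlite::write_json(cmp, file.path(out, "tolerance_summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    results$phenotype <- list(per_strain = per, comparison = cmp)
  }
  if (subcommand == "all") {
    man <- read_manifest(out)
    report <- list(
      manifest = man,
      rearrangement_summary = results$detect$summary,
      shared_block = results$haploshare$block,
      permutation_p = results$haploshare$test$p_value,
      expression_cells = nrow(results$qpcr),
      tolerance = results$phenotype$comparison)
    check_overwrite(file.path(out, "report.json"), force)
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    results$report <- report
  }
  invisible(results)
}
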