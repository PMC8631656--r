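## Annotated-genome data model and the FASTA/GFF3/TSV readers and writers
## shared by every downstream stage.

#' Construct an annotated genome
#'
#' The central container of the pipeline: per-strain chromosome sequences plus
#' an ordered table of gene features. Coordinates are 1-based inclusive
#' (GFF3 convention) throughout the package.
#'
#' @param strain_id character scalar naming the strain.
#' @param chromosomes named list or character vector of uppercase nucleotide
#'   sequences (A/C/G/T/N).
#' @param genes data.frame with columns `gene_id`, `ortholog_id`, `chromosome`,
#'   `start`, `end`, `strand`. `ortholog_id` may be `NA`.
#' @return object of class `annotated_genome`.
#' @export
annotated_genome <- function(strain_id, chromosomes, genes) {
  chromosomes <- as.list(chromosomes)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  need <- c("gene_id", "ortholog_id", "chromosome", "start", "end", "strand")
  missing_cols <- setdiff(need, names(genes))
  if (length(missing_cols) > 0L)
    stop_format("gene table lacks column(s): %s",
                paste(missing_cols, collapse = ", "))
  genes <- genes[order(genes$chromosome, genes$start), need, drop = FALSE]
  rownames(genes) <- NULL
  obj <- structure(list(strain_id = strain_id,
                        chromosomes = chromosomes,
                        genes = genes),
                   class = "annotated_genome")
  validate_genome(obj)
  obj
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> strain %s: %d chromosome(s), %d gene(s)\n",
              x$strain_id, length(x$chromosomes), nrow(x$genes)))
  for (nm in names(x$chromosomes))
    cat(sprintf("  %s  %s bp\n", nm,
                format(nchar(x$chromosomes[[nm]]), big.mark = ",")))
  invisible(x)
}

## Enforce the structural invariants of the data model.
validate_genome <- function(g) {
  genes <- g$genes
  if (anyDuplicated(genes$gene_id))
    stop_consistency("duplicate gene IDs in strain %s", g$strain_id)
  key <- paste(genes$chromosome, genes$start, genes$end, genes$strand)
  if (anyDuplicated(key))
    stop_consistency("two genes share an identical locus in strain %s",
                     g$strain_id)
  if (any(genes$start > genes$end))
    stop_format("gene with end < start in strain %s", g$strain_id)
  if (!all(genes$strand %in% c("+", "-")))
    stop_format("gene strand must be '+' or '-'")
  unknown <- setdiff(unique(genes$chromosome), names(g$chromosomes))
  if (length(unknown) > 0L)
    stop_consistency("gene(s) on unknown chromosome(s): %s",
                     paste(unknown, collapse = ", "))
  lens <- vapply(g$chromosomes, nchar, integer(1))
  if (any(genes$end > lens[genes$chromosome] | genes$start < 1L))
    stop_consistency("gene outside chromosome bounds in strain %s",
                     g$strain_id)
  invisible(g)
}

#' Read a (multi-)FASTA file
#'
#' Sequence names are the first whitespace-delimited token of each header;
#' sequences are uppercased. Characters outside A/C/G/T/N are rejected.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_format("FASTA file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_format("bad FASTA %s: %s", path,
                                                  conditionMessage(e)))
  if (length(set) == 0L) stop_format("empty FASTA file: %s", path)
  nms <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nms))
    stop_format("duplicate sequence name(s) in %s: %s", path,
                paste(unique(nms[duplicated(nms)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop_format("sequence(s) with characters outside A/C/G/T/N in %s: %s",
                path, paste(nms[bad], collapse = ", "))
  names(seqs) <- nms
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector or list of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  set <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read gene features from a GFF3 file
#'
#' Only rows of type `gene` are consumed. `gene_id` is taken from the `ID`
#' attribute and `ortholog_id` from an `ortholog` attribute when present.
#' Features are returned sorted by (chromosome, start), 1-based inclusive.
#'
#' @param path GFF3 file path.
#' @return data.frame of gene features.
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) stop_format("GFF3 file not found: %s", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop_format("bad GFF3 %s: %s", path,
                                                 conditionMessage(e)))
  gr <- gr[gr$type == "gene"]
  ids <- as.character(gr$ID)
  if (length(gr) > 0L && (is.null(gr$ID) || anyNA(ids)))
    stop_format("gene row(s) without an ID attribute in %s", path)
  orth <- if (!is.null(gr$ortholog)) as.character(gr$ortholog)
          else rep(NA_character_, length(gr))
  out <- data.frame(gene_id = ids,
                    ortholog_id = orth,
                    chromosome = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    stringsAsFactors = FALSE)
  if (any(out$strand == "*"))
    stop_format("gene row(s) without strand in %s", path)
  out <- out[order(out$chromosome, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write gene features to GFF3
#'
#' @param genes gene feature data.frame (see [read_gff()]).
#' @param path output path.
#' @export
write_gff <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chromosome,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand)
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  if (any(!is.na(genes$ortholog_id))) gr$ortholog <- genes$ortholog_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Load and cross-validate an annotated genome from FASTA + GFF3
#'
#' @param fasta FASTA path.
#' @param gff GFF3 path.
#' @param strain_id strain label.
#' @return `annotated_genome`.
#' @export
load_annotated_genome <- function(fasta, gff, strain_id) {
  annotated_genome(strain_id, read_fasta(fasta), read_gff(gff))
}

#' Write an annotated genome as FASTA + GFF3
#'
#' Inverse of [load_annotated_genome()]: the written pair re-reads to an
#' identical object.
#'
#' @param genome `annotated_genome`.
#' @param fasta,gff output paths.
#' @export
write_annotated_genome <- function(genome, fasta, gff) {
  write_fasta(genome$chromosomes, fasta)
  write_gff(genome$genes, gff)
  invisible(genome)
}

#' Read an ortholog table
#'
#' TSV with header `ortholog_id` followed by one column per strain; cells hold
#' gene IDs, empty cells mean the ortholog is absent in that strain.
#'
#' @param path TSV path.
#' @return data.frame (class `ortholog_map`), one row per ortholog.
#' @export
read_ortholog_table <- function(path) {
  if (!file.exists(path)) stop_format("ortholog table not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, na.strings = "")
  if (names(tab)[1] != "ortholog_id")
    stop_format("ortholog table must start with an 'ortholog_id' column")
  if (anyDuplicated(tab$ortholog_id))
    stop_format("duplicate ortholog_id row(s): %s",
                paste(unique(tab$ortholog_id[duplicated(tab$ortholog_id)]),
                      collapse = ", "))
  class(tab) <- c("ortholog_map", "data.frame")
  tab
}

#' Write an ortholog table
#'
#' @param map ortholog map data.frame.
#' @param path output TSV path.
#' @export
write_ortholog_table <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Build an ortholog map from a set of annotated genomes
#'
#' @param genomes list of `annotated_genome` objects.
#' @return ortholog map data.frame (`ortholog_id` + one column per strain).
#' @export
build_ortholog_map <- function(genomes) {
  ids <- sort(unique(unlist(lapply(genomes, function(g)
    g$genes$ortholog_id[!is.na(g$genes$ortholog_id)]))))
  out <- data.frame(ortholog_id = ids, stringsAsFactors = FALSE)
  for (g in genomes) {
    gt <- g$genes[!is.na(g$genes$ortholog_id), ]
    if (anyDuplicated(gt$ortholog_id))
      stop_format("ortholog assigned to more than one gene in strain %s",
                  g$strain_id)
    out[[g$strain_id]] <- gt$gene_id[match(ids, gt$ortholog_id)]
  }
  class(out) <- c("ortholog_map", "data.frame")
  out
}

## Look up the gene row carrying an ortholog in a genome; errors if absent or
## duplicated.
find_ortholog_gene <- function(genome, ortholog_id, required = TRUE) {
  hit <- which(genome$genes$ortholog_id == ortholog_id)
  if (length(hit) == 0L) {
    if (required)
      stop_lookup("ortholog %s absent from strain %s", ortholog_id,
                  genome$strain_id)
    return(NULL)
  }
  if (length(hit) > 1L)
    stop_lookup("ortholog %s present more than once in strain %s", ortholog_id,
                genome$strain_id)
  genome$genes[hit, , drop = FALSE]
}

## Strand-aware gene start: the translation-start-proximal coordinate on the
## coding strand (start for "+", end for "-").
gene_start_coord <- function(gene) {
  if (gene$strand == "+") gene$start else gene$end
}

#' Mirror one chromosome of a genome
#'
#' Reverse-complements the sequence and mirrors all gene coordinates and
#' strands on that chromosome. Biologically a no-op (same molecule read from
#' the other end); used to check strand-symmetry of downstream scans.
#'
#' @param genome `annotated_genome`.
#' @param chromosome chromosome name.
#' @return `annotated_genome`.
#' @export
flip_chromosome <- function(genome, chromosome) {
  if (!chromosome %in% names(genome$chromosomes))
    stop_lookup("no chromosome %s in strain %s", chromosome, genome$strain_id)
  len <- nchar(genome$chromosomes[[chromosome]])
  genome$chromosomes[[chromosome]] <- revcomp(genome$chromosomes[[chromosome]])
  on_chr <- genome$genes$chromosome == chromosome
  s <- genome$genes$start[on_chr]; e <- genome$genes$end[on_chr]
  genome$genes$start[on_chr] <- len - e + 1L
  genome$genes$end[on_chr] <- len - s + 1L
  genome$genes$strand[on_chr] <- ifelse(genome$genes$strand[on_chr] == "+",
                                        "-", "+")
  genome$genes <- genome$genes[order(genome$genes$chromosome,
                                     genome$genes$start), ]
  rownames(genome$genes) <- NULL
  genome
}
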