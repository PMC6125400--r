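#' Read a BED file of ChIP-seq peak calls
#'
#' Parses BED3/BED4/BED5 peak calls from one replicate. BED coordinates are
#' 0-based half-open on disk; internally peaks are held as an unstranded
#' [GenomicRanges::GRanges] (1-based closed), the conversion happening only at
#' this boundary. Track, browser and `#` comment lines are skipped. The result
#' is sorted by (chromosome, start, end) with lexicographic chromosome order,
#' so repeated reads of one file always yield the same order.
#'
#' @param path Path to a BED file.
#' @param replicate_id Label for the replicate the file comes from.
#' @param condition Label for the experimental condition.
#' @param normalize_chr If `TRUE`, strip a leading `"chr"` prefix from
#'   chromosome names. Chromosome comparison elsewhere is exact string match,
#'   so mixed naming must be normalised at read time.
#' @return A `GRanges` with metadata columns `name` and `score` (when present
#'   in the file), `replicate_id` and `condition`. An empty file yields an
#'   empty `GRanges` with a warning.
#' @export
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t500\tpk1\t7", "chr1\t800\t900"), bed)
#' read_peak_bed(bed, replicate_id = "rep1", condition = "control")
read_peak_bed <- function(path, replicate_id = NA_character_,
                          condition = NA_character_, normalize_chr = FALSE) {
  if (!file.exists(path)) stop_mc("BED file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    warning("no peak records in ", path, call. = FALSE)
    gr <- GenomicRanges::GRanges()
    mcols(gr)$replicate_id <- character(0)
    mcols(gr)$condition <- character(0)
    return(gr)
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop_mc("line ", idx[which(nf < 3L)[1L]], " of ", path,
            ": fewer than 3 tab-separated fields")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start0) | is.na(end0) |
    start0 != floor(start0) | end0 != floor(end0)
  if (any(bad)) {
    stop_mc("line ", idx[which(bad)[1L]], " of ", path,
            ": non-integer coordinate")
  }
  if (any(start0 >= end0)) {
    stop_mc("line ", idx[which(start0 >= end0)[1L]], " of ", path,
            ": start must be < end (0-based half-open)")
  }
  if (any(start0 < 0)) {
    stop_mc("line ", idx[which(start0 < 0)[1L]], " of ", path,
            ": negative coordinate")
  }
  if (normalize_chr) chrom <- sub("^chr", "", chrom)
  gr <- mc_granges(chrom, start0 + 1, end0)
  nmax <- max(nf)
  if (nmax >= 4L) {
    mcols(gr)$name <- vapply(fields, function(f)
      if (length(f) >= 4L) f[[4L]] else ".", "")
  }
  if (nmax >= 5L) {
    sc <- suppressWarnings(as.numeric(vapply(fields, function(f)
      if (length(f) >= 5L) f[[5L]] else NA_character_, "")))
    if (any(!is.na(sc) & sc < 0)) {
      stop_mc("line ", idx[which(!is.na(sc) & sc < 0)[1L]], " of ", path,
              ": negative score")
    }
    mcols(gr)$score <- sc
  }
  mcols(gr)$replicate_id <- replicate_id
  mcols(gr)$condition <- condition
  sort(gr)
}

#' Write peaks to a BED file
#'
#' Converts back to 0-based half-open coordinates. Writes BED3, BED4 or BED5
#' depending on which of `name`/`score` metadata columns are present, so that
#' `write_peak_bed(read_peak_bed(f), g)` reproduces the records of a
#' well-formed sorted input byte-identically.
#'
#' @param x A `GRanges` of peaks.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_bed <- function(x, path) {
  df <- data.frame(chrom = as.character(seqnames(x)),
                   start = start(x) - 1L, end = end(x),
                   stringsAsFactors = FALSE)
  mc <- mcols(x)
  if ("name" %in% colnames(mc)) df$name <- as.character(mc$name)
  if ("score" %in% colnames(mc)) {
    if (!"name" %in% colnames(mc)) df$name <- "."
    df$score <- mc$score
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-model table
#'
#' Reads a tab-delimited table with header columns `gene_id`, `chrom`,
#' `start`, `end`, `strand`; coordinates are 0-based half-open as in BED.
#' One interval per gene is expected (isoform collapsing, if needed, is up to
#' the caller); duplicate `gene_id`s are an error. The TSS of a `+` gene is
#' its start; for a `-` gene it is the last base before the half-open end.
#'
#' @param path Path to the TSV file.
#' @return A stranded `GRanges` with a `gene_id` metadata column (also used
#'   as names), sorted deterministically.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop_mc("gene-model file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_mc("gene-model table lacks column(s): ",
                            paste(miss, collapse = ", "))
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup)) stop_mc("duplicate gene_id(s): ", paste(dup, collapse = ", "))
  if (!all(df$strand %in% c("+", "-"))) {
    stop_mc("strand must be '+' or '-'; offending gene(s): ",
            paste(df$gene_id[!df$strand %in% c("+", "-")], collapse = ", "))
  }
  if (any(df$start >= df$end)) {
    stop_mc("start must be < end for gene(s): ",
            paste(df$gene_id[df$start >= df$end], collapse = ", "))
  }
  gr <- mc_granges(df$chrom, df$start + 1, df$end, gene_id = df$gene_id)
  strand(gr) <- df$strand
  names(gr) <- df$gene_id
  gr <- sort(gr, ignore.strand = TRUE)
  gr
}

#' Write a gene-model table
#'
#' Inverse of [read_gene_models()] (0-based half-open on disk).
#'
#' @param genes Stranded `GRanges` with `gene_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  df <- data.frame(gene_id = mcols(genes)$gene_id,
                   chrom = as.character(seqnames(genes)),
                   start = start(genes) - 1L, end = end(genes),
                   strand = as.character(strand(genes)),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' TSS positions of gene models
#'
#' The 5' base of each gene in its strand orientation, as a 1-based
#' coordinate: `start` for `+` genes, `end` for `-` genes.
#'
#' @param genes Stranded `GRanges` of gene models.
#' @return Integer vector of TSS positions, named by `gene_id` when present.
#' @export
tss_position <- function(genes) {
  pos <- ifelse(as.character(strand(genes)) == "+", start(genes), end(genes))
  if (!is.null(mcols(genes)$gene_id)) names(pos) <- mcols(genes)$gene_id
  pos
}

#' Read a differential-expression table
#'
#' Tab-delimited with header `gene_id`, `log_fc`, `p_value`. `log_fc` is the
#' signed log fold-change (treatment vs control); p-values must lie in (0, 1].
#' Rows with missing or non-finite values are rejected.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with columns `gene_id`, `log_fc`, `p_value`.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop_mc("expression file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log_fc", "p_value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_mc("expression table lacks column(s): ",
                            paste(miss, collapse = ", "))
  df$log_fc <- as.numeric(df$log_fc)
  df$p_value <- as.numeric(df$p_value)
  bad <- !is.finite(df$log_fc) | is.na(df$p_value)
  if (any(bad)) stop_mc("missing or non-finite values in row(s): ",
                        paste(which(bad), collapse = ", "))
  if (any(df$p_value <= 0 | df$p_value > 1)) {
    stop_mc("p_value outside (0, 1] in row(s): ",
            paste(which(df$p_value <= 0 | df$p_value > 1), collapse = ", "))
  }
  df[, need]
}

#' Write a differential-expression table
#' @param expr `data.frame` as returned by [read_expression_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path) {
  write.table(expr[, c("gene_id", "log_fc", "p_value")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain-text gene list (one gene per line)
#'
#' Blank lines and `#` comments are skipped; surrounding whitespace trimmed;
#' duplicates removed.
#'
#' @param path Path to the file.
#' @return Character vector of gene identifiers.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop_mc("gene list not found: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}
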