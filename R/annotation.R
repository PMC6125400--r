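# Region-classification rules, strand-aware and half-open at the BED
# boundary (1-based closed internally):
#   tss:       any peak base within 100 bp of the TSS base
#   promoter:  peak overlaps [TSS-2000, TSS+200) in gene orientation
#   gene_body: peak overlaps the gene interval
#   intergenic: none of the above; the peak is tied to its nearest gene
# Precedence tss > promoter > gene_body > intergenic, so each (peak, gene)
# pair maps to exactly one class.

REGION_CLASSES <- c("tss", "promoter", "gene_body", "intergenic")

#' Classify where a peak falls relative to a gene
#'
#' @param peak,gene `GRanges` of equal length (or one of length 1,
#'   recycled); `gene` must be stranded gene models. Peak and gene must lie
#'   on the same chromosome.
#' @param tss_radius Maximum distance (bp) from any peak base to the TSS
#'   base for the `tss` class (default 100).
#' @param promoter_upstream,promoter_downstream Promoter window extent in bp
#'   upstream of / into the gene (defaults 2000 and 200).
#' @return Character vector of region classes.
#' @export
classify_region <- function(peak, gene, tss_radius = 100L,
                            promoter_upstream = 2000L,
                            promoter_downstream = 200L) {
  n <- max(length(peak), length(gene))
  if (length(peak) == 1L) peak <- rep(peak, n)
  if (length(gene) == 1L) gene <- rep(gene, n)
  if (length(peak) != length(gene)) {
    stop_mc("peak and gene must have compatible lengths")
  }
  if (any(as.character(seqnames(peak)) != as.character(seqnames(gene)))) {
    stop_mc("peak and gene on different chromosomes")
  }
  plus <- as.character(strand(gene)) == "+"
  tss <- ifelse(plus, start(gene), end(gene))
  dist0 <- tss_distance_abs(start(peak), end(peak), tss)
  # promoter window, 1-based closed in genome coordinates
  prom_lo <- ifelse(plus, tss - promoter_upstream,
                    tss - promoter_downstream + 1L)
  prom_hi <- ifelse(plus, tss + promoter_downstream - 1L,
                    tss + promoter_upstream)
  in_prom <- start(peak) <= prom_hi & end(peak) >= prom_lo
  in_body <- start(peak) <= end(gene) & end(peak) >= start(gene)
  out <- rep("intergenic", length(peak))
  out[in_body] <- "gene_body"
  out[in_prom] <- "promoter"
  out[dist0 <= tss_radius] <- "tss"
  out
}

# unsigned nearest-base distance from a peak to the TSS base (0 if covered)
tss_distance_abs <- function(pstart, pend, tss) {
  ifelse(pstart <= tss & tss <= pend, 0L,
         pmin(abs(pstart - tss), abs(pend - tss)))
}

#' Signed peak-to-TSS distance in gene orientation
#'
#' Nearest-base distance from the peak to the TSS base; 0 when the peak
#' covers the TSS, negative when the peak lies upstream of the TSS in gene
#' orientation, positive downstream.
#'
#' @inheritParams classify_region
#' @return Integer vector of signed distances.
#' @export
tss_distance <- function(peak, gene) {
  n <- max(length(peak), length(gene))
  if (length(peak) == 1L) peak <- rep(peak, n)
  if (length(gene) == 1L) gene <- rep(gene, n)
  plus <- as.character(strand(gene)) == "+"
  tss <- ifelse(plus, start(gene), end(gene))
  d <- tss_distance_abs(start(peak), end(peak), tss)
  genomic_sign <- ifelse(d == 0L, 0L, ifelse(start(peak) > tss, 1L, -1L))
  as.integer(d * genomic_sign * ifelse(plus, 1L, -1L))
}

#' Associate peaks with genes and classify each association
#'
#' Each peak is associated with every gene whose TSS window, promoter or
#' gene body it overlaps, nearest TSS first, up to `max_multi` genes. A peak
#' overlapping no such window is associated with its single nearest gene
#' (nearest by bp to the gene interval, ties broken by smaller gene start
#' then lexicographic `gene_id`) as `intergenic`. Genes may receive multiple
#' peaks.
#'
#' @param peaks `GRanges` of peaks (differential or otherwise).
#' @param genes Stranded `GRanges` of gene models with `gene_id`.
#' @param max_multi Maximum genes associated per peak (default 3).
#' @inheritParams classify_region
#' @return A `data.frame` with one row per association: `peak_id`, `chrom`,
#'   `start`, `end` (1-based closed), `gene_id`, `region_class`,
#'   `distance_bp`.
#' @export
associate_peaks_to_genes <- function(peaks, genes, max_multi = 3L,
                                     tss_radius = 100L,
                                     promoter_upstream = 2000L,
                                     promoter_downstream = 200L) {
  if (length(genes) == 0L) stop_mc("empty gene annotation")
  if (length(peaks) == 0L) {
    return(data.frame(peak_id = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      gene_id = character(0), region_class = character(0),
                      distance_bp = integer(0), stringsAsFactors = FALSE))
  }
  both <- harmonize_seqlevels(list(peaks, genes))
  peaks <- both[[1L]]
  genes <- both[[2L]]
  plus <- as.character(strand(genes)) == "+"
  tss <- ifelse(plus, start(genes), end(genes))
  # association window: union of gene body, promoter and TSS +/- radius
  win_lo <- pmin(start(genes),
                 ifelse(plus, tss - promoter_upstream,
                        tss - promoter_downstream + 1L),
                 tss - tss_radius)
  win_hi <- pmax(end(genes),
                 ifelse(plus, tss + promoter_downstream - 1L,
                        tss + promoter_upstream),
                 tss + tss_radius)
  windows <- GenomicRanges::GRanges(seqnames(genes),
                                    IRanges::IRanges(win_lo, win_hi))
  hits <- GenomicRanges::findOverlaps(peaks, windows, ignore.strand = TRUE)
  qi <- queryHits(hits)
  si <- subjectHits(hits)
  rows <- list()
  if (length(qi)) {
    cls <- classify_region(peaks[qi], genes[si], tss_radius,
                           promoter_upstream, promoter_downstream)
    dst <- tss_distance(peaks[qi], genes[si])
    keep <- cls != "intergenic"
    rows[[1L]] <- data.frame(peak_id = qi[keep],
                             gene_idx = si[keep],
                             region_class = cls[keep],
                             distance_bp = dst[keep],
                             stringsAsFactors = FALSE)
  }
  assoc <- if (length(rows)) rows[[1L]] else
    data.frame(peak_id = integer(0), gene_idx = integer(0),
               region_class = character(0), distance_bp = integer(0))
  # cap at max_multi nearest genes per peak, deterministically ordered
  if (nrow(assoc)) {
    ord <- order(assoc$peak_id, abs(assoc$distance_bp),
                 start(genes)[assoc$gene_idx],
                 mcols(genes)$gene_id[assoc$gene_idx])
    assoc <- assoc[ord, , drop = FALSE]
    rank_in_peak <- stats::ave(seq_len(nrow(assoc)), assoc$peak_id,
                               FUN = seq_along)
    assoc <- assoc[rank_in_peak <= max_multi, , drop = FALSE]
  }
  # peaks with no gene window hit -> nearest gene, intergenic
  unhit <- setdiff(seq_along(peaks), unique(assoc$peak_id))
  extra <- lapply(unhit, function(i) {
    same <- which(as.character(seqnames(genes)) ==
                    as.character(seqnames(peaks[i])))
    if (!length(same)) {
      warning("peak ", i, " has no gene on its chromosome; skipped",
              call. = FALSE)
      return(NULL)
    }
    gap <- GenomicRanges::distance(rep(peaks[i], length(same)), genes[same])
    best <- same[order(gap, start(genes)[same],
                       mcols(genes)$gene_id[same])][1L]
    data.frame(peak_id = i, gene_idx = best, region_class = "intergenic",
               distance_bp = tss_distance(peaks[i], genes[best]),
               stringsAsFactors = FALSE)
  })
  assoc <- rbind(assoc, do.call(rbind, extra))
  assoc <- assoc[order(assoc$peak_id, abs(assoc$distance_bp)), , drop = FALSE]
  data.frame(peak_id = assoc$peak_id,
             chrom = as.character(seqnames(peaks))[assoc$peak_id],
             start = start(peaks)[assoc$peak_id],
             end = end(peaks)[assoc$peak_id],
             gene_id = mcols(genes)$gene_id[assoc$gene_idx],
             region_class = assoc$region_class,
             distance_bp = as.integer(assoc$distance_bp),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarise peak-gene associations
#'
#' Counts associations per region class, reports `tss` + `promoter` jointly
#' as TSS-proximal, and tallies multi-gene peaks and multi-peak genes. All
#' counts are recomputable by filtering the association table.
#'
#' @param assocs Association table from [associate_peaks_to_genes()].
#' @return A list with `class_counts`, `tss_proximal`, `n_multi_gene_peaks`,
#'   `n_multi_peak_genes`.
#' @export
summarize_annotation <- function(assocs) {
  cls <- factor(assocs$region_class, levels = REGION_CLASSES)
  class_counts <- table(cls)
  genes_per_peak <- table(assocs$peak_id)
  peaks_per_gene <- table(assocs$gene_id)
  list(class_counts = setNames(as.integer(class_counts), REGION_CLASSES),
       tss_proximal = sum(cls %in% c("tss", "promoter")),
       n_multi_gene_peaks = sum(genes_per_peak >= 2L),
       n_multi_peak_genes = sum(peaks_per_gene >= 2L))
}

#' Write an association table to TSV
#'
#' Coordinates are written 1-based inclusive; the header comment says so.
#'
#' @param assocs Association table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(assocs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates are 1-based inclusive", con)
  write.table(assocs, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
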