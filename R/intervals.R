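#' Pairwise interval overlap predicate
#'
#' Two intervals overlap when they are on the same chromosome and share at
#' least `min_bp` bases. Arithmetic is half-open at the BED boundary, so
#' abutting peaks (`[100,200)` vs `[200,300)`) do not overlap.
#'
#' @param a,b `GRanges` of equal length (or one of length 1, recycled).
#' @param min_bp Minimum number of shared bases (default 1).
#' @return Logical vector.
#' @export
overlaps <- function(a, b, min_bp = 1L) {
  if (!is_count(min_bp) || min_bp < 1) stop_mc("min_bp must be a count >= 1")
  if (length(a) == 1L && length(b) > 1L) a <- rep(a, length(b))
  if (length(b) == 1L && length(a) > 1L) b <- rep(b, length(a))
  if (length(a) != length(b)) stop_mc("a and b must have compatible lengths")
  same <- as.character(seqnames(a)) == as.character(seqnames(b))
  ov <- pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L
  same & ov >= min_bp
}

#' Merge overlapping intervals
#'
#' Collapses overlapping peaks into disjoint intervals covering the same
#' bases. Abutting-but-not-overlapping intervals are kept separate, in
#' keeping with the half-open overlap convention.
#'
#' @param x A `GRanges`.
#' @return A sorted, disjoint `GRanges` with identical base coverage.
#' @export
merge_intervals <- function(x) {
  sort(GenomicRanges::reduce(x, min.gapwidth = 0L, ignore.strand = TRUE))
}

#' Build per-condition consensus regions
#'
#' A consensus region of a condition is an interval supported by a called
#' peak in *every* replicate of that condition. Construction: pool all
#' replicate peaks, merge them into disjoint candidate regions, and keep the
#' candidates that every replicate overlaps with at least one peak. The
#' construction is symmetric in replicate order and deterministic.
#'
#' @param replicates Named list of `GRanges`, one element per replicate.
#' @param condition Condition label recorded on the result.
#' @param min_bp Minimum overlap (bases) for a peak to support a candidate.
#' @return A `GRanges` of consensus regions with metadata columns
#'   `condition`, `n_replicates`, and `rep_support` (matrix of per-replicate
#'   supporting-peak counts).
#' @export
build_consensus <- function(replicates, condition = NA_character_,
                            min_bp = 1L) {
  if (!is.list(replicates) || length(replicates) == 0L) {
    stop_mc("at least one replicate is required")
  }
  if (is.null(names(replicates))) {
    names(replicates) <- paste0("rep", seq_along(replicates))
  }
  replicates <- harmonize_seqlevels(replicates)
  pooled <- unlist(GenomicRanges::GRangesList(unname(lapply(
    replicates, function(g) {
      mcols(g) <- NULL
      names(g) <- NULL
      g
    }))))
  # candidates are maximal runs of pooled base coverage, so book-ended peaks
  # from different replicates fuse into one candidate (per-base semantics;
  # merge_intervals(), by contrast, is strictly overlap-only)
  cand <- sort(GenomicRanges::reduce(pooled, ignore.strand = TRUE))
  supp <- vapply(replicates, function(rep) {
    GenomicRanges::countOverlaps(cand, rep, minoverlap = min_bp)
  }, integer(length(cand)))
  if (!is.matrix(supp)) {
    supp <- matrix(supp,
                   nrow = if (length(replicates) == 1L) length(cand) else 1L)
    colnames(supp) <- names(replicates)
  }
  keep <- rowSums(supp >= 1L) == length(replicates)
  out <- cand[keep]
  mcols(out) <- S4Vectors::DataFrame(
    condition = rep(condition, length(out)),
    n_replicates = rep(length(replicates), length(out)),
    rep_support = I(supp[keep, , drop = FALSE]))
  out
}

#' Cross-condition replicate-support tabulation
#'
#' For each consensus region of one condition, counts how many replicates of
#' the *other* condition have at least one overlapping peak, and tabulates
#' regions by that support level (0..n other replicates). This is the
#' spectrum used to judge how many consensus peaks of one condition are
#' fully, partially, or not at all reproduced in the other.
#'
#' @param consensus `GRanges` from [build_consensus()].
#' @param other_replicates Named list of `GRanges` peaks for the other
#'   condition's replicates (may be empty).
#' @param min_bp Minimum overlap in bases.
#' @return An object of class `support_histogram`: a list with `condition`,
#'   `counts` (named vector indexed `"0"`..`"n"`), `total`, and `support`
#'   (per-region other-condition support, aligned with `consensus`).
#' @export
support_histogram <- function(consensus, other_replicates, min_bp = 1L) {
  n_other <- length(other_replicates)
  if (n_other > 0L) {
    both <- harmonize_seqlevels(c(list(consensus), other_replicates))
    cons <- both[[1L]]
    reps <- both[-1L]
    supp_mat <- vapply(reps, function(rep) {
      GenomicRanges::countOverlaps(cons, rep, minoverlap = min_bp) >= 1L
    }, logical(length(cons)))
    if (!is.matrix(supp_mat)) {
      supp_mat <- matrix(supp_mat,
                         nrow = if (length(reps) == 1L) length(cons) else 1L)
    }
    support <- as.integer(rowSums(supp_mat))
  } else {
    support <- integer(length(consensus))
  }
  counts <- vapply(0:n_other, function(k) sum(support == k), integer(1L))
  names(counts) <- as.character(0:n_other)
  structure(list(condition = mcols(consensus)$condition[1] %||% NA_character_,
                 counts = counts, total = length(consensus),
                 support = support),
            class = "support_histogram")
}

#' @export
print.support_histogram <- function(x, ...) {
  cat("Replicate-support histogram",
      if (!is.na(x$condition)) paste0(" (consensus: ", x$condition, ")"),
      "\n", sep = "")
  cat("  total consensus regions:", x$total, "\n")
  tab <- data.frame(other_replicates = names(x$counts),
                    regions = as.integer(x$counts))
  if (x$total > 0) tab$percent <- summarize_overlap_fractions(x)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
plot.support_histogram <- function(x, ...) {
  barplot(x$counts, xlab = "other-condition replicates with overlap",
          ylab = "consensus regions", ...)
  invisible(x)
}

#' Percentages of consensus regions by replicate support
#'
#' Converts a support histogram to percentages of the total, rounded half-up
#' to two decimals (the convention used when such spectra are reported, e.g.
#' "77.21%").
#'
#' @param hist A `support_histogram`, or a bare named count vector plus
#'   `total` implied by its sum.
#' @return Named numeric vector of percentages, one per support level.
#' @export
summarize_overlap_fractions <- function(hist) {
  if (inherits(hist, "support_histogram")) {
    counts <- hist$counts
    total <- hist$total
  } else {
    counts <- hist
    total <- sum(hist)
  }
  if (is.na(total) || total <= 0) stop_mc("histogram total must be > 0")
  setNames(round_half_up(100 * counts / total, 2L), names(counts))
}
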