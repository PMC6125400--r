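#' Call condition-exclusive differential peaks
#'
#' The stringent replicate-consistency criterion for broad marks: a
#' differential peak is a consensus region of one condition (supported by
#' every one of its replicates) that is overlapped by peaks in at most
#' `max_other` replicates of the other condition. With the default
#' `max_other = 0` this is the all-of-one / none-of-the-other rule; calling
#' the function again with the conditions' roles swapped yields the peaks
#' exclusive to the other condition.
#'
#' @param consensus `GRanges` of consensus regions (see [build_consensus()]).
#' @param other_replicates Named list of `GRanges`, the other condition's
#'   per-replicate peaks.
#' @param max_other Maximum tolerated number of other-condition replicates
#'   with an overlapping peak (default 0; exposed for sensitivity analyses).
#' @param direction Direction label to record, e.g. `"gain_in_treatment"`.
#'   Defaults to `"gain_in_<condition>"` from the consensus metadata.
#' @param mark Optional mark label (e.g. `"H3K27me3"`) recorded on the calls.
#' @param min_bp Minimum overlap in bases.
#' @return A `GRanges` of differential peaks with metadata columns `mark`,
#'   `direction`, `support_own`, `support_other`.
#' @export
call_exclusive_peaks <- function(consensus, other_replicates, max_other = 0L,
                                 direction = NULL, mark = NA_character_,
                                 min_bp = 1L) {
  if (!is_count(max_other)) stop_mc("max_other must be a non-negative count")
  hist <- support_histogram(consensus, other_replicates, min_bp = min_bp)
  keep <- hist$support <= max_other
  out <- consensus[keep]
  cond <- mcols(consensus)$condition[1] %||% NA_character_
  direction <- direction %||% paste0("gain_in_", cond)
  n_own <- mcols(consensus)$n_replicates[1] %||% NA_integer_
  mcols(out) <- S4Vectors::DataFrame(
    mark = rep(mark, length(out)),
    direction = rep(direction, length(out)),
    support_own = rep(n_own, length(out)),
    support_other = hist$support[keep])
  out
}

#' Simple count-based differential binding test
#'
#' A transparent stand-in for dispersion-modelling differential binding
#' tools, for narrow marks where per-region read counts are available. Counts
#' are normalised to counts-per-million with a 0.5 pseudocount, the effect is
#' the difference of group means on the log2-CPM scale, the p-value comes
#' from a pooled-variance two-sample t test per region, and regions are
#' selected by Benjamini-Hochberg FDR. It makes no claim of equivalence to a
#' negative-binomial fit; it is the simplest defensible test of the same
#' shape.
#'
#' @param counts Non-negative integer matrix, regions x samples.
#' @param design Character (or factor) vector mapping each column of
#'   `counts` to a condition; exactly two conditions, each with >= 2 samples.
#' @param treatment Which condition is the treatment (effect = treatment -
#'   control). Defaults to the condition that is not `"control"`, or the
#'   second distinct value of `design`.
#' @param fdr_cut FDR threshold for calling (default 0.1).
#' @param all If `TRUE`, return every region with its statistics instead of
#'   only the calls passing `fdr_cut`.
#' @return A `data.frame` with columns `region`, `effect`, `p`, `fdr`,
#'   `direction` (`"increase"`/`"decrease"` by effect sign).
#' @export
score_differential_binding <- function(counts, design, treatment = NULL,
                                       fdr_cut = 0.1, all = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L) stop_mc("need >= 2 regions for FDR estimation")
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop_mc("counts must be non-negative integers")
  }
  design <- as.character(design)
  if (length(design) != ncol(counts)) {
    stop_mc("design must have one entry per sample column")
  }
  lev <- unique(design)
  if (length(lev) != 2L) stop_mc("design must have exactly two conditions")
  if (is.null(treatment)) {
    treatment <- if ("control" %in% lev) setdiff(lev, "control") else lev[2L]
  }
  if (!treatment %in% lev) stop_mc("treatment level not present in design")
  control <- setdiff(lev, treatment)
  if (sum(design == treatment) < 2L || sum(design == control) < 2L) {
    stop_mc("each condition needs >= 2 samples")
  }
  libsize <- colSums(counts)
  if (any(libsize == 0)) {
    stop_mc("sample(s) with zero total counts: ",
            paste(which(libsize == 0), collapse = ", "))
  }
  logcpm <- log2(sweep(counts + 0.5, 2L, libsize, "/") * 1e6)
  tt <- row_t_stats(logcpm[, design == treatment, drop = FALSE],
                    logcpm[, design == control, drop = FALSE])
  fdr <- p.adjust(tt$p, method = "BH")
  region <- rownames(counts) %||% as.character(seq_len(nrow(counts)))
  res <- data.frame(region = region, effect = tt$effect, p = tt$p, fdr = fdr,
                    direction = ifelse(tt$effect >= 0, "increase", "decrease"),
                    stringsAsFactors = FALSE)
  res$direction[res$effect == 0] <- NA_character_
  if (all) res else res[res$fdr <= fdr_cut & !is.na(res$direction), ,
                        drop = FALSE]
}

# Row-wise pooled-variance two-sample t tests (treatment minus control),
# vectorised with matrix arithmetic. Degenerate rows with zero pooled
# variance get p = 1 when the effect is also zero, else p = 0.
row_t_stats <- function(xt, xc) {
  n1 <- ncol(xt)
  n2 <- ncol(xc)
  m1 <- rowMeans(xt)
  m2 <- rowMeans(xc)
  v1 <- rowSums((xt - m1)^2) / (n1 - 1L)
  v2 <- rowSums((xc - m2)^2) / (n2 - 1L)
  sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  effect <- m1 - m2
  tstat <- effect / se
  p <- 2 * pt(-abs(tstat), df = n1 + n2 - 2L)
  deg <- se == 0
  p[deg] <- ifelse(effect[deg] == 0, 1, 0)
  list(effect = effect, t = tstat, p = p, df = n1 + n2 - 2L)
}

#' Tally differential-peak directions
#'
#' Counts increases and decreases among direction-labelled differential
#' peaks and reports the percentage decreased, rounded half-up to the
#' nearest integer. Exclusive-call labels map to directions from the
#' treatment's point of view: `gain_in_treatment` is an increase,
#' `gain_in_control` a decrease.
#'
#' @param directions Character vector of direction labels, or a `GRanges` /
#'   `data.frame` with a `direction` column.
#' @return A list with `n_increase`, `n_decrease`, `pct_decrease`.
#' @export
summarize_directions <- function(directions) {
  if (inherits(directions, "GRanges")) directions <- mcols(directions)$direction
  if (is.data.frame(directions)) directions <- directions$direction
  directions <- as.character(directions)
  inc <- c("increase", "gain_in_treatment")
  dec <- c("decrease", "gain_in_control")
  unknown <- setdiff(unique(directions), c(inc, dec))
  if (length(unknown)) stop_mc("unknown direction label(s): ",
                               paste(unknown, collapse = ", "))
  n_inc <- sum(directions %in% inc)
  n_dec <- sum(directions %in% dec)
  if (n_inc + n_dec == 0L) stop_mc("no direction-labelled peaks")
  list(n_increase = n_inc, n_decrease = n_dec,
       pct_decrease = round_half_up(100 * n_dec / (n_inc + n_dec)))
}
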