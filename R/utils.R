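# internal helpers shared across modules

# round-half-up (base round() is round-half-even; printed report percentages
# such as 77.21 use the conventional half-up rule)
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mc <- function(...) stop(..., call. = FALSE)

# Build an unstranded GRanges from 1-based closed coordinates with
# lexicographically sorted seqlevels so that sort() is total and reproducible.
mc_granges <- function(chrom, start, end, ...) {
  lv <- sort(unique(as.character(chrom)))
  gr <- GenomicRanges::GRanges(
    seqnames = factor(as.character(chrom), levels = lv),
    ranges = IRanges::IRanges(start = start, end = end)
  )
  extra <- list(...)
  if (length(extra)) {
    for (nm in names(extra)) mcols(gr)[[nm]] <- extra[[nm]]
  }
  gr
}

# Re-level seqnames of a GRanges to the sorted union of several GRanges so
# that ranges from different files compare and sort deterministically.
harmonize_seqlevels <- function(grl) {
  lv <- sort(unique(unlist(lapply(grl, function(g) as.character(seqnames(g))))))
  lapply(grl, function(g) {
    GenomicRanges::GRanges(
      seqnames = factor(as.character(seqnames(g)), levels = lv),
      ranges = IRanges::ranges(g),
      strand = strand(g),
      mcols(g)
    )
  })
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}
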