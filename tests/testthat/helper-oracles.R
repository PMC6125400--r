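# Brute-force oracles, deliberately independent of the package's interval
# machinery: everything here works on per-base sets or exhaustive pair scans.

library(GenomicRanges)

gr1 <- function(chrom, start, end, strand = "*") {
  g <- GRanges(chrom, IRanges(start, end))
  BiocGenerics::strand(g) <- strand
  g
}

# set of covered bases, encoded chrom-index * 1e7 + position (all test
# genomes use chr1..chr26 names and positions < 1e7)
base_set <- function(gr) {
  if (length(gr) == 0) return(numeric(0))
  ch <- match(as.character(seqnames(gr)), paste0("chr", 1:26))
  stopifnot(!anyNA(ch))
  unlist(lapply(seq_along(gr), function(i) {
    ch[i] * 1e7 + seq(start(gr)[i], end(gr)[i])
  }))
}

brute_overlap <- function(a, b, min_bp = 1) {
  length(intersect(base_set(a), base_set(b))) >= min_bp
}

# merged runs of covered bases per chromosome, returned as a data.frame
brute_merge <- function(gr) {
  out <- NULL
  for (ch in sort(unique(as.character(seqnames(gr))))) {
    pos <- sort(unique(unlist(lapply(which(as.character(seqnames(gr)) == ch),
                                     function(i) seq(start(gr)[i], end(gr)[i])))))
    if (!length(pos)) next
    brk <- c(0, which(diff(pos) > 1), length(pos))
    for (j in seq_len(length(brk) - 1)) {
      run <- pos[(brk[j] + 1):brk[j + 1]]
      out <- rbind(out, data.frame(chrom = ch, start = min(run),
                                   end = max(run)))
    }
  }
  out
}

# consensus oracle: merged pooled runs kept when every replicate covers >= 1
# base of the run (min_bp = 1 semantics)
brute_consensus <- function(replicates) {
  pooled <- do.call(c, unname(lapply(replicates, function(g) {
    mcols(g) <- NULL
    names(g) <- NULL
    g
  })))
  runs <- brute_merge(pooled)
  if (is.null(runs)) return(runs)
  keep <- vapply(seq_len(nrow(runs)), function(i) {
    run <- gr1(runs$chrom[i], runs$start[i], runs$end[i])
    all(vapply(replicates, function(rep) brute_overlap(run, rep), logical(1)))
  }, logical(1))
  runs[keep, , drop = FALSE]
}

brute_support <- function(regions, reps) {
  vapply(seq_along(regions), function(i) {
    sum(vapply(reps, function(rep) brute_overlap(regions[i], rep),
               logical(1)))
  }, integer(1))
}

# all-pairs region classification by base-set membership
brute_classify <- function(peak, gene, tss_radius = 100,
                           up = 2000, down = 200) {
  pl <- as.character(strand(gene)) == "+"
  tss <- if (pl) start(gene) else end(gene)
  pbase <- seq(start(peak), end(peak))
  if (min(abs(pbase - tss)) <= tss_radius) return("tss")
  prom <- if (pl) seq(tss - up, tss + down - 1) else seq(tss - down + 1, tss + up)
  if (length(intersect(pbase, prom))) return("promoter")
  if (length(intersect(pbase, seq(start(gene), end(gene))))) return("gene_body")
  "intergenic"
}

brute_tss_distance <- function(peak, gene) {
  pl <- as.character(strand(gene)) == "+"
  tss <- if (pl) start(gene) else end(gene)
  pbase <- seq(start(peak), end(peak))
  d <- min(abs(pbase - tss))
  if (d == 0) return(0L)
  genomic <- if (pbase[which.min(abs(pbase - tss))] > tss) 1L else -1L
  as.integer(d * genomic * if (pl) 1L else -1L)
}

# exhaustive hypergeometric upper tail: probability that a random size-n
# subset of the universe shares >= k members with the prior set
enum_hypergeom <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(d) sum(d <= K) >= k))
}

random_peaks <- function(n, chroms = "chr1", max_pos = 3000, max_w = 40) {
  ch <- sample(chroms, n, replace = TRUE)
  s <- sample.int(max_pos, n, replace = TRUE)
  w <- sample.int(max_w, n, replace = TRUE)
  gr1(ch, s, s + w - 1)
}

# small, fast simulation configs used across tests
tiny_config <- function(...) {
  args <- utils::modifyList(list(
    n_chroms = 2L, chrom_length = 1.5e6, n_genes = 40L,
    n_shared = 100L, n_exclusive_treatment = 10L, n_exclusive_control = 5L,
    partial_spec = list(c(8L, 1L), c(8L, 2L), c(8L, 3L)),
    peak_width_range = c(300L, 800L), gene_length_range = c(2000L, 6000L),
    seed = 11L), list(...))
  do.call(sim_config, args)
}
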