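test_that("generator is deterministic under a fixed seed", {
  cfg <- tiny_config(seed = 3L)
  g1 <- simulate_annotation(cfg)
  g2 <- simulate_annotation(cfg)
  expect_identical(g1, g2)
  e1 <- simulate_peak_experiment(cfg, g1)
  e2 <- simulate_peak_experiment(cfg, g2)
  expect_identical(e1$truth, e2$truth)
  expect_identical(e1$peaks$control$rep1, e2$peaks$control$rep1)
  x1 <- simulate_expression(cfg, g1, e1$truth)
  x2 <- simulate_expression(cfg, g2, e2$truth)
  expect_identical(x1, x2)
})

test_that("annotation generator: degenerate and non-overlap guarantees", {
  expect_equal(length(simulate_annotation(tiny_config(n_genes = 0L))), 0L)
  # 50 genes on a 1 Mb chromosome: all-pairs scan finds no overlapping pair
  cfg <- tiny_config(n_chroms = 1L, chrom_length = 1e6, n_genes = 50L,
                     gene_length_range = c(1000L, 3000L),
                     peak_width_range = c(100L, 300L))
  genes <- simulate_annotation(cfg)
  expect_equal(length(genes), 50L)
  n_olap <- 0L
  for (i in seq_along(genes)) {
    for (j in seq_along(genes)) {
      if (i < j &&
          start(genes)[i] <= end(genes)[j] &&
          end(genes)[i] >= start(genes)[j]) {
        n_olap <- n_olap + 1L
      }
    }
  }
  expect_equal(n_olap, 0L)
  # sizing error names the required length
  expect_error(simulate_annotation(tiny_config(chrom_length = 1e4)),
               "genome too small")
})

test_that("noise-free limit gives byte-identical replicate coordinates", {
  cfg <- tiny_config(jitter_sd = 0, drop_prob = 0)
  ex <- simulate_peak_experiment(cfg, simulate_annotation(cfg))
  # control replicates carry every control-side region identically; in the
  # treatment condition, partial-support regions differ by design, so the
  # comparison excludes them there
  partial_ids <- ex$truth$region_id[startsWith(ex$truth$class, "partial")]
  for (cond in names(ex$peaks)) {
    full <- cond == names(ex$peaks)[1]  # control hosts all partial regions
    for (r in 2:4) {
      a <- ex$peaks[[cond]][[r]]
      b <- ex$peaks[[cond]][[1]]
      if (!full) {
        a <- a[!mcols(a)$name %in% partial_ids]
        b <- b[!mcols(b)$name %in% partial_ids]
      }
      expect_identical(ranges(a), ranges(b))
    }
  }
})

test_that("planted exclusive regions touch zero other-condition peaks", {
  cfg <- tiny_config(n_exclusive_treatment = 25L, jitter_sd = 20,
                     drop_prob = 0)
  ex <- simulate_peak_experiment(cfg, simulate_annotation(cfg))
  tr <- ex$truth[ex$truth$class == "exclusive_treatment", ]
  expect_equal(nrow(tr), 25L)
  # all-pairs scan against every control-replicate peak, plain arithmetic
  for (rep in ex$peaks$control) {
    df <- data.frame(chrom = as.character(seqnames(rep)),
                     start = start(rep), end = end(rep))
    for (i in seq_len(nrow(tr))) {
      hits <- df$chrom == tr$chrom[i] & df$start <= tr$end[i] &
        df$end >= tr$start[i]
      expect_equal(sum(hits), 0L)
    }
  }
})

test_that("shared-peak replicate support follows the binomial expectation", {
  cfg <- tiny_config(n_shared = 1000L, n_exclusive_treatment = 0L,
                     n_exclusive_control = 0L, partial_spec = list(),
                     drop_prob = 0.1, chrom_length = 3e6)
  ex <- simulate_peak_experiment(cfg, simulate_annotation(cfg))
  shared_ids <- ex$truth$region_id[ex$truth$class == "shared"]
  in_all4 <- rowSums(vapply(ex$peaks$control, function(rep)
    shared_ids %in% mcols(rep)$name, logical(length(shared_ids)))) == 4L
  p <- 0.9^4
  expect_lt(abs(mean(in_all4) - p), 3 * sqrt(p * (1 - p) / 1000))
})

test_that("null expression p-values are uniform", {
  cfg <- tiny_config(n_chroms = 4L, chrom_length = 1.5e7, n_genes = 10000L,
                     n_shared = 0L, n_exclusive_treatment = 0L,
                     n_exclusive_control = 0L, partial_spec = list(),
                     gene_length_range = c(100L, 200L),
                     peak_width_range = c(50L, 100L))
  genes <- simulate_annotation(cfg)
  expr <- simulate_expression(cfg, genes, truth = NULL)
  frac <- mean(expr$p_value < 0.01)
  expect_lt(abs(frac - 0.01), 3 * sqrt(0.01 * 0.99 / 10000))
})

test_that("zero effect size makes planted genes indistinguishable from null", {
  n_sig <- 0L
  for (s in 1:10) {
    cfg <- tiny_config(seed = 100L + s)
    genes <- simulate_annotation(cfg)
    ex <- simulate_peak_experiment(cfg, genes)
    expr <- simulate_expression(cfg, genes, ex$truth, effect_size = 0)
    planted <- names(attr(expr, "planted"))
    ks <- suppressWarnings(stats::ks.test(
      expr$log_fc[expr$gene_id %in% planted],
      expr$log_fc[!expr$gene_id %in% planted]))
    if (ks$p.value < 0.01) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig, 1L)
})

test_that("expression truth linkage validates gene ids", {
  cfg <- tiny_config()
  genes <- simulate_annotation(cfg)
  truth <- data.frame(region_id = "r1", chrom = "chr1", start = 1L,
                      end = 10L, class = "exclusive_treatment", k_other = 0L,
                      gene_id = "NOT_A_GENE", mark = "H3K4me3",
                      stringsAsFactors = FALSE)
  expect_error(simulate_expression(cfg, genes, truth), "absent from annotation")
})
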