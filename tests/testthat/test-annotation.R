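test_that("classification rules on the plus strand", {
  gene <- gr1("chr1", 10000, 14000, "+")  # TSS at 10000
  expect_equal(classify_region(gr1("chr1", 9950, 10050), gene), "tss")
  # BED [8200,9500) -> promoter window [TSS-2000, TSS+200)
  expect_equal(classify_region(gr1("chr1", 8201, 9500), gene), "promoter")
  expect_equal(classify_region(gr1("chr1", 12000, 12100), gene), "gene_body")
  expect_equal(classify_region(gr1("chr1", 20000, 20100), gene), "intergenic")
  expect_error(classify_region(gr1("chr2", 1, 10), gene), "chromosome")
})

test_that("minus-strand classification agrees with the reflected plus rule", {
  # reflect coordinates around M and flip the strand: classes must agree
  M <- 50000
  set.seed(31)
  for (i in 1:40) {
    gs <- sample(5000:20000, 1)
    ge <- gs + sample(1000:5000, 1)
    ps <- sample(3000:28000, 1)
    pe <- ps + sample(50:800, 1)
    minus <- classify_region(gr1("chr1", ps, pe),
                             gr1("chr1", gs, ge, "-"))
    plus_reflected <- classify_region(gr1("chr1", M - pe, M - ps),
                                      gr1("chr1", M - ge, M - gs, "+"))
    expect_equal(minus, plus_reflected)
    expect_equal(tss_distance(gr1("chr1", ps, pe), gr1("chr1", gs, ge, "-")),
                 tss_distance(gr1("chr1", M - pe, M - ps),
                              gr1("chr1", M - ge, M - gs, "+")))
  }
  # worked minus-strand cases: gene BED [1000,5000) on -, TSS base 5000
  gene <- gr1("chr1", 1001, 5000, "-")
  expect_equal(classify_region(gr1("chr1", 5601, 6900), gene), "promoter")
  expect_equal(classify_region(gr1("chr1", 201, 900), gene), "intergenic")
})

test_that("classification matches the per-base oracle and is total", {
  set.seed(17)
  for (i in 1:60) {
    gs <- sample(3000:8000, 1)
    ge <- gs + sample(500:4000, 1)
    st <- sample(c("+", "-"), 1)
    ps <- sample(1:12000, 1)
    pe <- ps + sample(20:500, 1)
    got <- classify_region(gr1("chr1", ps, pe), gr1("chr1", gs, ge, st))
    expect_equal(got, brute_classify(gr1("chr1", ps, pe),
                                     gr1("chr1", gs, ge, st)))
    expect_true(got %in% c("tss", "promoter", "gene_body", "intergenic"))
  }
})

test_that("association table equals the all-pairs brute-force oracle", {
  set.seed(23)
  genes <- gr1(rep(c("chr1", "chr2"), each = 10),
               seq(10000, by = 20000, length.out = 20),
               seq(10000, by = 20000, length.out = 20) +
                 sample(2000:8000, 20, replace = TRUE),
               sample(c("+", "-"), 20, replace = TRUE))
  mcols(genes)$gene_id <- sprintf("G%02d", 1:20)
  peaks <- random_peaks(120, chroms = c("chr1", "chr2"),
                        max_pos = 400000, max_w = 3000)
  assoc <- associate_peaks_to_genes(peaks, genes, max_multi = 20L)
  for (i in seq_along(peaks)) {
    same <- which(as.character(seqnames(genes)) ==
                    as.character(seqnames(peaks[i])))
    cls <- vapply(same, function(j)
      brute_classify(peaks[i], genes[j]), character(1))
    hits <- same[cls != "intergenic"]
    rows <- assoc[assoc$peak_id == i, ]
    if (length(hits)) {
      expect_setequal(rows$gene_id, mcols(genes)$gene_id[hits])
      for (j in hits) {
        r <- rows[rows$gene_id == mcols(genes)$gene_id[j], ]
        expect_equal(r$region_class, cls[match(j, same)])
        expect_equal(r$distance_bp, brute_tss_distance(peaks[i], genes[j]))
      }
    } else {
      # nearest gene by bp, intergenic
      expect_equal(nrow(rows), 1L)
      expect_equal(rows$region_class, "intergenic")
      gaps <- vapply(same, function(j)
        max(0L, max(start(genes)[j] - end(peaks)[i],
                    start(peaks)[i] - end(genes)[j])), integer(1))
      expect_equal(min(gaps), max(0L, max(
        start(genes)[match(rows$gene_id, mcols(genes)$gene_id)] -
          end(peaks)[i],
        start(peaks)[i] -
          end(genes)[match(rows$gene_id, mcols(genes)$gene_id)])))
    }
  }
})

test_that("multi-gene peaks, the max_multi cap, and error cases", {
  genes <- gr1("chr1", c(10000, 13000), c(12000, 16000), c("-", "+"))
  mcols(genes)$gene_id <- c("GA", "GB")
  # peak spanning GA's downstream promoter and GB's upstream promoter
  peak <- gr1("chr1", 12400, 12600)
  assoc <- associate_peaks_to_genes(peak, genes)
  expect_setequal(assoc$gene_id, c("GA", "GB"))
  expect_equal(nrow(associate_peaks_to_genes(peak, genes, max_multi = 1L)), 1L)
  expect_error(associate_peaks_to_genes(peak, genes[0]), "empty gene")
})

test_that("annotation summary counts are recomputable and handle empties", {
  assoc <- data.frame(
    peak_id = c(1, 1, 2, 3, 4, 5),
    chrom = "chr1", start = 1L, end = 2L,
    gene_id = c("A", "B", "A", "C", "D", "E"),
    region_class = c("tss", "promoter", "gene_body", "tss", "intergenic",
                     "promoter"),
    distance_bp = 0L)
  s <- summarize_annotation(assoc)
  expect_equal(s$class_counts[["tss"]], 2L)
  expect_equal(s$tss_proximal, 4L)
  expect_equal(s$n_multi_gene_peaks, 1L)   # peak 1 has two genes
  expect_equal(s$n_multi_peak_genes, 1L)   # gene A has two peaks
  s0 <- summarize_annotation(assoc[0, ])
  expect_true(all(s0$class_counts == 0L))
  expect_equal(s0$tss_proximal, 0L)
})

test_that("planted promoter placements are recovered exactly without jitter", {
  cfg <- tiny_config(jitter_sd = 0, drop_prob = 0)
  genes <- simulate_annotation(cfg)
  ex <- simulate_peak_experiment(cfg, genes)
  cons_t <- build_consensus(ex$peaks$ethanol, condition = "ethanol")
  calls <- call_exclusive_peaks(cons_t, ex$peaks$control,
                                direction = "gain_in_treatment")
  assoc <- associate_peaks_to_genes(calls, genes)
  expect_equal(nrow(assoc), cfg$n_exclusive_treatment)
  expect_true(all(assoc$region_class == "promoter"))
  planted <- ex$truth$gene_id[ex$truth$class == "exclusive_treatment"]
  expect_setequal(assoc$gene_id, planted)
})
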