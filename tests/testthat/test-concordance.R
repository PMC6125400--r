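test_that("DE selection uses p < cut and the sign of the fold-change", {
  expr <- data.frame(gene_id = c("Ezr", "Pard3", "Flat", "Null"),
                     log_fc = c(0.208, -0.302, 0, 0.5),
                     p_value = c(0.0003, 0.0084, 0.001, 0.5))
  expect_warning(de <- select_de_genes(expr), "zero log_fc")
  expect_equal(de[["Ezr"]], "up")
  expect_equal(de[["Pard3"]], "down")
  expect_false("Flat" %in% names(de))
  expect_false("Null" %in% names(de))
  expect_equal(length(select_de_genes(expr, p_cut = 0)), 0L)
})

test_that("the 9-case direction prediction table matches hand enumeration", {
  k4 <- rep(c("none", "increase", "decrease"), each = 3)
  k27 <- rep(c("none", "gain_treatment", "gain_control"), times = 3)
  expect_equal(predict_direction(k4, k27),
               c("none", "down", "up",
                 "up", "ambiguous", "up",
                 "down", "down", "ambiguous"))
  expect_error(predict_direction("sideways", "none"), "invalid k4")
})

test_that("gene-level collapse keeps clean genes and flags conflicts", {
  st <- collapse_gene_status(c("A", "A", "B", "C", "C"),
                             c("increase", "increase", "decrease",
                               "increase", "decrease"))
  expect_equal(st$status[["A"]], "increase")
  expect_equal(st$status[["B"]], "decrease")
  expect_equal(st$conflicts, "C")
})

test_that("concordance matrix reproduces study-shaped dual-mark overlap", {
  # 294 K4 genes (112 up / rest down including the three dual-mark genes),
  # 245 K27 genes (209 treatment-gain / 36 control-gain); the overlap is
  # exactly Trp63, Wnt5a, Lhfpl3, all (decrease, gain_treatment)
  dual <- c("Trp63", "Wnt5a", "Lhfpl3")
  k4 <- setNames(rep(c("increase", "decrease"), c(112, 182)),
                 paste0("k4_", 1:294))
  names(k4)[113:115] <- dual
  k27 <- setNames(rep(c("gain_treatment", "gain_control"), c(209, 36)),
                  paste0("k27_", 1:245))
  names(k27)[1:3] <- dual
  cm <- build_concordance_matrix(k4, k27, setNames(character(0), character(0)))
  expect_equal(unname(cm$core["decrease", "gain_treatment"]), 3L)
  expect_equal(unname(cm$core["increase", "gain_treatment"]), 0L)
  expect_setequal(cm$dual_mark_genes, dual)
  # marginals equal the input set sizes
  expect_equal(sum(cm$core[, "gain_treatment"]) +
                 sum(cm$core[, "gain_control"]), 245L)
  expect_equal(sum(cm$core["increase", ]) + sum(cm$core["decrease", ]), 294L)
})

test_that("matrix cells equal brute-force triple intersections", {
  set.seed(41)
  genes <- sprintf("g%03d", 1:200)
  k4 <- setNames(sample(c("increase", "decrease"), 60, replace = TRUE),
                 sample(genes, 60))
  k27 <- setNames(sample(c("gain_treatment", "gain_control"), 50,
                         replace = TRUE), sample(genes, 50))
  de <- setNames(sample(c("up", "down"), 40, replace = TRUE),
                 sample(genes, 40))
  cm <- build_concordance_matrix(k4, k27, de)
  for (a in c("none", "increase", "decrease")) {
    for (b in c("none", "gain_treatment", "gain_control")) {
      universe <- unique(c(names(k4), names(k27), names(de)))
      in_a <- if (a == "none") setdiff(universe, names(k4))
              else names(k4)[k4 == a]
      in_b <- if (b == "none") setdiff(universe, names(k27))
              else names(k27)[k27 == b]
      expect_equal(unname(cm$core[a, b]), length(intersect(in_a, in_b)))
    }
  }
  # disjoint universes: all cross cells zero
  cm2 <- build_concordance_matrix(
    setNames("increase", "only_k4"), setNames("gain_treatment", "only_k27"),
    setNames("up", "only_de"))
  expect_equal(unname(cm2$core["increase", "gain_treatment"]), 0L)
  expect_equal(unname(cm2$k4_expr["increase", "up"]), 0L)
})

test_that("conflicting gene statuses are rejected by the matrix builder", {
  expect_error(build_concordance_matrix(
    setNames(c("increase", "decrease"), c("A", "A")),
    setNames(character(0), character(0)),
    setNames(character(0), character(0))), "uniquely named")
})

test_that("observed expression is checked against the predicted direction", {
  k4 <- setNames(c("increase", "decrease", "increase"),
                 c("Ezr", "Calu", "Disc"))
  k27 <- setNames(character(0), character(0))
  de <- setNames(c("up", "down", "down"), c("Ezr", "Calu", "Disc"))
  st <- gene_mark_status(k4, k27, de)
  fc <- find_concordant_genes(st)
  expect_true(fc$concordant[fc$gene_id == "Ezr"])    # K4 up, expression up
  expect_true(fc$concordant[fc$gene_id == "Calu"])   # K4 down, expression down
  expect_false(fc$concordant[fc$gene_id == "Disc"])  # K4 up, expression down
})

test_that("strong planted effects give fully concordant mark-linked DE genes", {
  cfg <- tiny_config(jitter_sd = 0, drop_prob = 0)
  sim <- simulate_dataset(cfg, effect_size = 1, null_sd = 0.1)
  de <- select_de_genes(sim$expression)
  planted <- attr(sim$expression, "planted")
  expect_true(all(names(planted) %in% names(de)))  # full power at effect 1
  k4_linked <- sim$k4$truth[!is.na(sim$k4$truth$gene_id), ]
  k4 <- setNames(ifelse(k4_linked$class == "exclusive_treatment",
                        "increase", "decrease"), k4_linked$gene_id)
  k27_linked <- sim$k27$truth[!is.na(sim$k27$truth$gene_id), ]
  k27 <- setNames(ifelse(k27_linked$class == "exclusive_treatment",
                         "gain_treatment", "gain_control"),
                  k27_linked$gene_id)
  fc <- find_concordant_genes(gene_mark_status(k4, k27, de))
  linked_de <- fc[fc$gene_id %in% names(planted), ]
  expect_gt(nrow(linked_de), 0L)
  expect_true(all(linked_de$concordant))
})
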