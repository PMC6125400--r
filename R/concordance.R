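# Gene-level integration of the two marks and differential expression.
# Statuses:
#   k4   in {none, increase, decrease}            (narrow activating mark)
#   k27  in {none, gain_treatment, gain_control}  (broad repressive mark)
#   expr in {none, up, down}
# The biological prediction: more H3K4me3 -> expression up; H3K27me3 gained
# in the treatment -> expression down (and the mirror images).

K4_LEVELS <- c("none", "increase", "decrease")
K27_LEVELS <- c("none", "gain_treatment", "gain_control")
EXPR_LEVELS <- c("none", "up", "down")

#' Select differentially expressed genes
#'
#' Genes with `p_value < p_cut` (unadjusted, matching the platform-level
#' convention of the source analyses); direction is the sign of `log_fc`,
#' with no magnitude threshold. Genes with exactly zero `log_fc` below the
#' cut are excluded with a warning, as their direction is undefined.
#'
#' @param expression `data.frame` with `gene_id`, `log_fc`, `p_value`.
#' @param p_cut Unadjusted p-value cutoff (default 0.01).
#' @return Named character vector (`"up"`/`"down"`), names are gene ids.
#' @export
select_de_genes <- function(expression, p_cut = 0.01) {
  sel <- expression$p_value < p_cut
  zero <- sel & expression$log_fc == 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) with zero log_fc below p_cut excluded",
            call. = FALSE)
    sel <- sel & !zero
  }
  setNames(ifelse(expression$log_fc[sel] > 0, "up", "down"),
           expression$gene_id[sel])
}

#' Predicted expression direction from mark statuses
#'
#' Pure function of the 9 (k4 x k27) combinations: each mark maps to a
#' direction vote (k4 increase -> up, k4 decrease -> down, k27 gained in
#' treatment -> down, k27 gained in control -> up); agreeing votes give that
#' direction, conflicting votes give `"ambiguous"`, no votes give `"none"`.
#'
#' @param k4 Character vector in `none`/`increase`/`decrease`.
#' @param k27 Character vector in `none`/`gain_treatment`/`gain_control`.
#' @return Character vector in `up`/`down`/`ambiguous`/`none`.
#' @export
predict_direction <- function(k4, k27) {
  n <- max(length(k4), length(k27))
  k4 <- rep_len(as.character(k4), n)
  k27 <- rep_len(as.character(k27), n)
  if (!all(k4 %in% K4_LEVELS)) stop_mc("invalid k4 status")
  if (!all(k27 %in% K27_LEVELS)) stop_mc("invalid k27 status")
  v4 <- c(none = "none", increase = "up", decrease = "down")[k4]
  v27 <- c(none = "none", gain_treatment = "down", gain_control = "up")[k27]
  out <- ifelse(v4 == "none", v27,
                ifelse(v27 == "none", v4,
                       ifelse(v4 == v27, v4, "ambiguous")))
  unname(out)
}

#' Collapse peak-level directions to one status per gene
#'
#' A gene carrying several same-direction peaks of one mark gets that
#' direction; a gene with mixed directions for the same mark is a conflict,
#' excluded from downstream tables and reported separately.
#'
#' @param gene_ids Character vector, one entry per differential peak.
#' @param directions Parallel character vector of peak direction labels.
#' @return A list with `status` (named vector, one direction per clean gene)
#'   and `conflicts` (character vector of excluded gene ids).
#' @export
collapse_gene_status <- function(gene_ids, directions) {
  stopifnot(length(gene_ids) == length(directions))
  spl <- split(as.character(directions), as.character(gene_ids))
  uniq <- lapply(spl, unique)
  conflicts <- names(uniq)[lengths(uniq) > 1L]
  clean <- uniq[lengths(uniq) == 1L]
  list(status = unlist(clean) %||% setNames(character(0), character(0)),
       conflicts = conflicts)
}

#' Build the two-mark by expression concordance matrix
#'
#' Cross-tabulates gene-level H3K4me3 status, H3K27me3 status and
#' differential-expression direction over the union of the three input gene
#' sets. Every cell is a plain set-intersection count; marginal totals equal
#' the input set sizes. The dual-mark gene list (both marks changed) is
#' returned alongside.
#'
#' @param k4_status Named vector, gene -> `increase`/`decrease`.
#' @param k27_status Named vector, gene -> `gain_treatment`/`gain_control`.
#' @param de_status Named vector, gene -> `up`/`down` (see
#'   [select_de_genes()]).
#' @return An object of class `concordance_matrix`: list with `core`
#'   (3x3 table k4 x k27), `k4_expr`, `k27_expr` tables, `dual_mark_genes`,
#'   and `totals`.
#' @export
build_concordance_matrix <- function(k4_status, k27_status, de_status) {
  check_status <- function(x, levels, what) {
    if (length(x) && (is.null(names(x)) || anyDuplicated(names(x)))) {
      stop_mc(what, " must be uniquely named by gene")
    }
    if (!all(x %in% levels)) stop_mc("invalid ", what, " value(s)")
  }
  check_status(k4_status, K4_LEVELS[-1L], "k4_status")
  check_status(k27_status, K27_LEVELS[-1L], "k27_status")
  check_status(de_status, EXPR_LEVELS[-1L], "de_status")
  genes <- unique(c(names(k4_status), names(k27_status), names(de_status)))
  k4 <- factor(unname(ifelse(genes %in% names(k4_status),
                             k4_status[genes], "none")), levels = K4_LEVELS)
  k27 <- factor(unname(ifelse(genes %in% names(k27_status),
                              k27_status[genes], "none")), levels = K27_LEVELS)
  expr <- factor(unname(ifelse(genes %in% names(de_status),
                               de_status[genes], "none")),
                 levels = EXPR_LEVELS)
  structure(list(
    core = table(k4 = k4, k27 = k27),
    k4_expr = table(k4 = k4, expr = expr),
    k27_expr = table(k27 = k27, expr = expr),
    dual_mark_genes = genes[k4 != "none" & k27 != "none"],
    totals = c(k4 = length(k4_status), k27 = length(k27_status),
               expr = length(de_status)),
    genes = data.frame(gene_id = genes, k4 = as.character(k4),
                       k27 = as.character(k27), expr = as.character(expr),
                       stringsAsFactors = FALSE)
  ), class = "concordance_matrix")
}

#' @export
print.concordance_matrix <- function(x, ...) {
  cat("Concordance matrix (genes)\n\nH3K4me3 x H3K27me3:\n")
  print(x$core)
  cat("\nH3K4me3 x expression:\n")
  print(x$k4_expr)
  cat("\nH3K27me3 x expression:\n")
  print(x$k27_expr)
  cat("\nDual-mark genes:",
      if (length(x$dual_mark_genes))
        paste(x$dual_mark_genes, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Per-gene mark/expression status table
#'
#' Combines the three gene-level status maps into one table with the
#' predicted expression direction for each gene.
#'
#' @inheritParams build_concordance_matrix
#' @return A `data.frame` with columns `gene_id`, `k4`, `k27`, `expr`,
#'   `predicted_expr`.
#' @export
gene_mark_status <- function(k4_status, k27_status, de_status) {
  cm <- build_concordance_matrix(k4_status, k27_status, de_status)
  df <- cm$genes
  df$predicted_expr <- predict_direction(df$k4, df$k27)
  df
}

#' Genes where observed expression can be checked against prediction
#'
#' Restricts a status table to genes that are differentially expressed and
#' have an unambiguous predicted direction, and flags whether the observed
#' direction matches.
#'
#' @param status Status table from [gene_mark_status()].
#' @return The subset `data.frame` with an added logical `concordant`.
#' @export
find_concordant_genes <- function(status) {
  sel <- status$expr != "none" & status$predicted_expr %in% c("up", "down")
  out <- status[sel, , drop = FALSE]
  out$concordant <- out$expr == out$predicted_expr
  row.names(out) <- NULL
  out
}
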