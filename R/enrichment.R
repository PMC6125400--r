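#' Hypergeometric overlap test between two gene sets
#'
#' Upper-tail probability of observing at least the realised overlap between
#' a query set and a prior set when the query is drawn at random from a
#' declared universe. The universe must be supplied explicitly (e.g. the
#' expression platform's gene list): enrichment probabilities are
#' meaningless, and irreproducible, without it. Genes outside the universe
#' are dropped with a warning. The tail includes the observed overlap
#' (P(X >= k), not P(X > k)).
#'
#' @param query Character vector of query genes.
#' @param prior Character vector of prior-set genes.
#' @param universe Character vector defining the universe.
#' @return An object of class `overlap_test`: list with `N`, `K`, `n`, `k`,
#'   `p_value`, `percent_chance` (= 100 * p).
#' @export
hypergeometric_overlap <- function(query, prior, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop_mc("empty universe")
  query <- unique(as.character(query))
  prior <- unique(as.character(prior))
  q_out <- setdiff(query, universe)
  p_out <- setdiff(prior, universe)
  if (length(q_out)) warning(length(q_out),
                             " query gene(s) outside universe dropped",
                             call. = FALSE)
  if (length(p_out)) warning(length(p_out),
                             " prior gene(s) outside universe dropped",
                             call. = FALSE)
  query <- intersect(query, universe)
  prior <- intersect(prior, universe)
  N <- length(universe)
  K <- length(prior)
  n <- length(query)
  k <- length(intersect(query, prior))
  p <- if (n == 0L) 1 else phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  structure(list(N = N, K = K, n = n, k = k, p_value = p,
                 percent_chance = 100 * p),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "Hypergeometric overlap: k = %d of n = %d query genes in a prior set of K = %d (universe N = %d)\n",
    x$k, x$n, x$K, x$N))
  cat(sprintf("  P(X >= k) = %.4g (%.4g%% chance)\n", x$p_value,
              x$percent_chance))
  invisible(x)
}

#' Test a query gene list against a collection of prior sets
#'
#' One hypergeometric overlap test per named prior set, with multiple-test
#' correction across sets. Sets with no members in the universe are skipped
#' with a warning. A local, explicit-universe stand-in for database
#' enrichment services.
#'
#' @param query Character vector of query genes.
#' @param sets Named list of character vectors (the prior sets).
#' @param universe Character vector defining the universe.
#' @param correction `"BH"`, `"bonferroni"`, or `"none"`.
#' @return A `data.frame` sorted by p-value with one row per tested set:
#'   `set`, `N`, `K`, `n`, `k`, `p_value`, `p_adjusted`.
#' @export
gene_set_enrichment <- function(query, sets, universe,
                                correction = c("BH", "bonferroni", "none")) {
  correction <- match.arg(correction)
  if (!length(sets)) stop_mc("at least one prior set is required")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop_mc("sets must be named")
  }
  universe <- unique(as.character(universe))
  keep <- vapply(sets, function(s) length(intersect(s, universe)) > 0L,
                 logical(1L))
  if (any(!keep)) warning("skipping set(s) with no members in universe: ",
                          paste(names(sets)[!keep], collapse = ", "),
                          call. = FALSE)
  sets <- sets[keep]
  if (!length(sets)) stop_mc("no set has members in the universe")
  tests <- lapply(sets, function(s)
    suppressWarnings(hypergeometric_overlap(query, s, universe)))
  res <- data.frame(set = names(sets),
                    N = vapply(tests, `[[`, 0, "N"),
                    K = vapply(tests, `[[`, 0, "K"),
                    n = vapply(tests, `[[`, 0, "n"),
                    k = vapply(tests, `[[`, 0, "k"),
                    p_value = vapply(tests, `[[`, 0, "p_value"),
                    stringsAsFactors = FALSE)
  res$p_adjusted <- p.adjust(res$p_value, method = correction)
  res <- res[order(res$p_value, res$set), , drop = FALSE]
  row.names(res) <- NULL
  res
}
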