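# Synthetic replicate peak landscapes with planted, fully known truth.
#
# Genome layout guarantees, by construction rather than by rejection
# sampling, that planted regions can never interfere with one another:
# each chromosome is split into a gene zone and a peak zone. Genes sit on a
# coarse grid whose slots leave a margin of (promoter_upstream + 2 * wmax)
# on both sides; gene-linked planted regions live inside the upstream
# promoter segment [TSS-2000, TSS-101], clear of the TSS window. Unlinked
# regions (shared / partial-support) sit on a fine grid in the peak zone
# with pitch 3 * wmax, so any two planted regions are always separated by
# >= 2 * wmax bases -- at least twice the maximum peak width, far beyond
# any realistic positional jitter.

#' Simulation configuration
#'
#' Defaults describe the study conditions the generator emulates: two
#' conditions (control and ethanol) with 4 replicates each, a large body of
#' shared peaks, a modest number of condition-exclusive peaks skewed towards
#' the treatment, partially supported peaks present in 1-3 replicates of the
#' other condition, broad-mark peak widths, mild positional jitter and a
#' per-replicate miss rate.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param n_genes Number of genes.
#' @param n_replicates Replicates per condition (default 4).
#' @param n_shared Shared (non-differential) peaks.
#' @param n_exclusive_treatment,n_exclusive_control Planted
#'   condition-exclusive peaks per direction.
#' @param partial_spec List of `c(n_peaks, k_other)` pairs: peaks present in
#'   every control replicate and exactly `k_other` treatment replicates.
#' @param peak_width_range,gene_length_range Width/length ranges in bp.
#' @param jitter_sd SD (bp) of the Gaussian jitter applied independently to
#'   both ends of every replicate-level peak.
#' @param drop_prob Probability that a given replicate misses a shared peak.
#'   Exclusive and partial-support peaks are never dropped, keeping the
#'   planted truth exact.
#' @param promoter_upstream,promoter_downstream Promoter window in bp.
#' @param conditions Named length-2 character vector,
#'   `c(control = ..., treatment = ...)`.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 4L, chrom_length = 3e6, n_genes = 100L,
                       n_replicates = 4L, n_shared = 1000L,
                       n_exclusive_treatment = 25L, n_exclusive_control = 10L,
                       partial_spec = list(c(30L, 1L), c(30L, 2L), c(30L, 3L)),
                       peak_width_range = c(500L, 2000L),
                       gene_length_range = c(5000L, 20000L),
                       jitter_sd = 20, drop_prob = 0.1,
                       promoter_upstream = 2000L, promoter_downstream = 200L,
                       conditions = c(control = "control",
                                      treatment = "ethanol"),
                       seed = 1L) {
  cfg <- list(n_chroms = as.integer(n_chroms),
              chrom_length = as.numeric(chrom_length),
              n_genes = as.integer(n_genes),
              n_replicates = as.integer(n_replicates),
              n_shared = as.integer(n_shared),
              n_exclusive_treatment = as.integer(n_exclusive_treatment),
              n_exclusive_control = as.integer(n_exclusive_control),
              partial_spec = partial_spec,
              peak_width_range = as.integer(peak_width_range),
              gene_length_range = as.integer(gene_length_range),
              jitter_sd = as.numeric(jitter_sd),
              drop_prob = as.numeric(drop_prob),
              promoter_upstream = as.integer(promoter_upstream),
              promoter_downstream = as.integer(promoter_downstream),
              conditions = conditions, seed = as.integer(seed))
  counts <- c(cfg$n_chroms, cfg$n_genes, cfg$n_replicates, cfg$n_shared,
              cfg$n_exclusive_treatment, cfg$n_exclusive_control)
  if (any(counts < 0)) stop_mc("counts must be >= 0")
  if (cfg$n_chroms < 1L || cfg$n_replicates < 1L) {
    stop_mc("need >= 1 chromosome and >= 1 replicate per condition")
  }
  if (cfg$jitter_sd < 0) stop_mc("jitter_sd must be >= 0")
  if (cfg$drop_prob < 0 || cfg$drop_prob >= 1) {
    stop_mc("drop_prob must be in [0, 1)")
  }
  if (any(cfg$peak_width_range < 1L) ||
      cfg$peak_width_range[1L] > cfg$peak_width_range[2L]) {
    stop_mc("invalid peak_width_range")
  }
  if (any(cfg$gene_length_range < 1L) ||
      cfg$gene_length_range[1L] > cfg$gene_length_range[2L]) {
    stop_mc("invalid gene_length_range")
  }
  for (ps in cfg$partial_spec) {
    if (length(ps) != 2L || any(ps < 0) ||
        ps[2L] > cfg$n_replicates) {
      stop_mc("partial_spec entries must be c(n_peaks, k_other) with ",
              "0 <= k_other <= n_replicates")
    }
  }
  if (length(cfg$conditions) != 2L ||
      !all(c("control", "treatment") %in% names(cfg$conditions))) {
    stop_mc("conditions must be c(control = ..., treatment = ...)")
  }
  structure(cfg, class = "sim_config")
}

# deterministic genome layout shared by annotation and peak placement
sim_layout <- function(config) {
  wmax <- config$peak_width_range[2L]
  margin <- config$promoter_upstream + 2L * wmax
  gene_pitch <- config$gene_length_range[2L] + 2L * margin
  genes_per_chrom <- if (config$n_genes > 0L)
    ceiling(config$n_genes / config$n_chroms) else 0L
  gene_zone <- genes_per_chrom * gene_pitch
  peak_zone_start <- gene_zone + 2L * wmax
  peak_pitch <- 3L * wmax
  slots_per_chrom <- max(0L, floor((config$chrom_length - peak_zone_start) /
                                     peak_pitch))
  list(wmax = wmax, margin = margin, gene_pitch = gene_pitch,
       genes_per_chrom = genes_per_chrom, gene_zone = gene_zone,
       peak_zone_start = peak_zone_start, peak_pitch = peak_pitch,
       slots_per_chrom = slots_per_chrom,
       n_slots = slots_per_chrom * config$n_chroms,
       chrom_names = sprintf("chr%d", seq_len(config$n_chroms)))
}

rint <- function(n, lo, hi) {
  if (lo == hi) rep.int(lo, n) else lo + floor(runif(n) * (hi - lo + 1L))
}

#' Simulate a gene annotation
#'
#' Places non-overlapping genes with random lengths and strands on a coarse
#' genome grid (round-robin over chromosomes). Deterministic under a fixed
#' config seed.
#'
#' @param config A [sim_config()].
#' @return Stranded `GRanges` of gene models with `gene_id`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lay <- sim_layout(config)
  if (config$n_genes == 0L) {
    gr <- GenomicRanges::GRanges()
    mcols(gr)$gene_id <- character(0)
    return(gr)
  }
  if (lay$gene_zone + 2L * lay$wmax >= config$chrom_length) {
    stop_mc("genome too small for ", config$n_genes, " genes: need ",
            "chrom_length > ", lay$gene_zone + 2L * lay$wmax,
            " bp (got ", config$chrom_length, ")")
  }
  set.seed(config$seed + 1L)
  i <- seq_len(config$n_genes)
  chrom_idx <- ((i - 1L) %% config$n_chroms) + 1L
  slot_idx <- ((i - 1L) %/% config$n_chroms)
  start1 <- slot_idx * lay$gene_pitch + lay$margin + 1L
  len <- rint(config$n_genes, config$gene_length_range[1L],
              config$gene_length_range[2L])
  strands <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  gr <- mc_granges(lay$chrom_names[chrom_idx], start1, start1 + len - 1L,
                   gene_id = sprintf("G%04d", i))
  strand(gr) <- strands
  names(gr) <- mcols(gr)$gene_id
  sort(gr, ignore.strand = TRUE)
}

# planted expression direction implied by a mark change
planted_expr_direction <- function(mark, class) {
  ifelse(class == "exclusive_treatment",
         ifelse(mark == "H3K4me3", "up", "down"),
         ifelse(class == "exclusive_control",
                ifelse(mark == "H3K4me3", "down", "up"),
                "null"))
}

#' Simulate a replicated two-condition peak experiment
#'
#' Generates per-replicate peak sets for one histone mark with planted
#' truth: shared peaks appear in each replicate independently with
#' probability `1 - drop_prob`; condition-exclusive peaks appear in every
#' replicate of their condition and never in the other (they are placed at
#' least twice the maximum peak width away from any other planted region);
#' partial-support peaks appear in every control replicate and in exactly
#' `k` treatment replicates. Every replicate-level peak receives independent
#' Gaussian jitter on both ends, clamped to width >= 1 and to the
#' chromosome.
#'
#' @param config A [sim_config()].
#' @param genes Gene models from [simulate_annotation()] (same config).
#' @param mark Mark label, `"H3K4me3"` or `"H3K27me3"`.
#' @param linked_genes Optional character vector of gene ids to host the
#'   exclusive regions (in their upstream promoters); defaults to a random
#'   sample. Must have at least as many genes as exclusive regions.
#' @return A list with `peaks` (condition -> replicate -> `GRanges`) and
#'   `truth` (`data.frame`: `region_id`, `chrom`, `start`, `end` 1-based
#'   closed, `class`, `k_other`, `gene_id`, `mark`).
#' @export
simulate_peak_experiment <- function(config, genes, mark = "H3K27me3",
                                     linked_genes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  lay <- sim_layout(config)
  wmin <- config$peak_width_range[1L]
  wmax <- config$peak_width_range[2L]
  n_partial <- sum(vapply(config$partial_spec, `[[`, 0L, 1L))
  n_excl <- config$n_exclusive_treatment + config$n_exclusive_control
  n_slots_needed <- config$n_shared + n_partial
  if (n_slots_needed > lay$n_slots) {
    need_len <- lay$peak_zone_start +
      ceiling(n_slots_needed / config$n_chroms) * lay$peak_pitch
    stop_mc("genome too small: need chrom_length >= ", need_len,
            " bp for ", n_slots_needed, " unlinked regions")
  }
  seed_off <- switch(mark, H3K4me3 = 11L, H3K27me3 = 13L, 17L)
  set.seed(config$seed + seed_off)

  # 1. unlinked regions (shared + partial) on the peak-zone grid
  slots <- if (n_slots_needed > 0L) sample(lay$n_slots, n_slots_needed)
           else integer(0)
  slot_chrom <- ((slots - 1L) %/% lay$slots_per_chrom) + 1L
  slot_in_chrom <- ((slots - 1L) %% lay$slots_per_chrom)
  w <- rint(n_slots_needed, wmin, wmax)
  off <- floor(runif(n_slots_needed) * (wmax - w + 1L))
  u_start <- lay$peak_zone_start + slot_in_chrom * lay$peak_pitch + off + 1L
  u_end <- u_start + w - 1L
  u_chrom <- lay$chrom_names[slot_chrom]

  # 2. gene-linked exclusive regions inside upstream promoter segments
  if (n_excl > 0L) {
    ids <- if (!is.null(mcols(genes)$gene_id)) mcols(genes)$gene_id
           else character(0)
    if (is.null(linked_genes)) {
      if (n_excl > length(ids)) {
        stop_mc("not enough genes (", length(ids), ") to link ", n_excl,
                " exclusive regions")
      }
      linked_genes <- sample(ids, n_excl)
    }
    if (n_excl > length(linked_genes)) {
      stop_mc("linked_genes shorter than the number of exclusive regions")
    }
    linked_genes <- linked_genes[seq_len(n_excl)]
    gidx <- match(linked_genes, ids)
    if (anyNA(gidx)) stop_mc("linked_genes absent from annotation")
    g <- genes[gidx]
    plus <- as.character(strand(g)) == "+"
    tssb <- ifelse(plus, start(g), end(g))
    # usable upstream segment [TSS-2000, TSS-101] has span up - radius - 100
    span <- config$promoter_upstream - 100L - 1L  # 1899 usable offsets + width
    wcap <- span - 400L
    if (wcap < 1L) {
      stop_mc("promoter_upstream too small to host gene-linked regions")
    }
    we <- pmin(rint(n_excl, wmin, wmax), wcap)
    oe <- floor(runif(n_excl) * (span - we + 1L))
    e_start <- ifelse(plus, tssb - config$promoter_upstream + oe,
                      tssb + 101L + oe)
    e_end <- e_start + we - 1L
    e_chrom <- as.character(seqnames(g))
  } else {
    e_start <- e_end <- integer(0)
    e_chrom <- linked_genes <- character(0)
  }

  # assemble planted-region table
  part_k <- unlist(lapply(config$partial_spec,
                          function(ps) rep.int(ps[2L], ps[1L])))
  class_u <- c(rep("shared", config$n_shared),
               if (n_partial > 0L) paste0("partial_", part_k))
  class_e <- rep(c("exclusive_treatment", "exclusive_control"),
                 c(config$n_exclusive_treatment, config$n_exclusive_control))
  truth <- data.frame(
    region_id = sprintf("%s_R%05d", mark,
                        seq_len(n_slots_needed + n_excl)),
    chrom = c(u_chrom, e_chrom),
    start = as.integer(c(u_start, e_start)),
    end = as.integer(c(u_end, e_end)),
    class = c(class_u, class_e),
    k_other = c(rep(NA_integer_, config$n_shared),
                if (n_partial > 0L) as.integer(part_k),
                rep(0L, n_excl)),
    gene_id = c(rep(NA_character_, n_slots_needed), linked_genes),
    mark = mark, stringsAsFactors = FALSE)

  # 3. replicate-level realisations
  n_rep <- config$n_replicates
  is_shared <- truth$class == "shared"
  is_partial <- startsWith(truth$class, "partial")
  is_excl_t <- truth$class == "exclusive_treatment"
  is_excl_c <- truth$class == "exclusive_control"
  # which treatment replicates carry each partial region (fixed per region)
  partial_reps <- lapply(which(is_partial), function(i) {
    sort(sample(n_rep, truth$k_other[i]))
  })
  names(partial_reps) <- truth$region_id[is_partial]

  realize <- function(idx) {
    n <- length(idx)
    s <- truth$start[idx]
    e <- truth$end[idx]
    if (config$jitter_sd > 0 && n > 0L) {
      s <- s + round(rnorm(n, 0, config$jitter_sd))
      e <- e + round(rnorm(n, 0, config$jitter_sd))
    }
    s <- pmax(1L, pmin(s, config$chrom_length - 1L))
    e <- pmax(s, pmin(e, config$chrom_length))  # clamp to width >= 1
    mc_granges(truth$chrom[idx], s, e, name = truth$region_id[idx])
  }

  peaks <- list()
  for (cond in c("control", "treatment")) {
    label <- config$conditions[[cond]]
    reps <- list()
    for (r in seq_len(n_rep)) {
      present <- logical(nrow(truth))
      present[is_shared] <- runif(sum(is_shared)) >= config$drop_prob
      if (cond == "control") {
        present[is_partial] <- TRUE
        present[is_excl_c] <- TRUE
      } else {
        present[is_excl_t] <- TRUE
        pr <- vapply(partial_reps, function(set) r %in% set, logical(1L))
        present[is_partial] <- pr
      }
      gr <- realize(which(present))
      mcols(gr)$replicate_id <- paste0(label, "_rep", r)
      mcols(gr)$condition <- label
      reps[[paste0("rep", r)]] <- sort(gr)
    }
    peaks[[label]] <- reps
  }
  list(peaks = peaks, truth = truth, mark = mark)
}

#' Simulate a matched differential-expression table
#'
#' Genes hosting planted mark changes get expression shifted in the
#' direction the mark predicts (activating mark gained in treatment: up;
#' repressive mark gained in treatment: down; the mirror images for
#' control-exclusive regions); all other genes are null. Per-replicate
#' expression values are drawn per gene (`n_replicates` per condition) and
#' compared with a pooled-variance two-sample t test, so null p-values are
#' exactly uniform and the realised `log_fc` is Normal(direction *
#' `effect_size`, `null_sd`).
#'
#' @param config A [sim_config()].
#' @param genes Gene models (supplies the gene universe).
#' @param truth Truth table(s) from [simulate_peak_experiment()] (may be
#'   `NULL` for an all-null table), possibly row-bound across marks.
#' @param effect_size Mean |log fold-change| of planted genes (log2 units;
#'   default 0.3, the magnitude typical of the bulk-tissue changes the
#'   generator emulates).
#' @param null_sd SD of the realised log fold-change (default 0.1).
#' @return `data.frame` with `gene_id`, `log_fc`, `p_value`; the planted
#'   direction of every non-null gene is in `attr(, "planted")`.
#' @export
simulate_expression <- function(config, genes, truth = NULL,
                                effect_size = 0.3, null_sd = 0.1) {
  stopifnot(inherits(config, "sim_config"))
  if (effect_size < 0) stop_mc("effect_size must be >= 0")
  ids <- mcols(genes)$gene_id
  delta <- setNames(numeric(length(ids)), ids)
  planted <- setNames(character(0), character(0))
  if (!is.null(truth)) {
    linked <- truth[!is.na(truth$gene_id) &
                      startsWith(truth$class, "exclusive"), , drop = FALSE]
    if (nrow(linked)) {
      missing <- setdiff(linked$gene_id, ids)
      if (length(missing)) {
        stop_mc("truth references gene_id(s) absent from annotation: ",
                paste(missing, collapse = ", "))
      }
      dirs <- planted_expr_direction(linked$mark, linked$class)
      delta[linked$gene_id] <- ifelse(dirs == "up", effect_size,
                                      -effect_size)
      planted <- setNames(dirs, linked$gene_id)
    }
  }
  set.seed(config$seed + 3L)
  n <- config$n_replicates
  ng <- length(ids)
  rep_sd <- null_sd * sqrt(n / 2)
  base <- 8
  xc <- matrix(rnorm(ng * n, base, rep_sd), nrow = ng)
  xt <- matrix(rnorm(ng * n, base, rep_sd), nrow = ng) + delta
  tt <- row_t_stats(xt, xc)
  out <- data.frame(gene_id = ids, log_fc = tt$effect,
                    p_value = pmax(tt$p, .Machine$double.xmin),
                    stringsAsFactors = FALSE)
  attr(out, "planted") <- planted
  out
}

#' Simulate a full two-mark dataset with planted truth
#'
#' Runs [simulate_annotation()], one [simulate_peak_experiment()] per mark
#' (H3K4me3 and H3K27me3, with disjoint sets of linked genes so no gene
#' accidentally carries conflicting planted changes), and
#' [simulate_expression()] on the combined truth.
#'
#' @param config A [sim_config()].
#' @param effect_size,null_sd Passed to [simulate_expression()].
#' @return List with `genes`, `k4`, `k27` (each `peaks` + `truth`),
#'   `truth` (combined), `expression`, `config`.
#' @export
simulate_dataset <- function(config, effect_size = 0.3, null_sd = 0.1) {
  stopifnot(inherits(config, "sim_config"))
  genes <- simulate_annotation(config)
  n_excl <- config$n_exclusive_treatment + config$n_exclusive_control
  ids <- mcols(genes)$gene_id
  if (2L * n_excl > length(ids)) {
    stop_mc("need >= ", 2L * n_excl, " genes to host both marks' ",
            "exclusive regions (got ", length(ids), ")")
  }
  set.seed(config$seed + 2L)
  linked <- if (n_excl > 0L) sample(ids, 2L * n_excl) else character(0)
  k4 <- simulate_peak_experiment(config, genes, mark = "H3K4me3",
                                 linked_genes = linked[seq_len(n_excl)])
  k27 <- simulate_peak_experiment(config, genes, mark = "H3K27me3",
                                  linked_genes = linked[n_excl + seq_len(n_excl)])
  truth <- rbind(k4$truth, k27$truth)
  expression <- simulate_expression(config, genes, truth,
                                    effect_size = effect_size,
                                    null_sd = null_sd)
  list(genes = genes, k4 = k4, k27 = k27, truth = truth,
       expression = expression, config = config)
}

#' Simulate a per-region read-count matrix
#'
#' Poisson counts for the count-based differential test: null regions share
#' one mean; planted regions have their treatment mean multiplied by
#' `fold`.
#'
#' @param n_regions Number of regions.
#' @param n_per_group Samples per condition (default 4).
#' @param mean_count Mean read count per region (default 100).
#' @param planted Integer indices of regions with a real effect.
#' @param fold Fold-change of planted regions in the treatment (default 8).
#' @return List with `counts` (matrix), `design` (character vector), and
#'   `planted`.
#' @export
simulate_region_counts <- function(n_regions, n_per_group = 4L,
                                   mean_count = 100, planted = integer(0),
                                   fold = 8) {
  mu <- matrix(mean_count, nrow = n_regions, ncol = 2L * n_per_group)
  if (length(planted)) {
    mu[planted, n_per_group + seq_len(n_per_group)] <- mean_count * fold
  }
  counts <- matrix(stats::rpois(length(mu), mu), nrow = n_regions)
  colnames(counts) <- c(paste0("control_", seq_len(n_per_group)),
                        paste0("treatment_", seq_len(n_per_group)))
  rownames(counts) <- sprintf("region_%05d", seq_len(n_regions))
  list(counts = counts,
       design = rep(c("control", "treatment"), each = n_per_group),
       planted = planted)
}

#' Write a simulated dataset to plain-text files
#'
#' Per-replicate BED files named `{mark}_{condition}_rep{i}.bed`, plus
#' `genes.tsv`, `expression.tsv` and `truth.tsv`.
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (mk in c("k4", "k27")) {
    mark <- sim[[mk]]$mark
    for (cond in names(sim[[mk]]$peaks)) {
      reps <- sim[[mk]]$peaks[[cond]]
      for (r in names(reps)) {
        write_peak_bed(reps[[r]],
                       file.path(dir, sprintf("%s_%s_%s.bed", mark, cond, r)))
      }
    }
  }
  write_gene_models(sim$genes, file.path(dir, "genes.tsv"))
  write_expression_table(sim$expression, file.path(dir, "expression.tsv"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
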