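# End-to-end orchestration: simulate (or load) -> consensus -> exclusive
# differential peaks -> annotation -> concordance -> enrichment, with a
# machine-readable summary, an audit log, and deterministic re-runs.

default_params <- function() {
  list(min_bp = 1L, max_other = 0L, p_cut = 0.01, fdr_cut = 0.1,
       tss_radius = 100L, promoter_upstream = 2000L,
       promoter_downstream = 200L, max_multi = 3L,
       effect_size = 0.3, null_sd = 0.1)
}

#' Run the full mark-concordance pipeline
#'
#' Stages, in order: data (simulated via [simulate_dataset()] or read from
#' files), per-condition consensus construction for each mark,
#' replicate-support histograms, condition-exclusive differential calls in
#' both directions, peak-to-gene annotation, gene-level status collapse,
#' differential-expression selection, the concordance matrix and concordant
#' gene table, and (when prior gene lists are supplied) hypergeometric
#' enrichment. Identical config and inputs give identical outputs; a
#' completed output directory is not recomputed unless `force = TRUE`.
#'
#' @param config A named list, or the path of a YAML file holding one.
#'   Recognised keys: `outdir` (required), `seed`, `sim` (list of
#'   [sim_config()] arguments; presence selects simulation mode), `inputs`
#'   (list with `genes`, `expression`, and `<mark>_<condition>` BED path
#'   vectors for marks `k4`/`k27` and conditions `control`/`treatment`),
#'   `params` (any of `min_bp`, `max_other`, `p_cut`, `fdr_cut`,
#'   `tss_radius`, `promoter_upstream`, `promoter_downstream`, `max_multi`,
#'   `effect_size`, `null_sd`), `prior_sets` (named list: set name -> gene
#'   list path), `universe` (gene list path). Unknown keys are rejected.
#' @param force Recompute even if the output directory holds a completed
#'   summary.
#' @param quiet Suppress progress messages (they always go to the log file).
#' @return An object of class `markconcord_run` with elements `summary`,
#'   `results`, `outdir`.
#' @export
run_pipeline <- function(config, force = FALSE, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  known <- c("outdir", "seed", "sim", "inputs", "params", "prior_sets",
             "universe")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop_mc("unknown config key(s): ",
                               paste(unknown, collapse = ", "))
  if (is.null(config$outdir)) stop_mc("config$outdir is required")
  if (is.null(config$sim) && is.null(config$inputs)) {
    stop_mc("config needs either 'sim' or 'inputs'")
  }
  params <- modifyList(default_params(), config$params %||% list())
  bad_par <- setdiff(names(config$params %||% list()), names(default_params()))
  if (length(bad_par)) stop_mc("unknown params key(s): ",
                               paste(bad_par, collapse = ", "))
  outdir <- config$outdir
  summary_path <- file.path(outdir, "summary.json")
  if (file.exists(summary_path) && !force) {
    if (!quiet) message("completed run found in ", outdir,
                        "; use force = TRUE to recompute")
    return(structure(list(summary = jsonlite::read_json(summary_path),
                          results = NULL, outdir = outdir),
                     class = "markconcord_run"))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " INFO ", ...)
    writeLines(line, log_con)
    if (!quiet) message(line)
  }
  stage <- function(name, expr) {
    logmsg("stage ", name, " started")
    tryCatch(expr, error = function(e) {
      writeLines(paste0("ERROR in stage ", name, ": ", conditionMessage(e)),
                 log_con)
      stop_mc("stage ", name, " failed: ", conditionMessage(e))
    })
  }

  # ---- data -------------------------------------------------------------
  data <- stage("data", {
    if (!is.null(config$sim)) {
      sim_args <- config$sim
      if (!is.null(config$seed)) sim_args$seed <- config$seed
      cfg <- do.call(sim_config, sim_args)
      sim <- simulate_dataset(cfg, effect_size = params$effect_size,
                              null_sd = params$null_sd)
      list(genes = sim$genes, expression = sim$expression,
           peaks = list(k4 = sim$k4$peaks, k27 = sim$k27$peaks),
           truth = sim$truth,
           conditions = cfg$conditions)
    } else {
      ins <- config$inputs
      genes <- read_gene_models(ins$genes)
      expression <- read_expression_table(ins$expression)
      peaks <- list()
      for (mk in c("k4", "k27")) {
        peaks[[mk]] <- list()
        for (cond in c("control", "treatment")) {
          key <- paste0(mk, "_", cond)
          files <- ins[[key]]
          if (is.null(files)) stop_mc("inputs$", key, " missing")
          peaks[[mk]][[cond]] <- setNames(
            lapply(seq_along(files), function(i)
              read_peak_bed(files[[i]], replicate_id = paste0(cond, "_rep", i),
                            condition = cond)),
            paste0("rep", seq_along(files)))
        }
      }
      list(genes = genes, expression = expression, peaks = peaks,
           truth = NULL,
           conditions = c(control = "control", treatment = "ethanol"))
    }
  })
  cond_names <- names(data$peaks$k4)
  names(cond_names) <- c("control", "treatment")

  # ---- consensus + support histograms + exclusive calls -----------------
  marks <- c(k4 = "H3K4me3", k27 = "H3K27me3")
  consensus <- list()
  hists <- list()
  exclusive <- list()
  for (mk in names(marks)) {
    consensus[[mk]] <- stage(paste0("consensus_", mk), {
      lapply(setNames(nm = cond_names), function(cond)
        build_consensus(data$peaks[[mk]][[cond]], condition = cond,
                        min_bp = params$min_bp))
    })
    hists[[mk]] <- stage(paste0("supporthist_", mk), {
      list(control = support_histogram(consensus[[mk]][[cond_names[1L]]],
                                       data$peaks[[mk]][[cond_names[2L]]],
                                       min_bp = params$min_bp),
           treatment = support_histogram(consensus[[mk]][[cond_names[2L]]],
                                         data$peaks[[mk]][[cond_names[1L]]],
                                         min_bp = params$min_bp))
    })
    exclusive[[mk]] <- stage(paste0("diffpeaks_", mk), {
      gain_t <- call_exclusive_peaks(consensus[[mk]][[cond_names[2L]]],
                                     data$peaks[[mk]][[cond_names[1L]]],
                                     max_other = params$max_other,
                                     direction = "gain_in_treatment",
                                     mark = marks[[mk]],
                                     min_bp = params$min_bp)
      gain_c <- call_exclusive_peaks(consensus[[mk]][[cond_names[1L]]],
                                     data$peaks[[mk]][[cond_names[2L]]],
                                     max_other = params$max_other,
                                     direction = "gain_in_control",
                                     mark = marks[[mk]],
                                     min_bp = params$min_bp)
      list(gain_treatment = gain_t, gain_control = gain_c)
    })
  }

  # ---- annotation + gene status -----------------------------------------
  annot <- list()
  status <- list()
  conflicts <- list()
  for (mk in names(marks)) {
    annot[[mk]] <- stage(paste0("annotate_", mk), {
      calls <- c(exclusive[[mk]]$gain_treatment, exclusive[[mk]]$gain_control)
      a <- associate_peaks_to_genes(
        calls, data$genes, max_multi = params$max_multi,
        tss_radius = params$tss_radius,
        promoter_upstream = params$promoter_upstream,
        promoter_downstream = params$promoter_downstream)
      a$direction <- mcols(calls)$direction[a$peak_id]
      a
    })
    st <- collapse_gene_status(
      annot[[mk]]$gene_id,
      if (mk == "k4") {
        ifelse(annot[[mk]]$direction == "gain_in_treatment",
               "increase", "decrease")
      } else {
        ifelse(annot[[mk]]$direction == "gain_in_treatment",
               "gain_treatment", "gain_control")
      })
    status[[mk]] <- st$status
    conflicts[[mk]] <- st$conflicts
  }

  # ---- expression + concordance -----------------------------------------
  de <- stage("select_de", select_de_genes(data$expression,
                                           p_cut = params$p_cut))
  conc <- stage("concordance", {
    cm <- build_concordance_matrix(status$k4, status$k27, de)
    gs <- gene_mark_status(status$k4, status$k27, de)
    list(matrix = cm, status = gs, concordant = find_concordant_genes(gs))
  })

  # ---- enrichment (optional) --------------------------------------------
  enrich <- NULL
  if (!is.null(config$prior_sets)) {
    enrich <- stage("enrichment", {
      if (is.null(config$universe)) {
        stop_mc("prior_sets given but no universe; the universe must be ",
                "declared explicitly")
      }
      universe <- read_gene_list(config$universe)
      sets <- lapply(config$prior_sets, read_gene_list)
      query <- unique(c(names(status$k4), names(status$k27)))
      gene_set_enrichment(query, sets, universe)
    })
  }

  # ---- summary + outputs ------------------------------------------------
  summarize_hist <- function(h) {
    list(total = h$total, counts = as.list(h$counts),
         percent = if (h$total > 0)
           as.list(summarize_overlap_fractions(h)) else NULL)
  }
  n_excl <- lapply(exclusive, function(e)
    list(gain_treatment = length(e$gain_treatment),
         gain_control = length(e$gain_control),
         total = length(e$gain_treatment) + length(e$gain_control)))
  summary <- list(
    version = as.character(packageVersion("markconcord")),
    params = params,
    consensus_totals = lapply(consensus, function(cc) lapply(cc, length)),
    support_histograms = lapply(hists, function(hh)
      lapply(hh, summarize_hist)),
    exclusive_peaks = n_excl,
    annotation = lapply(annot, summarize_annotation),
    gene_status_counts = lapply(status, function(s) as.list(table(s))),
    conflicts = conflicts,
    n_de_genes = length(de),
    concordance = list(
      core = as.data.frame(conc$matrix$core, stringsAsFactors = FALSE),
      dual_mark_genes = conc$matrix$dual_mark_genes,
      n_checkable = nrow(conc$concordant),
      n_concordant = sum(conc$concordant$concordant)),
    enrichment = enrich)

  cfg_path <- file.path(outdir, "config_used.yaml")
  yaml::write_yaml(config, cfg_path)
  summary$config_md5 <- unname(tools::md5sum(cfg_path))
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  for (mk in names(marks)) {
    write_annotation(annot[[mk]], file.path(outdir, paste0(mk, "_annot.tsv")))
    write_peak_bed(exclusive[[mk]]$gain_treatment,
                   file.path(outdir, paste0(mk, "_gain_treatment.bed")))
    write_peak_bed(exclusive[[mk]]$gain_control,
                   file.path(outdir, paste0(mk, "_gain_control.bed")))
  }
  write.table(conc$concordant, file.path(outdir, "concordant_genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  logmsg("pipeline finished; summary written to ", summary_path)

  structure(list(summary = summary,
                 results = list(data = data, consensus = consensus,
                                hists = hists, exclusive = exclusive,
                                annot = annot, status = status, de = de,
                                concordance = conc, enrichment = enrich),
                 outdir = outdir),
            class = "markconcord_run")
}

#' @export
print.markconcord_run <- function(x, ...) {
  s <- x$summary
  cat("markconcord pipeline run (v", s$version, ")\n", sep = "")
  cat("  output directory:", x$outdir, "\n")
  for (mk in names(s$exclusive_peaks)) {
    e <- s$exclusive_peaks[[mk]]
    cat(sprintf("  %s exclusive peaks: %d gain_treatment + %d gain_control = %d\n",
                mk, e$gain_treatment, e$gain_control, e$total))
  }
  cat("  DE genes:", s$n_de_genes, "\n")
  cat(sprintf("  concordant genes: %d of %d checkable\n",
              s$concordance$n_concordant, s$concordance$n_checkable))
  invisible(x)
}

#' @export
summary.markconcord_run <- function(object, ...) {
  object$summary
}
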