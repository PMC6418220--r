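#' Pipeline configuration
#'
#' Declarative configuration of an end-to-end run: a simulation config (or a
#' directory of input files), analysis thresholds, stage toggles, and one
#' root seed from which every stage derives a named substream.
#'
#' @param sim a [sim_config()] for the synthetic study.
#' @param outdir output directory for stage files and the manifest.
#' @param min_reads entry-level coverage floor (default 5).
#' @param max_strand_diff strand-concordance threshold (default 0.20).
#' @param min_individuals site-level coverage breadth (default 100).
#' @param min_variable_frac site-level variability fraction (default 0.10).
#' @param fdr_levels FDR levels reported (default 0.05 and 0.10).
#' @param bonferroni_alpha replication family-wise level (default 0.05).
#' @param qtl_window cis metQTL window in bp (default 250 kb).
#' @param expr_window cis expression window in bp (default 1 Mb).
#' @param stages character vector of stages to run, in canonical order.
#' @param seed root seed (overrides `sim$seed`).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), outdir = tempfile("ewasrun"),
                            min_reads = 5, max_strand_diff = 0.20,
                            min_individuals = 100, min_variable_frac = 0.10,
                            fdr_levels = c(0.05, 0.10),
                            bonferroni_alpha = 0.05,
                            qtl_window = 250000, expr_window = 1e6,
                            stages = PIPELINE_STAGES, seed = sim$seed) {
  stop_if_not(max_strand_diff >= 0 && max_strand_diff <= 1,
              "max_strand_diff must lie in [0, 1]")
  stop_if_not(all(fdr_levels > 0 & fdr_levels < 1),
              "FDR levels must lie in (0, 1)")
  stop_if_not(all(stages %in% PIPELINE_STAGES),
              "unknown stage name")
  sim$seed <- as.integer(seed)
  structure(
    list(sim = sim, outdir = outdir, min_reads = min_reads,
         max_strand_diff = max_strand_diff,
         min_individuals = min_individuals,
         min_variable_frac = min_variable_frac, fdr_levels = fdr_levels,
         bonferroni_alpha = bonferroni_alpha, qtl_window = qtl_window,
         expr_window = expr_window, stages = stages, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

PIPELINE_STAGES <- c("simulate", "qc", "ewas", "adjust", "annotate",
                     "replicate", "integrate", "report")

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; the `sim` block
#' mirrors [sim_config()].
#'
#' @param path path to a YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  sim <- do.call(sim_config, sim_args)
  y$sim <- NULL
  do.call(pipeline_config, c(list(sim = sim), y))
}

#' Run the full analysis pipeline
#'
#' Executes simulate, qc, ewas, adjust, annotate, replicate, integrate and
#' report in order (disabled stages are skipped and recorded), writing stage
#' outputs under `config$outdir` and returning a manifest with per-stage
#' record counts, file hashes and the seeds used. Stage randomness flows
#' from the root seed through named substreams, so identical configs give
#' identical manifests.
#'
#' @param config a [pipeline_config()].
#' @return list with `manifest` and the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stop_if_not(inherits(config, "pipeline_config"),
              "config must be a pipeline_config")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  res <- list()
  manifest <- list(
    package_version = as.character(utils::packageVersion("lipidews")),
    seed = config$seed,
    stages = list()
  )
  note <- function(stage, status, n_records = NA, files = character(0)) {
    hashes <- if (length(files)) {
      h <- tools::md5sum(files)
      # keys relative to the run directory so manifests are portable
      names(h) <- substring(files, nchar(config$outdir) + 2L)
      as.list(h)
    } else list()
    manifest$stages[[stage]] <<- list(
      status = status, n_records = n_records, files = hashes,
      seed = if (stage %in% c("simulate")) stage_seed(config$seed, stage)
             else NULL
    )
    message(sprintf("[%s] %s (%s records)", stage, status,
                    ifelse(is.na(n_records), "-", n_records)))
  }
  want <- function(stage) stage %in% config$stages

  # --- simulate -------------------------------------------------------
  if (want("simulate")) {
    pair <- simulate_tissue_pair(config$sim)
    res$pair <- pair
    write_cohort(pair$discovery, file.path(config$outdir, "cohort"))
    note("simulate", "done", nrow(pair$cpgs),
         file.path(config$outdir, "cohort",
                   c("elements.bed", "phenotypes.tsv", "truth.json")))
  } else {
    note("simulate", "skipped")
  }

  # --- qc -------------------------------------------------------------
  if (want("qc")) {
    if (is.null(res$pair)) stop("stage 'qc' needs output of stage 'simulate'",
                                call. = FALSE)
    qc_one <- function(counts) {
      m <- merge_strands(counts, config$max_strand_diff)
      m <- apply_min_coverage(m, config$min_reads)
      filter_sites(m, min_individuals = min(config$min_individuals,
                                            ncol(m$m)),
                   min_variable_frac = config$min_variable_frac)
    }
    res$qc <- qc_one(res$pair$discovery$counts)
    res$qc_repl <- qc_one(res$pair$replication$counts)
    f <- file.path(config$outdir, "site_qc.tsv")
    write_tsv(res$qc$report, f)
    note("qc", "done", nrow(res$qc$mat$m), f)
  } else note("qc", "skipped")

  # --- ewas -----------------------------------------------------------
  if (want("ewas")) {
    if (is.null(res$qc)) stop("stage 'ewas' needs output of stage 'qc'",
                              call. = FALSE)
    res$ewas <- run_ewas(res$qc$mat, res$pair$discovery$phenotypes)
    res$ewas_repl <- run_ewas(res$qc_repl$mat,
                              res$pair$replication$phenotypes,
                              transforms = c(TG = "log", HDL = "log"))
    note("ewas", "done", nrow(res$ewas))
  } else note("ewas", "skipped")

  # --- adjust ---------------------------------------------------------
  if (want("adjust")) {
    if (is.null(res$ewas)) stop("stage 'adjust' needs output of stage 'ewas'",
                                call. = FALSE)
    res$ewas <- adjust_ewas(res$ewas)
    res$ewas_repl <- adjust_ewas(res$ewas_repl)
    nf <- attr(res$ewas, "null_fits")
    lam <- attr(res$ewas, "lambdas")
    f <- file.path(config$outdir, "null_fit.json")
    jsonlite::write_json(
      lapply(names(nf), function(tr) list(
        trait = tr, mu0 = nf[[tr]]$mu0, sigma0 = nf[[tr]]$sigma0,
        w0 = nf[[tr]]$w0, lambda_raw = lam[[tr]][["raw"]],
        lambda_corrected = lam[[tr]][["corrected"]])),
      f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (tr in unique(res$ewas$trait)) {
      write_tsv(res$ewas[res$ewas$trait == tr, ],
                file.path(config$outdir, sprintf("ewas_%s.tsv", tr)))
    }
    note("adjust", "done", nrow(res$ewas), f)
  } else note("adjust", "skipped")

  # --- annotate -------------------------------------------------------
  if (want("annotate")) {
    if (is.null(res$ewas)) stop("stage 'annotate' needs output of stage 'adjust'",
                                call. = FALSE)
    ann <- annotate_cpgs(res$pair$cpgs, res$pair$elements)
    res$annotated <- ann
    join <- function(ew) {
      idx <- match(ew$cpg_id, ann$cpg_id)
      ew$element_id <- ann$element_id[idx]
      ew$element_class <- ann$element_class[idx]
      ew$specificity <- ann$specificity[idx]
      ew
    }
    res$ewas <- join(res$ewas)
    res$ewas_repl <- join(res$ewas_repl)
    sig <- res$ewas$cpg_id[!is.na(res$ewas$q) & res$ewas$q < max(config$fdr_levels)]
    res$profile_all <- positional_profile(ann, res$pair$elements)
    res$profile_sig <- positional_profile(ann, res$pair$elements,
                                          subset = unique(sig))
    f <- file.path(config$outdir, "positional_profile.tsv")
    write_tsv(res$profile_all, f)
    note("annotate", "done", nrow(res$profile_all), f)
  } else note("annotate", "skipped")

  # --- replicate ------------------------------------------------------
  if (want("replicate")) {
    if (is.null(res$annotated)) stop(
      "stage 'replicate' needs output of stage 'annotate'", call. = FALSE)
    sig <- res$ewas[!is.na(res$ewas$q) & res$ewas$q < max(config$fdr_levels) &
                      !is.na(res$ewas$element_id), , drop = FALSE]
    if (nrow(sig) > 0) {
      disc_regions <- res$ewas[res$ewas$element_id %in% sig$element_id &
                                 paste(res$ewas$element_id, res$ewas$trait) %in%
                                 paste(sig$element_id, sig$trait), , drop = FALSE]
      res$replication <- replicate_regions(
        disc_regions, res$ewas_repl, alpha = config$bonferroni_alpha)
      f <- file.path(config$outdir, "replication.tsv")
      write_tsv(res$replication, f)
      note("replicate", "done", nrow(res$replication), f)
    } else {
      res$replication <- NULL
      note("replicate", "done", 0)
    }
  } else note("replicate", "skipped")

  # --- integrate ------------------------------------------------------
  if (want("integrate")) {
    if (is.null(res$qc)) stop("stage 'integrate' needs output of stage 'qc'",
                              call. = FALSE)
    res$qtls <- cis_met_qtl(res$qc$mat, res$pair$discovery$genotypes,
                            window = config$qtl_window)
    res$genetic <- classify_genetic_regulation(res$qtls, res$annotated,
                                               res$pair$elements)
    f1 <- file.path(config$outdir, "metqtl.tsv")
    f2 <- file.path(config$outdir, "genetic_regulation_report.tsv")
    write_tsv(res$qtls, f1)
    write_tsv(res$genetic$report, f2)
    expr_cov <- NULL
    res$expr_assoc <- cis_expression_association(
      res$qc$mat, res$pair$discovery$expression, res$pair$discovery$genes,
      covariates = expr_cov, window = config$expr_window)
    idx <- match(res$expr_assoc$cpg_id, res$annotated$cpg_id)
    res$expr_assoc$element_id <- res$annotated$element_id[idx]
    f3 <- file.path(config$outdir, "expr_assoc.tsv")
    write_tsv(res$expr_assoc, f3)
    note("integrate", "done", nrow(res$qtls), c(f1, f2, f3))
  } else note("integrate", "skipped")

  # --- report ---------------------------------------------------------
  if (want("report")) {
    rep <- list(
      n_cpgs_tested = if (!is.null(res$qc)) nrow(res$qc$mat$m) else NA,
      n_records = if (!is.null(res$ewas)) nrow(res$ewas) else NA,
      lambdas = if (!is.null(res$ewas)) attr(res$ewas, "lambdas") else NULL,
      n_significant_fdr10 = if (!is.null(res$ewas) && "q" %in% names(res$ewas))
        sum(res$ewas$q < 0.10, na.rm = TRUE) else NA
    )
    f <- file.path(config$outdir, "report.json")
    jsonlite::write_json(rep, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    res$report <- rep
    note("report", "done", 1, f)
  } else note("report", "skipped")

  message(sprintf("pipeline finished in %.1f s",
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  mf <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
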