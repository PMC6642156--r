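#' Configuration for an end-to-end synthetic pipeline run
#'
#' Bundles the simulation configuration, stage toggles and all stage
#' parameters. Stage dependencies are validated up front (fail-fast): the
#' signature stage needs the quantification/integration stage, and the
#' validation stage needs the signature stage.
#'
#' @param seed Integer seed; flows into the simulation config and is the
#'   only source of randomness of the run.
#' @param outdir Output directory for all artifacts.
#' @param sim A [sim_config()] (defaults to `sim_config(seed = seed)`).
#' @param stages Named logical vector toggling `spectra`, `psm`, `quant`,
#'   `signature`, `validate`.
#' @param fdr_level Target-decoy FDR level for PSM filtering.
#' @param window_width Reporter extraction window (total width, Th).
#' @param up_fold,balance_threshold NE-LCSS thresholds
#'   (see [derive_ne_lcss()]).
#' @param alpha AS/ND-LCSS adjusted-p cutoff.
#' @param linkage,distance,k Clustering parameters for the validation
#'   stage.
#' @param write_mzml Also serialize the simulated spectra as mzML.
#' @param verbose Log stage progress to stderr.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            outdir = tempfile("nelcss_run_"),
                            sim = sim_config(seed = seed),
                            stages = c(spectra = TRUE, psm = TRUE,
                                       quant = TRUE, signature = TRUE,
                                       validate = TRUE),
                            fdr_level = 0.01,
                            window_width = 0.03,
                            up_fold = 1.5,
                            balance_threshold = 0.2,
                            alpha = 0.05,
                            linkage = "complete",
                            distance = "euclidean",
                            k = 2L,
                            write_mzml = FALSE,
                            verbose = TRUE) {
  all_stages <- c("spectra", "psm", "quant", "signature", "validate")
  st <- stats::setNames(rep(TRUE, 5), all_stages)
  st[names(stages)] <- stages
  if (st[["signature"]] && !st[["quant"]])
    stop("pipeline_config: the signature stage requires the quant stage")
  if (st[["validate"]] && !st[["signature"]])
    stop("pipeline_config: the validate stage requires the signature ",
         "stage")
  if (fdr_level <= 0 || fdr_level > 1)
    stop("pipeline_config: fdr_level must lie in (0, 1]")
  cfg <- list(seed = as.integer(seed), outdir = outdir,
              sim = validate_sim_config(sim), stages = st,
              fdr_level = fdr_level, window_width = window_width,
              up_fold = up_fold, balance_threshold = balance_threshold,
              alpha = alpha, linkage = linkage, distance = distance,
              k = as.integer(k), write_mzml = isTRUE(write_mzml),
              verbose = isTRUE(verbose))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Any subset of the arguments of [pipeline_config()] (and, under the
#' `sim` key, of [sim_config()]) may be given; the rest take their
#' defaults.
#'
#' @param path YAML file path.
#' @param outdir Optional override of the output directory.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, outdir = NULL) {
  y <- yaml::read_yaml(path)
  seed <- if (!is.null(y$seed)) as.integer(y$seed) else 1L
  sim_args <- y$sim
  if (is.null(sim_args)) sim_args <- list()
  if (is.null(sim_args$seed)) sim_args$seed <- seed
  if (!is.null(sim_args$expr_samples))
    sim_args$expr_samples <- unlist(sim_args$expr_samples)
  args <- y[setdiff(names(y), c("sim", "stages"))]
  args$seed <- seed
  args$sim <- do.call(sim_config, sim_args)
  if (!is.null(y$stages)) args$stages <- unlist(y$stages)
  if (!is.null(outdir)) args$outdir <- outdir
  do.call(pipeline_config, args)
}

stage_log <- function(cfg, stage, ...) {
  if (cfg$verbose)
    message("[nelcss:", stage, "] ", ...)
}

#' Run the full synthetic secretome pipeline
#'
#' Executes the enabled stages in order -- spectra simulation + reporter
#' extraction, PSM simulation + discriminant FDR filtering + protein
#' aggregation, quantification-experiment simulation + normalization +
#' fold-change integration + plasma filtering, signature derivation
#' (NE-LCSS and AS/ND-LCSS), and validation (marker clustering
#' concordance, expression-matrix driver correlation) -- writing each
#' stage's artifacts under `config$outdir` plus a machine-readable run
#' report (`run_report.json`). Identical config + seed reproduces
#' byte-identical signature tables and report. A stage failure aborts with
#' the stage name and leaves a `FAILED_<stage>` marker file next to any
#' partial outputs.
#'
#' @param config A [pipeline_config()].
#' @return The run report (a list of per-stage summaries), invisibly.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(seed = 1,
#'                        sim = sim_config(seed = 1, n_proteins = 200,
#'                                         n_up_pan = 10, n_down_pan = 5,
#'                                         n_subtype_markers = 12,
#'                                         n_spectra = 20, n_psms = 500),
#'                        verbose = FALSE)
#' rep <- run_pipeline(cfg)
#' rep$stages$signature$ne_lcss_up
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed,
                 parameters = list(fdr_level = config$fdr_level,
                                   window_width = config$window_width,
                                   up_fold = config$up_fold,
                                   balance_threshold =
                                     config$balance_threshold,
                                   alpha = config$alpha,
                                   linkage = config$linkage,
                                   distance = config$distance,
                                   k = config$k),
                 stages = list())
  run_stage <- function(name, expr) {
    if (!config$stages[[name]]) {
      stage_log(config, name, "skipped")
      return(list(status = "skipped"))
    }
    tryCatch(c(list(status = "ok"), expr),
             error = function(e) {
               writeLines(conditionMessage(e),
                          file.path(config$outdir,
                                    paste0("FAILED_", name)))
               stop("pipeline stage '", name, "' failed: ",
                    conditionMessage(e), call. = FALSE)
             })
  }
  channels <- reporter_channels(window_width = config$window_width)

  report$stages$spectra <- run_stage("spectra", {
    sim <- simulate_spectra(config$sim, channels)
    stage_log(config, "spectra", "simulated ", length(sim$spectra),
              " spectra")
    ext <- t(vapply(sim$spectra, extract_reporter_intensities,
                    numeric(length(channels$labels)), channels))
    rownames(ext) <- rownames(sim$truth$true_reporter_intensities)
    exact <- mean(ext == sim$truth$true_reporter_intensities)
    write_peaklist(sim$spectra, file.path(config$outdir,
                                          "spectra_peaklist.tsv"))
    if (config$write_mzml)
      write_spectra_mzml(sim$spectra, file.path(config$outdir,
                                                "spectra.mzML"))
    list(n_spectra = length(sim$spectra),
         extraction_exact_fraction = exact)
  })

  report$stages$psm <- run_stage("psm", {
    sim <- simulate_psm_table(config$sim)
    n_multi <- sum(sim$psms$charge >= 2)
    res <- filter_psms(sim$psms, level = config$fdr_level)
    realized <- if (length(res$retained_psm_ids))
      mean(!sim$truth$psm_labels[res$retained_psm_ids]) else NA_real_
    stage_log(config, "psm", "retained ", res$n_retained, " of ",
              nrow(sim$psms), " PSMs at FDR ", config$fdr_level)
    qt <- aggregate_protein_sn(res$retained_psms)
    qt <- normalize_channel_sums(qt)
    write_quant_table(qt, file.path(config$outdir,
                                    "psm_protein_quant.tsv"))
    list(n_psms_simulated = nrow(sim$psms),
         n_after_charge_filter = n_multi,
         n_retained_at_fdr = res$n_retained,
         score_threshold = res$score_threshold,
         estimated_fdr_peptide = res$estimated_fdr_peptide,
         estimated_fdr_protein = res$estimated_fdr_protein,
         realized_false_discovery_proportion = realized,
         n_proteins_quantified = nrow(qt$sn))
  })

  quant_env <- new.env()
  report$stages$quant <- run_stage("quant", {
    sim <- simulate_quant_experiment(config$sim)
    tabs <- lapply(sim$tables, normalize_channel_sums)
    # replicate reproducibility on the duplicated channels of set 1
    rep_r <- NA_real_
    for (tab in tabs) {
      dsn <- tab$design
      dups <- names(which(table(dsn$sample) >= 2))
      if (length(dups)) {
        chs <- dsn$channel[dsn$sample == dups[1]][1:2]
        rep_r <- unname(replicate_correlation(tab, list(chs)))
        break
      }
    }
    fcms <- lapply(tabs, compute_fold_changes)
    merged <- intersect_common_proteins(fcms)
    plasma <- filter_plasma_detectable(merged, sim$truth$plasma_ids)
    write_fold_change_matrix(
      merged, file.path(config$outdir, "fold_changes_merged.tsv"),
      file.path(config$outdir, "fold_changes_design.tsv"))
    writeLines(sim$truth$plasma_ids,
               file.path(config$outdir, "plasma_list.txt"))
    write_truth(sim$truth, file.path(config$outdir, "ground_truth.json"))
    stage_log(config, "quant", nrow(merged$fc),
              " proteins common across sets, ",
              attr(plasma, "n_retained"), " plasma-detectable")
    assign("plasma_fcm", plasma, envir = quant_env)
    assign("truth", sim$truth, envir = quant_env)
    list(n_sets = length(tabs),
         n_quantified_per_set =
           unname(vapply(tabs, function(t) nrow(t$sn), integer(1))),
         replicate_correlation_r = rep_r,
         n_common_proteins = nrow(merged$fc),
         n_plasma_detectable = attr(plasma, "n_retained"))
  })

  sig_env <- new.env()
  report$stages$signature <- run_stage("signature", {
    fcm <- get("plasma_fcm", envir = quant_env)
    truth <- get("truth", envir = quant_env)
    ne <- derive_ne_lcss(fcm, up_threshold = config$up_fold,
                         balance_threshold = config$balance_threshold)
    asnd <- derive_asnd_lcss(fcm, alpha = config$alpha)
    ne_tab <- ne$stats
    ne_tab$in_up_lcss <- ne_tab$protein %in% ne$up_ids
    ne_tab$in_down_lcss <- ne_tab$protein %in% ne$down_ids
    write_tsv_precise(ne_tab, file.path(config$outdir, "ne_lcss.tsv"))
    as_tab <- as.data.frame(asnd$differential)
    as_tab$in_asnd_lcss <- as_tab$p_adj < asnd$alpha
    write_tsv_precise(as_tab, file.path(config$outdir, "asnd_lcss.tsv"))
    stage_log(config, "signature", "NE-LCSS ", length(ne$up_ids), " up / ",
              length(ne$down_ids), " down; AS/ND-LCSS ",
              length(asnd$up_ascl1_ids) + length(asnd$up_neurod1_ids),
              " proteins")
    assign("asnd", asnd, envir = sig_env)
    assign("fcm", fcm, envir = sig_env)
    sens <- function(found, planted)
      if (length(planted)) length(intersect(found, planted)) /
        length(planted) else NA_real_
    fdp <- function(found, planted)
      if (length(found)) 1 - length(intersect(found, planted)) /
        length(found) else 0
    planted_sub <- names(truth$subtype_marker_ids)
    asnd_found <- c(asnd$up_ascl1_ids, asnd$up_neurod1_ids)
    list(ne_lcss_up = length(ne$up_ids),
         ne_lcss_down = length(ne$down_ids),
         asnd_lcss = length(asnd_found),
         ne_up_sensitivity = sens(ne$up_ids, truth$up_pan_ids),
         ne_up_fdp = fdp(ne$up_ids, truth$up_pan_ids),
         ne_down_sensitivity = sens(ne$down_ids, truth$down_pan_ids),
         ne_down_fdp = fdp(ne$down_ids, truth$down_pan_ids),
         asnd_sensitivity = sens(asnd_found, planted_sub),
         asnd_fdp = fdp(asnd_found, planted_sub))
  })

  report$stages$validate <- run_stage("validate", {
    asnd <- get("asnd", envir = sig_env)
    fcm <- get("fcm", envir = sig_env)
    sig <- c(asnd$up_ascl1_ids, asnd$up_neurod1_ids)
    ari <- NA_real_
    if (length(sig) >= 2L) {
      cl <- hierarchical_cluster(t(fcm$log2fc[sig, , drop = FALSE]),
                                 linkage = config$linkage,
                                 distance = config$distance)
      ari <- cluster_concordance(cl, config$k, fcm$subtype)
      write_newick(cl, file.path(config$outdir,
                                 "sample_dendrogram.nwk"))
    }
    esim <- simulate_expression_matrix(config$sim)
    em <- log_transform_fpkm(esim$em)
    top <- top_correlated_genes(em, esim$truth$driver, k = 4L)
    write_expression_matrix(esim$em,
                            file.path(config$outdir,
                                      "expression_matrix.tsv"),
                            file.path(config$outdir,
                                      "expression_subtypes.tsv"))
    stage_log(config, "validate", "clustering ARI ", format(ari),
              "; top driver-correlated genes: ",
              paste(top$gene, collapse = ", "))
    list(clustering_ari = ari,
         n_markers_clustered = length(sig),
         top_correlated_genes = top$gene,
         n_planted_recovered_in_top4 =
           length(intersect(top$gene,
                            esim$truth$driver_correlated_gene_ids)))
  })

  jsonlite::write_json(report,
                       file.path(config$outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  class(report) <- "pipeline_report"
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("nelcss pipeline run (seed", x$seed, ")\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat("  ", nm, ": ", st$status, "\n", sep = "")
  }
  invisible(x)
}
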