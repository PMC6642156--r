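#' Default three-set TMT study design
#'
#' The study layout this package emulates: three six-plex TMT sets profiling
#' 12 neuroendocrine lung cancer cell lines (7 ASCL1-high, 5 NEUROD1-high)
#' with the normal bronchial epithelial line HBEC34-KT carried in every set
#' as the reference standard. Set 1 runs the reference and two ASCL1-high
#' lines in duplicate channels; sets 2 and 3 run one channel per line.
#'
#' @return A `sample_design` data frame with columns `set_id`, `channel`,
#'   `sample` and `subtype` (one of `"REF"`, `"ASCL1"`, `"NEUROD1"`).
#' @examples
#' default_tmt_design()
#' @export
default_tmt_design <- function() {
  ch <- c("126", "127", "128", "129", "130", "131")
  d <- rbind(
    data.frame(
      set_id = "set1", channel = ch,
      sample = c("HBEC34-KT", "HBEC34-KT", "HCC4018", "HCC4018",
                 "H2081", "H2081"),
      subtype = c("REF", "REF", "ASCL1", "ASCL1", "ASCL1", "ASCL1"),
      stringsAsFactors = FALSE),
    data.frame(
      set_id = "set2", channel = ch,
      sample = c("HBEC34-KT", "H889", "H1092", "H69", "H2107", "H128"),
      subtype = c("REF", rep("ASCL1", 5)),
      stringsAsFactors = FALSE),
    data.frame(
      set_id = "set3", channel = ch,
      sample = c("HBEC34-KT", "H378", "H82", "H2171", "HCC970", "H524"),
      subtype = c("REF", rep("NEUROD1", 5)),
      stringsAsFactors = FALSE))
  class(d) <- c("sample_design", "data.frame")
  d
}

validate_design <- function(design) {
  req <- c("set_id", "channel", "sample", "subtype")
  if (!all(req %in% names(design)))
    stop("design: missing column(s) ", paste(setdiff(req, names(design)),
                                             collapse = ", "))
  bad <- setdiff(unique(design$subtype), c("REF", "ASCL1", "NEUROD1"))
  if (length(bad))
    stop("design: unknown subtype label(s) ", paste(bad, collapse = ", "))
  for (s in unique(design$set_id)) {
    sub <- design[design$set_id == s, ]
    refs <- unique(sub$sample[sub$subtype == "REF"])
    if (length(refs) != 1L)
      stop("design: set ", s, " must contain exactly one reference sample, ",
           "found ", length(refs))
    if (anyDuplicated(sub$channel))
      stop("design: set ", s, " maps a channel twice")
  }
  invisible(design)
}

#' Configuration for the synthetic secretome study generator
#'
#' Collects every parameter of the synthetic-data module. The defaults are
#' the study conditions the pipeline targets: the [default_tmt_design()]
#' layout, 58 up- and 18 down-regulated pan-NE marker proteins and 65
#' subtype-differential proteins planted at 2-fold, 10% multiplicative noise
#' (coefficient of variation), and 76% of proteins placed on the synthetic
#' plasma-detectability list.
#'
#' @param seed Integer seed driving all randomness of the generator.
#' @param n_proteins Number of proteins in the simulated proteome.
#' @param n_shared Number of proteins quantified in every TMT set (the first
#'   `n_shared` protein ids). Remaining proteins are each dropped from one
#'   set, so the cross-set intersection has exactly `n_shared` rows. Planted
#'   markers are always drawn from the shared core.
#' @param design A `sample_design` data frame (see [default_tmt_design()]).
#' @param n_up_pan,n_down_pan Numbers of planted pan-NE markers secreted
#'   more/less in every tumor line relative to the reference.
#' @param n_subtype_markers Number of planted subtype-differential proteins;
#'   directions alternate ASCL1-high / NEUROD1-high.
#' @param effect_fold Linear fold change (>= 1) of planted effects.
#' @param cv Coefficient of variation of the multiplicative log-normal noise
#'   applied per protein x channel (`exp(N(0, cv))`, small-cv convention).
#' @param abundance_meanlog,abundance_sdlog Natural-log parameters of the
#'   log-normal baseline protein abundance.
#' @param n_spectra Number of synthetic MS2 spectra.
#' @param n_noise_peaks Noise peaks per spectrum, all placed at least
#'   0.05 Th away from every reporter center.
#' @param mz_jitter Half-width (Th) of the uniform jitter applied to planted
#'   reporter peak positions; must stay inside the extraction half-window.
#' @param n_psms Number of synthetic peptide-spectrum matches.
#' @param decoy_fraction Fraction of PSMs drawn from the reversed-database
#'   (decoy) population.
#' @param false_target_fraction Fraction of target PSMs that are false
#'   matches (drawn from the decoy score distribution but not flagged).
#' @param score_separation Separation, in within-class standard deviations,
#'   between the true-match and false/decoy Xcorr distributions.
#' @param plasma_fraction Fraction of proteins on the synthetic
#'   plasma-detectability list (planted markers are always included).
#' @param n_genes Number of genes in the synthetic expression matrix.
#' @param n_correlated Number of planted driver-correlated genes.
#' @param expr_samples Named integer vector: samples per subtype in the
#'   synthetic expression matrix.
#' @param expr_noise Noise level of planted correlated genes, as a fraction
#'   of the driver's across-sample standard deviation.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_quant_experiment()], [simulate_spectra()],
#'   [simulate_psm_table()], [simulate_expression_matrix()]
#' @examples
#' cfg <- sim_config(seed = 1, n_proteins = 200)
#' cfg$n_up_pan
#' @export
sim_config <- function(seed = 1L,
                       n_proteins = 1000L,
                       n_shared = n_proteins,
                       design = default_tmt_design(),
                       n_up_pan = 58L,
                       n_down_pan = 18L,
                       n_subtype_markers = 65L,
                       effect_fold = 2,
                       cv = 0.1,
                       abundance_meanlog = 10,
                       abundance_sdlog = 1,
                       n_spectra = 1000L,
                       n_noise_peaks = 10L,
                       mz_jitter = 0.010,
                       n_psms = 10000L,
                       decoy_fraction = 0.5,
                       false_target_fraction = 0.1,
                       score_separation = 3,
                       plasma_fraction = 0.76,
                       n_genes = 1000L,
                       n_correlated = 3L,
                       expr_samples = c(ASCL1 = 27L, NEUROD1 = 12L),
                       expr_noise = 0.3) {
  cfg <- list(
    seed = as.integer(seed), n_proteins = as.integer(n_proteins),
    n_shared = as.integer(n_shared), design = design,
    n_up_pan = as.integer(n_up_pan), n_down_pan = as.integer(n_down_pan),
    n_subtype_markers = as.integer(n_subtype_markers),
    effect_fold = effect_fold, cv = cv,
    abundance_meanlog = abundance_meanlog,
    abundance_sdlog = abundance_sdlog,
    n_spectra = as.integer(n_spectra),
    n_noise_peaks = as.integer(n_noise_peaks), mz_jitter = mz_jitter,
    n_psms = as.integer(n_psms), decoy_fraction = decoy_fraction,
    false_target_fraction = false_target_fraction,
    score_separation = score_separation,
    plasma_fraction = plasma_fraction,
    n_genes = as.integer(n_genes), n_correlated = as.integer(n_correlated),
    expr_samples = expr_samples, expr_noise = expr_noise)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks every invariant of [sim_config()]; errors name the offending
#' field.
#'
#' @param cfg A `sim_config` object.
#' @return `cfg`, invisibly usable, after validation.
#' @export
validate_sim_config <- function(cfg) {
  chk_count <- function(x, nm) {
    if (length(x) != 1L || is.na(x) || x < 0)
      stop("sim_config: field '", nm, "' must be a nonnegative count",
           call. = FALSE)
  }
  for (nm in c("n_proteins", "n_shared", "n_up_pan", "n_down_pan",
               "n_subtype_markers", "n_spectra", "n_noise_peaks", "n_psms",
               "n_genes", "n_correlated"))
    chk_count(cfg[[nm]], nm)
  chk_frac <- function(x, nm) {
    if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop("sim_config: field '", nm, "' must lie in [0, 1]", call. = FALSE)
  }
  chk_frac(cfg$decoy_fraction, "decoy_fraction")
  chk_frac(cfg$false_target_fraction, "false_target_fraction")
  chk_frac(cfg$plasma_fraction, "plasma_fraction")
  if (cfg$effect_fold < 1)
    stop("sim_config: field 'effect_fold' must be >= 1", call. = FALSE)
  if (cfg$cv < 0)
    stop("sim_config: field 'cv' must be >= 0", call. = FALSE)
  if (cfg$n_up_pan + cfg$n_down_pan + cfg$n_subtype_markers > cfg$n_proteins)
    stop("sim_config: planted marker counts (n_up_pan + n_down_pan + ",
         "n_subtype_markers) exceed 'n_proteins'", call. = FALSE)
  if (cfg$n_up_pan + cfg$n_down_pan + cfg$n_subtype_markers > cfg$n_shared)
    stop("sim_config: planted marker counts exceed 'n_shared'",
         call. = FALSE)
  if (cfg$n_shared > cfg$n_proteins)
    stop("sim_config: field 'n_shared' cannot exceed 'n_proteins'",
         call. = FALSE)
  if (cfg$mz_jitter < 0 || cfg$mz_jitter > 0.015)
    stop("sim_config: field 'mz_jitter' must lie in [0, 0.015]",
         call. = FALSE)
  if (cfg$n_correlated >= cfg$n_genes)
    stop("sim_config: field 'n_correlated' must be < 'n_genes'",
         call. = FALSE)
  validate_design(cfg$design)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic secretome study configuration\n")
  cat("  seed:", x$seed, " proteins:", x$n_proteins,
      "(", x$n_shared, "shared across sets )\n")
  cat("  planted markers: pan-NE", x$n_up_pan, "up /", x$n_down_pan,
      "down;", x$n_subtype_markers, "subtype-differential\n")
  cat("  effect fold:", x$effect_fold, " cv:", x$cv, "\n")
  cat("  TMT sets:", length(unique(x$design$set_id)), " samples:",
      length(unique(x$design$sample)), "\n")
  invisible(x)
}
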