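#' Simulate a multi-set TMT quantification experiment with known truth
#'
#' Generates one protein-by-channel quantification table per TMT set of the
#' configured design. Baseline protein abundances are log-normal; planted
#' pan-NE markers are multiplied (up) or divided (down) by
#' `config$effect_fold` in every non-reference sample, and planted subtype
#' markers only in samples of their subtype. Multiplicative log-normal noise
#' `exp(N(0, cv))` is applied independently per protein x channel, so
#' replicate channels of the same sample receive independent noise. With
#' `cv = 0` the realized fold changes equal `effect_fold` exactly.
#'
#' Proteins beyond the shared core (`n_shared`) are each omitted from one
#' TMT set in rotation, so the cross-set intersection of quantified proteins
#' has exactly `n_shared` rows by construction.
#'
#' @param config A [sim_config()].
#' @return A list with elements `tables` (list of [protein_quant_table()],
#'   one per set), `design` (the full `sample_design`), and `truth`, a
#'   `ground_truth` list recording `up_pan_ids`, `down_pan_ids`,
#'   `subtype_marker_ids` (named by protein id, values `"ASCL1"` or
#'   `"NEUROD1"` = the subtype with higher secretion), `plasma_ids`,
#'   `baseline` abundances and per-set protein lists.
#' @examples
#' sim <- simulate_quant_experiment(sim_config(seed = 1, n_proteins = 100,
#'                                             n_up_pan = 5, n_down_pan = 2,
#'                                             n_subtype_markers = 6))
#' sim$tables[[1]]
#' length(sim$truth$up_pan_ids)
#' @export
simulate_quant_experiment <- function(config) {
  config <- validate_sim_config(config)
  withr::with_seed(config$seed, {
    ids <- sprintf("P%04d", seq_len(config$n_proteins))
    shared <- ids[seq_len(config$n_shared)]
    n_plant <- config$n_up_pan + config$n_down_pan + config$n_subtype_markers
    planted <- if (n_plant) sample(shared, n_plant) else character()
    up_ids <- planted[seq_len2(config$n_up_pan)]
    down_ids <- planted[config$n_up_pan + seq_len2(config$n_down_pan)]
    sub_ids <- planted[config$n_up_pan + config$n_down_pan +
                         seq_len2(config$n_subtype_markers)]
    # alternate directions so both volcano tails are populated
    sub_dir <- rep(c("ASCL1", "NEUROD1"),
                   length.out = length(sub_ids))
    names(sub_dir) <- sub_ids

    f <- config$effect_fold
    eff_A <- eff_N <- stats::setNames(rep(1, length(ids)), ids)
    eff_A[up_ids] <- eff_N[up_ids] <- f
    eff_A[down_ids] <- eff_N[down_ids] <- 1 / f
    eff_A[sub_ids[sub_dir == "ASCL1"]] <- f
    eff_N[sub_ids[sub_dir == "NEUROD1"]] <- f

    baseline <- stats::setNames(
      stats::rlnorm(length(ids), config$abundance_meanlog,
                    config$abundance_sdlog), ids)

    sets <- unique(config$design$set_id)
    extras <- setdiff(ids, shared)
    present <- lapply(seq_along(sets), function(si) {
      drop <- extras[(seq_along(extras) - 1L) %% length(sets) + 1L == si]
      setdiff(ids, drop)
    })
    names(present) <- sets

    tables <- lapply(sets, function(s) {
      sub <- config$design[config$design$set_id == s, ]
      p <- present[[s]]
      sn <- matrix(0, length(p), nrow(sub),
                   dimnames = list(p, sub$channel))
      for (j in seq_len(nrow(sub))) {
        e <- switch(sub$subtype[j], REF = rep(1, length(p)),
                    ASCL1 = eff_A[p], NEUROD1 = eff_N[p])
        sn[, j] <- baseline[p] * e *
          exp(stats::rnorm(length(p), 0, config$cv))
      }
      protein_quant_table(sn, sub)
    })
    names(tables) <- sets

    n_plasma <- round(config$plasma_fraction * config$n_proteins)
    pool <- setdiff(ids, planted)
    plasma <- c(planted,
                sample(pool, max(0L, min(length(pool),
                                         n_plasma - length(planted)))))

    truth <- structure(list(
      up_pan_ids = up_ids, down_pan_ids = down_ids,
      subtype_marker_ids = sub_dir, plasma_ids = sort(plasma),
      baseline = baseline, proteins_per_set = present,
      effect_fold = f, cv = config$cv), class = "ground_truth")
    list(tables = tables, design = config$design, truth = truth)
  })
}

# seq_len that tolerates 0 in the middle of an index chain
seq_len2 <- function(n) if (n > 0L) seq_len(n) else integer()

#' Simulate MS2 spectra carrying TMT reporter ions
#'
#' Each spectrum contains exactly one planted peak per reporter channel at
#' the theoretical m/z (jittered uniformly within `config$mz_jitter` Th, by
#' default inside the +/- 0.015 Th extraction window) plus
#' `config$n_noise_peaks` noise peaks placed at least 0.05 Th away from
#' every channel center, so reporter extraction can recover the planted
#' intensities exactly.
#'
#' @param config A [sim_config()].
#' @param channels A [reporter_channels()] definition.
#' @return A list with `spectra` (list of [spectrum()]) and `truth`
#'   containing `true_reporter_intensities`, a spectra x channel matrix of
#'   planted intensities.
#' @examples
#' sp <- simulate_spectra(sim_config(seed = 1, n_spectra = 3,
#'                                   n_noise_peaks = 0))
#' length(sp$spectra[[1]]$mz)  # exactly 6 peaks
#' @export
simulate_spectra <- function(config, channels = reporter_channels()) {
  config <- validate_sim_config(config)
  centers <- channels$theoretical_mz
  lo <- min(centers) - 0.6
  hi <- max(centers) + 0.6
  withr::with_seed(config$seed, {
    spectra <- vector("list", config$n_spectra)
    truth <- matrix(NA_real_, config$n_spectra, length(centers),
                    dimnames = list(sprintf("scan_%05d",
                                            seq_len(config$n_spectra)),
                                    channels$labels))
    for (i in seq_len(config$n_spectra)) {
      planted <- stats::rlnorm(length(centers), 8, 1)
      mzp <- centers + stats::runif(length(centers), -config$mz_jitter,
                                    config$mz_jitter)
      nmz <- numeric(0)
      while (length(nmz) < config$n_noise_peaks) {
        cand <- stats::runif(2L * (config$n_noise_peaks - length(nmz)) + 4L,
                             lo, hi)
        keep <- vapply(cand, function(m) min(abs(m - centers)) >= 0.05,
                       logical(1))
        nmz <- c(nmz, cand[keep])
      }
      nmz <- nmz[seq_len(config$n_noise_peaks)]
      nint <- stats::rlnorm(config$n_noise_peaks, 6, 1)
      mz <- c(mzp, nmz)
      int <- c(planted, nint)
      ord <- order(mz)
      mz <- mz[ord]
      int <- int[ord]
      while (any(diff(mz) <= 0)) {  # astronomically rare duplicate m/z
        dup <- which(diff(mz) <= 0) + 1L
        mz[dup] <- mz[dup] + 1e-6
        ord <- order(mz)
        mz <- mz[ord]
        int <- int[ord]
      }
      spectra[[i]] <- spectrum(rownames(truth)[i], mz, int)
      truth[i, ] <- planted
    }
    list(spectra = spectra,
         truth = structure(list(true_reporter_intensities = truth),
                           class = "ground_truth"))
  })
}

AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Simulate a target-decoy PSM feature table
#'
#' True target matches draw their quality features (Xcorr, delta-Cn,
#' fraction of ions matched, mass accuracy) from a high-scoring
#' distribution; decoys and a configurable fraction of false target matches
#' draw from a shared low-scoring distribution shifted
#' `config$score_separation` within-class standard deviations below the
#' true-match Xcorr mean. Missed cleavages (0-2), charge state (1-4, mostly
#' 2-3) and peptide length are populated for every record, as are
#' per-channel reporter intensities.
#'
#' @param config A [sim_config()].
#' @return A list with `psms`, a data frame with columns `psm_id`,
#'   `peptide`, `proteins` (semicolon-joined), `charge`, `xcorr`,
#'   `delta_cn`, `missed_cleavages`, `mass_error_ppm`, `peptide_length`,
#'   `fraction_ions_matched`, `is_decoy` and one `reporter_*` column per
#'   channel; and `truth` whose `psm_labels` flags the true matches (named
#'   by `psm_id`).
#' @examples
#' tab <- simulate_psm_table(sim_config(seed = 1, n_psms = 100,
#'                                      decoy_fraction = 0.5))
#' sum(tab$psms$is_decoy)  # exactly 50
#' @export
simulate_psm_table <- function(config) {
  config <- validate_sim_config(config)
  withr::with_seed(config$seed, {
    n <- config$n_psms
    n_decoy <- round(config$decoy_fraction * n)
    n_target <- n - n_decoy
    n_false <- round(config$false_target_fraction * n_target)
    is_decoy <- c(rep(FALSE, n_target), rep(TRUE, n_decoy))
    true_match <- c(rep(TRUE, n_target - n_false), rep(FALSE, n_false),
                    rep(FALSE, n_decoy))
    low <- !true_match  # decoys and false targets share the low-score class

    sd0 <- 0.5
    mu_low <- 1.5
    mu_hi <- mu_low + config$score_separation * sd0
    xcorr <- ifelse(low, stats::rnorm(n, mu_low, sd0),
                    stats::rnorm(n, mu_hi, sd0))
    delta_cn <- pmax(0, ifelse(low, stats::rnorm(n, 0.08, 0.05),
                               stats::rnorm(n, 0.25, 0.07)))
    frac <- ifelse(low, stats::rbeta(n, 3, 8), stats::rbeta(n, 8, 3))
    ppm <- pmin(50, pmax(-50, ifelse(low, stats::rnorm(n, 0, 12),
                                     stats::rnorm(n, 0, 4))))
    mc <- sample(0:2, n, replace = TRUE, prob = c(0.7, 0.25, 0.05))
    charge <- sample(1:4, n, replace = TRUE,
                     prob = c(0.05, 0.55, 0.30, 0.10))
    plen <- sample(8:30, n, replace = TRUE)
    peptide <- vapply(plen, function(L)
      paste(sample(AMINO_ACIDS, L, replace = TRUE), collapse = ""),
      character(1))

    pool <- sprintf("P%04d", seq_len(config$n_proteins))
    prot1 <- sample(pool, n, replace = TRUE)
    second <- stats::runif(n) < 0.05
    prot2 <- sample(pool, n, replace = TRUE)
    proteins <- ifelse(second & prot2 != prot1,
                       paste(prot1, prot2, sep = ";"), prot1)
    proteins[is_decoy] <- paste0("rev_", prot1[is_decoy])

    rep_int <- matrix(stats::rlnorm(6L * n, 8, 1), n, 6,
                      dimnames = list(NULL,
                                      paste0("reporter_",
                                             c(126, 127, 128, 129, 130,
                                               131))))
    psms <- data.frame(
      psm_id = sprintf("psm_%06d", seq_len(n)), peptide = peptide,
      proteins = proteins, charge = charge, xcorr = xcorr,
      delta_cn = delta_cn, missed_cleavages = mc, mass_error_ppm = ppm,
      peptide_length = plen, fraction_ions_matched = frac,
      is_decoy = is_decoy, stringsAsFactors = FALSE)
    psms <- cbind(psms, as.data.frame(rep_int))
    truth <- structure(list(psm_labels = stats::setNames(true_match,
                                                         psms$psm_id)),
                       class = "ground_truth")
    list(psms = psms, truth = truth)
  })
}

#' Simulate an FPKM-style expression matrix with a driver gene
#'
#' One designated driver gene (`ASCL1`) is highly expressed in ASCL1-type
#' samples and low in NEUROD1-type samples. Planted driver-correlated genes
#' are positive affine images of the driver's sample profile plus Gaussian
#' noise (truncated at 0 to stay FPKM-like); with `expr_noise = 0` their
#' Pearson correlation with the driver is exactly 1. All remaining genes
#' are independent log-normal.
#'
#' @param config A [sim_config()].
#' @return A list with `em`, an [expression_matrix()] (platform `"fpkm"`),
#'   and `truth` containing `driver` and `driver_correlated_gene_ids`.
#' @examples
#' sim <- simulate_expression_matrix(sim_config(seed = 1, n_genes = 50,
#'                                              n_correlated = 3))
#' sim$truth$driver_correlated_gene_ids
#' @export
simulate_expression_matrix <- function(config) {
  config <- validate_sim_config(config)
  withr::with_seed(config$seed, {
    ns <- config$expr_samples
    subtype <- rep(names(ns), ns)
    samples <- sprintf("%s_%02d", subtype,
                       unlist(lapply(ns, seq_len), use.names = FALSE))
    names(subtype) <- samples
    genes <- c("ASCL1", sprintf("G%04d", seq_len(config$n_genes - 1L)))
    correlated <- sample(genes[-1L], config$n_correlated)

    driver <- ifelse(subtype == "ASCL1", 64, 1) *
      exp(stats::rnorm(length(samples), 0, 0.2))
    vals <- matrix(0, length(genes), length(samples),
                   dimnames = list(genes, samples))
    vals["ASCL1", ] <- driver
    for (g in correlated) {
      a <- stats::runif(1, 0.5, 2)
      noise_sd <- config$expr_noise * stats::sd(driver) * a
      vals[g, ] <- pmax(0, a * driver +
                          stats::rnorm(length(samples), 0, noise_sd))
    }
    rest <- setdiff(genes, c("ASCL1", correlated))
    vals[rest, ] <- stats::rlnorm(length(rest) * length(samples),
                                  log(5), 1)
    em <- expression_matrix(vals, subtype, platform = "fpkm")
    truth <- structure(list(driver = "ASCL1",
                            driver_correlated_gene_ids = sort(correlated)),
                       class = "ground_truth")
    list(em = em, truth = truth)
  })
}

#' Simulate a merged fold-change matrix with planted signatures
#'
#' Generates the reference-relative fold-change matrix directly, one column
#' per non-reference sample of the design, with planted pan-NE and
#' subtype-differential effects and independent multiplicative log-normal
#' noise `exp(N(0, cv))` per protein x sample. This is the object the
#' signature stage consumes, free of the reference-ratio noise compounding
#' that the channel-level generator ([simulate_quant_experiment()])
#' produces, and is the input for signature-recovery studies: with
#' `cv = 0` the fold change of a planted marker equals `effect_fold`
#' exactly in every affected sample.
#'
#' @param config A [sim_config()].
#' @return A list with `matrix` (a [fold_change_matrix()]) and `truth`
#'   (same planted-id structure as [simulate_quant_experiment()]).
#' @examples
#' sim <- simulate_fold_change_matrix(sim_config(seed = 1,
#'                                               n_proteins = 100,
#'                                               n_up_pan = 5,
#'                                               n_down_pan = 2,
#'                                               n_subtype_markers = 4))
#' dim(sim$matrix$fc)
#' @export
simulate_fold_change_matrix <- function(config) {
  config <- validate_sim_config(config)
  withr::with_seed(config$seed, {
    ids <- sprintf("P%04d", seq_len(config$n_proteins))
    n_plant <- config$n_up_pan + config$n_down_pan + config$n_subtype_markers
    planted <- if (n_plant) sample(ids[seq_len(config$n_shared)], n_plant)
               else character()
    up_ids <- planted[seq_len2(config$n_up_pan)]
    down_ids <- planted[config$n_up_pan + seq_len2(config$n_down_pan)]
    sub_ids <- planted[config$n_up_pan + config$n_down_pan +
                         seq_len2(config$n_subtype_markers)]
    sub_dir <- rep(c("ASCL1", "NEUROD1"), length.out = length(sub_ids))
    names(sub_dir) <- sub_ids

    f <- config$effect_fold
    eff_A <- eff_N <- stats::setNames(rep(1, length(ids)), ids)
    eff_A[up_ids] <- eff_N[up_ids] <- f
    eff_A[down_ids] <- eff_N[down_ids] <- 1 / f
    eff_A[sub_ids[sub_dir == "ASCL1"]] <- f
    eff_N[sub_ids[sub_dir == "NEUROD1"]] <- f

    dsn <- config$design[config$design$subtype != "REF", ]
    samples <- unique(dsn$sample)
    subtype <- stats::setNames(
      dsn$subtype[match(samples, dsn$sample)], samples)
    set_id <- stats::setNames(
      dsn$set_id[match(samples, dsn$sample)], samples)
    fc <- matrix(0, length(ids), length(samples),
                 dimnames = list(ids, samples))
    for (j in seq_along(samples)) {
      e <- if (subtype[j] == "ASCL1") eff_A else eff_N
      fc[, j] <- e * exp(stats::rnorm(length(ids), 0, config$cv))
    }
    truth <- structure(list(
      up_pan_ids = up_ids, down_pan_ids = down_ids,
      subtype_marker_ids = sub_dir,
      effect_fold = f, cv = config$cv), class = "ground_truth")
    list(matrix = fold_change_matrix(fc, subtype, set_id), truth = truth)
  })
}
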