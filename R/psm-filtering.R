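PSM_FEATURES <- c("xcorr", "delta_cn", "missed_cleavages", "charge",
                  "mass_error_ppm", "peptide_length",
                  "fraction_ions_matched")

check_psm_table <- function(psms, features = FALSE) {
  req <- c("psm_id", "is_decoy")
  if (features) req <- c(req, PSM_FEATURES)
  miss <- setdiff(req, names(psms))
  if (length(miss))
    stop("PSM table: missing column(s) ", paste(miss, collapse = ", "))
  invisible(psms)
}

#' Drop singly charged peptide-spectrum matches
#'
#' Charge 1+ PSMs are excluded before discriminant scoring, following the
#' standard search-filtering practice for tryptic TMT data.
#'
#' @param psms PSM data frame with a `charge` column.
#' @return The records with `charge >= 2`, order preserved.
#' @examples
#' df <- data.frame(psm_id = 1:4, charge = c(1, 2, 3, 1), is_decoy = FALSE)
#' exclude_singly_charged(df)$psm_id
#' @export
exclude_singly_charged <- function(psms) {
  if (!"charge" %in% names(psms))
    stop("exclude_singly_charged: no 'charge' column")
  psms[psms$charge >= 2, , drop = FALSE]
}

#' Fit a target-vs-decoy linear discriminant over PSM quality features
#'
#' Fisher's linear discriminant on the seven search-quality features
#' (Xcorr, delta-Cn, missed cleavages, charge state, mass accuracy, peptide
#' length, fraction of ions matched), standardized internally so the
#' retained set is invariant to affine rescaling of any input feature. A
#' small ridge term stabilizes the pooled within-class covariance against
#' collinear features. The sign convention is enforced so that higher
#' combined score means more target-like (target mean score above decoy
#' mean score).
#'
#' @param psms PSM data frame containing the feature columns and
#'   `is_decoy`.
#' @param ridge Ridge term added to the diagonal of the pooled
#'   (standardized) covariance.
#' @return An object of class `psm_discriminant`: feature names, weights,
#'   centering/scaling constants.
#' @seealso [score_psms()], [filter_at_fdr()]
#' @export
fit_linear_discriminant <- function(psms, ridge = 1e-6) {
  check_psm_table(psms, features = TRUE)
  if (sum(!psms$is_decoy) < 2L || sum(psms$is_decoy) < 2L)
    stop("fit_linear_discriminant: need at least 2 targets and 2 decoys")
  x <- as.matrix(psms[, PSM_FEATURES])
  if (any(!is.finite(x)))
    stop("fit_linear_discriminant: non-finite feature values")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1  # constant features carry no information
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  g <- psms$is_decoy
  mu_t <- colMeans(xs[!g, , drop = FALSE])
  mu_d <- colMeans(xs[g, , drop = FALSE])
  sw <- ((sum(!g) - 1) * stats::cov(xs[!g, , drop = FALSE]) +
           (sum(g) - 1) * stats::cov(xs[g, , drop = FALSE])) /
    (nrow(xs) - 2)
  w <- tryCatch(
    solve(sw + diag(ridge, ncol(xs)), mu_t - mu_d),
    error = function(e)
      stop("fit_linear_discriminant: singular within-class covariance; ",
           "increase 'ridge' (", conditionMessage(e), ")", call. = FALSE))
  if (sqrt(sum((mu_t - mu_d)^2)) < 1e-10)
    warning("fit_linear_discriminant: target and decoy feature means ",
            "coincide; discriminant has no discrimination power")
  disc <- structure(list(features = PSM_FEATURES, weights = w,
                         center = ctr, scale = scl),
                    class = "psm_discriminant")
  # sign convention: targets must score higher on average
  s <- score_psms(disc, psms)
  if (mean(s[!g]) < mean(s[g])) disc$weights <- -disc$weights
  disc
}

#' Score PSMs with a fitted discriminant
#'
#' @param disc A `psm_discriminant` from [fit_linear_discriminant()].
#' @param psms PSM data frame with the feature columns.
#' @return Numeric vector of combined scores, higher = more target-like.
#' @export
score_psms <- function(disc, psms) {
  x <- as.matrix(psms[, disc$features])
  xs <- sweep(sweep(x, 2, disc$center), 2, disc$scale, "/")
  drop(xs %*% disc$weights)
}

# Threshold sweep of the simple target-decoy FDR estimate #decoy/#target
# (conservative variant (1+#decoy)/#target available). Returns the lowest
# threshold meeting the level; ties at the threshold all retained.
td_threshold <- function(scores, is_decoy, level, conservative = FALSE) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  d <- is_decoy[ord]
  cum_t <- cumsum(!d)
  cum_d <- cumsum(d)
  block_end <- c(diff(s) < 0, TRUE)  # last index of each tied score block
  num <- if (conservative) cum_d + 1 else cum_d
  fdr <- ifelse(cum_t == 0, Inf, num / cum_t)
  ok <- which(block_end & fdr <= level & cum_t > 0)
  if (!length(ok)) return(NULL)
  i <- max(ok)
  list(threshold = unname(s[i]), fdr = unname(fdr[i]))
}

#' Filter PSMs to a target-decoy FDR at peptide and protein level
#'
#' Chooses the lowest score threshold such that the decoy-based FDR
#' estimate `#decoys / #targets` among records scoring at or above it does
#' not exceed `level`, and retains the target PSMs above that threshold.
#' The protein-level pass assigns each protein the maximum score over its
#' PSMs, calls a protein decoy only if all of its PSMs are decoy (shared
#' target/decoy peptides count toward targets), and applies the same
#' threshold rule at the same level.
#'
#' @param psms PSM data frame (`psm_id`, `proteins`, `is_decoy`, ...).
#' @param scores Numeric vector aligned with `psms` rows (e.g. from
#'   [score_psms()]).
#' @param level Target FDR, default 0.01 (the "< 1% matches to the reverse
#'   database" criterion).
#' @param conservative Use the `(1 + #decoys) / #targets` estimate instead
#'   of the plain ratio.
#' @return An object of class `fdr_filter_result`: `score_threshold`,
#'   `retained_psm_ids`, `retained_protein_ids`, `estimated_fdr_peptide`,
#'   `estimated_fdr_protein`, plus counts. If no threshold achieves the
#'   level the retained sets are empty, with a warning.
#' @examples
#' psms <- data.frame(psm_id = letters[1:10],
#'                    proteins = LETTERS[1:10],
#'                    is_decoy = c(rep(FALSE, 5), TRUE, FALSE, FALSE, TRUE,
#'                                 FALSE))
#' sc <- c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1)
#' filter_at_fdr(psms, sc, level = 0.01)$retained_psm_ids
#' @export
filter_at_fdr <- function(psms, scores, level = 0.01,
                          conservative = FALSE) {
  check_psm_table(psms)
  if (length(scores) != nrow(psms))
    stop("filter_at_fdr: scores not aligned with psms")
  if (!any(!psms$is_decoy)) stop("filter_at_fdr: no target PSMs")

  pep <- td_threshold(scores, psms$is_decoy, level, conservative)
  if (is.null(pep)) {
    warning("filter_at_fdr: no score threshold achieves FDR <= ", level,
            "; returning empty retained set")
    retained <- character()
    thr <- Inf
    fdr_pep <- NA_real_
  } else {
    keep <- !psms$is_decoy & scores >= pep$threshold
    retained <- psms$psm_id[keep]
    thr <- pep$threshold
    fdr_pep <- pep$fdr
  }

  # protein level: max score per protein, decoy iff all PSMs decoy
  prot_list <- strsplit(as.character(psms$proteins), ";", fixed = TRUE)
  nrep <- lengths(prot_list)
  flat <- data.frame(protein = unlist(prot_list),
                     score = rep(scores, nrep),
                     decoy = rep(psms$is_decoy, nrep),
                     stringsAsFactors = FALSE)
  pscore <- tapply(flat$score, flat$protein, max)
  pdecoy <- tapply(flat$decoy, flat$protein, all)
  prot <- td_threshold(as.numeric(pscore), as.logical(pdecoy), level,
                       conservative)
  if (is.null(prot)) {
    retained_prot <- character()
    fdr_prot <- NA_real_
  } else {
    retained_prot <- names(pscore)[!pdecoy & pscore >= prot$threshold]
    fdr_prot <- prot$fdr
  }

  structure(list(score_threshold = thr,
                 retained_psm_ids = retained,
                 retained_protein_ids = sort(retained_prot),
                 estimated_fdr_peptide = fdr_pep,
                 estimated_fdr_protein = fdr_prot,
                 n_input = nrow(psms),
                 n_retained = length(retained),
                 level = level),
            class = "fdr_filter_result")
}

#' @export
print.fdr_filter_result <- function(x, ...) {
  cat("Target-decoy FDR filter at level", x$level, "\n")
  cat("  retained", x$n_retained, "of", x$n_input, "PSMs (threshold",
      format(x$score_threshold, digits = 4), ")\n")
  cat("  estimated FDR: peptide", format(x$estimated_fdr_peptide,
                                         digits = 3),
      "/ protein", format(x$estimated_fdr_protein, digits = 3), "\n")
  cat("  retained proteins:", length(x$retained_protein_ids), "\n")
  invisible(x)
}

#' One-call PSM filtering: exclude 1+, fit discriminant, filter at FDR
#'
#' Convenience wrapper chaining [exclude_singly_charged()],
#' [fit_linear_discriminant()], [score_psms()] and [filter_at_fdr()].
#'
#' @inheritParams filter_at_fdr
#' @param psms Full PSM data frame with feature columns.
#' @return The `fdr_filter_result`, with the discriminant attached as
#'   `$discriminant` and the filtered PSM rows as `$retained_psms`.
#' @export
filter_psms <- function(psms, level = 0.01, conservative = FALSE) {
  psms2 <- exclude_singly_charged(psms)
  disc <- fit_linear_discriminant(psms2)
  sc <- score_psms(disc, psms2)
  res <- filter_at_fdr(psms2, sc, level = level,
                       conservative = conservative)
  res$discriminant <- disc
  res$retained_psms <- psms2[psms2$psm_id %in% res$retained_psm_ids, ,
                             drop = FALSE]
  res
}
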