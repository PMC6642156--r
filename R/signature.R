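#' Derive the pan-NE secretome signature (NE-LCSS)
#'
#' A protein enters the upregulated signature when (1) its average linear
#' fold change over all tumor lines (`AveFC_all`, arithmetic mean) is at
#' least `up_threshold` (default 1.5), and (2) it is not differentially
#' secreted between the subtypes: the balance
#' `log2(AveFC_ASCL1 / AveFC_NEUROD1)` is below `balance_threshold`
#' (default 0.2) in absolute value. The downregulated signature mirrors the
#' rule with the reciprocal threshold `AveFC_all <= 1 / up_threshold` and
#' the same balance filter.
#'
#' @param matrix A [fold_change_matrix()] whose columns carry both subtype
#'   labels.
#' @param up_threshold Linear fold-change threshold for the up list (its
#'   reciprocal bounds the down list).
#' @param balance_threshold Bound on `|log2(AveFC_ASCL1/AveFC_NEUROD1)|`.
#' @return An object of class `signature_result`: `up_ids`, `down_ids`,
#'   a per-protein `stats` data frame (`AveFC_all`, `AveFC_ASCL1`,
#'   `AveFC_NEUROD1`, `balance`) and the thresholds used.
#' @examples
#' fc <- matrix(2, 3, 12, dimnames = list(paste0("P", 1:3),
#'                                        paste0("s", 1:12)))
#' st <- setNames(rep(c("ASCL1", "NEUROD1"), c(7, 5)), colnames(fc))
#' derive_ne_lcss(fold_change_matrix(fc, st))$up_ids
#' @export
derive_ne_lcss <- function(matrix, up_threshold = 1.5,
                           balance_threshold = 0.2) {
  stopifnot(inherits(matrix, "fold_change_matrix"))
  if (!all(c("ASCL1", "NEUROD1") %in% matrix$subtype))
    stop("derive_ne_lcss: both subtypes must be represented")
  fc <- matrix$fc
  ave_all <- rowMeans(fc)
  ave_a <- rowMeans(fc[, matrix$subtype == "ASCL1", drop = FALSE])
  ave_n <- rowMeans(fc[, matrix$subtype == "NEUROD1", drop = FALSE])
  balance <- log2(ave_a / ave_n)
  balanced <- abs(balance) < balance_threshold
  up <- rownames(fc)[ave_all >= up_threshold & balanced]
  down <- rownames(fc)[ave_all <= 1 / up_threshold & balanced]
  structure(list(
    up_ids = up, down_ids = down,
    stats = data.frame(protein = rownames(fc), AveFC_all = ave_all,
                       AveFC_ASCL1 = ave_a, AveFC_NEUROD1 = ave_n,
                       balance = balance, row.names = NULL,
                       stringsAsFactors = FALSE),
    up_threshold = up_threshold, balance_threshold = balance_threshold),
    class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat("NE-LCSS:", length(x$up_ids), "up /", length(x$down_ids),
      "down (AveFC >=", x$up_threshold, ", |balance| <",
      x$balance_threshold, ")\n")
  invisible(x)
}

# Newton inversion of the trigamma function on (0, Inf); monotone
# decreasing, so the iteration converges from the standard start 0.5 + 1/x.
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

#' Fit the empirical-Bayes variance prior (scaled inverse chi-square)
#'
#' Method-of-moments fit of the prior degrees of freedom `d0` and prior
#' variance `s0_sq` from per-protein sample variances, using the moments of
#' `log(s2)`: with `e = log(s2) - digamma(d_g/2) + log(d_g/2)`, solve
#' `trigamma(d0/2) = var(e) - trigamma(d_g/2)` by monotone trigamma
#' inversion and recover `s0_sq` from `mean(e)`. When the spread of the
#' observed log-variances does not exceed what sampling alone explains, the
#' prior is degenerate: `d0 = Inf` and `s0_sq = exp(mean(e))`.
#'
#' @param s2 Per-protein sample variances (finite, positive, length >= 10).
#' @param d_g Common residual degrees of freedom (>= 1).
#' @return A list with `d0` (possibly `Inf`) and `s0_sq`.
#' @references Smyth, G.K. (2004) Linear models and empirical Bayes methods
#'   for assessing differential expression in microarray experiments.
#'   Stat. Appl. Genet. Mol. Biol. 3, Article 3.
#' @export
fit_variance_prior <- function(s2, d_g) {
  if (length(s2) < 10L)
    stop("fit_variance_prior: need at least 10 variances")
  if (any(!is.finite(s2)) || any(s2 <= 0))
    stop("fit_variance_prior: variances must be finite and positive")
  if (d_g < 1) stop("fit_variance_prior: d_g must be >= 1")
  e <- log(s2) - digamma(d_g / 2) + log(d_g / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(d_g / 2)
  if (evar <= 0)
    return(list(d0 = Inf, s0_sq = exp(emean)))
  d0 <- 2 * trigamma_inverse(evar)
  s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated two-group t-test with variance shrinkage
#'
#' Per protein: the pooled two-group sample variance `s2` (with
#' `d_g = n1 + n2 - 2` residual df) is shrunk toward the empirical-Bayes
#' prior as `s2_post = (d0 * s0_sq + d_g * s2) / (d0 + d_g)`, and the
#' moderated statistic `t = effect / sqrt(s2_post * (1/n1 + 1/n2))` is
#' referred to a t distribution on `d0 + d_g` degrees of freedom (standard
#' normal when `d0 = Inf`). Forcing `d0 = 0` reproduces the ordinary
#' pooled-variance two-sample t-test exactly. The effect is
#' `mean(group 1) - mean(group 2)` with group 1 = the first factor level
#' (`"ASCL1"` is placed first when present).
#'
#' @param log2fc Numeric matrix, proteins x samples (log2 fold changes).
#' @param groups Two-level factor or character vector aligned with
#'   columns; both groups need at least 2 samples.
#' @param prior Optional list with `d0` and `s0_sq` to override the fitted
#'   prior (use `d0 = 0` or `d0 = Inf` for the limiting cases; with
#'   `d0 = Inf` and no `s0_sq`, the prior variance is fitted).
#' @return A data frame of class `differential_result` with columns
#'   `protein`, `mean_g1`, `mean_g2`, `effect`, `s2`, `s2_post`, `t_mod`,
#'   `df_total`, `p`, `p_adj`, and attributes `d0`, `s0_sq`, `groups`.
#' @export
moderated_t_test <- function(log2fc, groups, prior = NULL) {
  if (!is.matrix(log2fc)) stop("moderated_t_test: log2fc must be a matrix")
  groups <- as.character(groups)
  if (length(groups) != ncol(log2fc))
    stop("moderated_t_test: groups not aligned with columns")
  lev <- unique(groups)
  if (length(lev) != 2L)
    stop("moderated_t_test: exactly two groups required")
  if ("ASCL1" %in% lev) lev <- c("ASCL1", setdiff(lev, "ASCL1"))
  g1 <- groups == lev[1]
  g2 <- groups == lev[2]
  n1 <- sum(g1)
  n2 <- sum(g2)
  if (n1 < 2L || n2 < 2L)
    stop("moderated_t_test: each group needs at least 2 samples")
  if (any(!is.finite(log2fc)))
    stop("moderated_t_test: non-finite values in log2fc")

  x1 <- log2fc[, g1, drop = FALSE]
  x2 <- log2fc[, g2, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  d_g <- n1 + n2 - 2L
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  s2 <- ss / d_g

  if (is.null(prior)) {
    pr <- fit_variance_prior(s2, d_g)
  } else {
    pr <- prior
    if (is.null(pr$s0_sq)) {
      if (is.infinite(pr$d0)) pr$s0_sq <- fit_variance_prior(s2, d_g)$s0_sq
      else if (pr$d0 == 0) pr$s0_sq <- NA_real_
      else stop("moderated_t_test: prior needs s0_sq for finite d0 > 0")
    }
  }
  d0 <- pr$d0
  s0_sq <- pr$s0_sq
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2))
             else if (d0 == 0) s2
             else (d0 * s0_sq + d_g * s2) / (d0 + d_g)

  effect <- m1 - m2
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se == 0, ifelse(effect == 0, 0, sign(effect) * Inf),
                  effect / se)
  df_total <- d0 + d_g
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(t_mod))
       else 2 * stats::pt(-abs(t_mod), df_total)
  res <- data.frame(protein = rownames(log2fc), mean_g1 = unname(m1),
                    mean_g2 = unname(m2), effect = unname(effect),
                    s2 = unname(s2), s2_post = unname(s2_post),
                    t_mod = unname(t_mod), df_total = df_total,
                    p = unname(p), p_adj = unname(bh_adjust(p)),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "d0") <- d0
  attr(res, "s0_sq") <- s0_sq
  attr(res, "groups") <- lev
  class(res) <- c("differential_result", "data.frame")
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up procedure: sort ascending, multiply `p_(i)` by `m / i`,
#' enforce monotonicity by the cumulative minimum from the largest rank,
#' cap at 1, and return in the original order.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("bh_adjust: p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  pmin(1, cummin(m / (m:1) * p[ord]))[order(ord)]
}

#' Derive the ASCL1/NEUROD1 subtype signature (AS/ND-LCSS)
#'
#' Runs the moderated t-test on the log2 fold changes of the ASCL1-high
#' versus NEUROD1-high samples and calls significant every protein with
#' `p_adj < alpha` (Benjamini-Hochberg). The significant set is partitioned
#' by effect sign into proteins secreted more by the ASCL1-high lines and
#' proteins secreted more by the NEUROD1-high lines.
#'
#' @param matrix A [fold_change_matrix()] with both subtypes.
#' @param alpha Adjusted-p cutoff, default 0.05.
#' @param prior Passed to [moderated_t_test()].
#' @return A list of class `asnd_result`: `differential` (the
#'   `differential_result` table), `up_ascl1_ids`, `up_neurod1_ids`,
#'   `alpha`.
#' @export
derive_asnd_lcss <- function(matrix, alpha = 0.05, prior = NULL) {
  stopifnot(inherits(matrix, "fold_change_matrix"))
  diff <- moderated_t_test(matrix$log2fc, matrix$subtype, prior = prior)
  sig <- diff$p_adj < alpha
  structure(list(
    differential = diff,
    up_ascl1_ids = diff$protein[sig & diff$effect > 0],
    up_neurod1_ids = diff$protein[sig & diff$effect < 0],
    alpha = alpha), class = "asnd_result")
}

#' @export
print.asnd_result <- function(x, ...) {
  cat("AS/ND-LCSS at adjusted p <", x$alpha, ":",
      length(x$up_ascl1_ids) + length(x$up_neurod1_ids),
      "proteins (", length(x$up_ascl1_ids), "ASCL1-high /",
      length(x$up_neurod1_ids), "NEUROD1-high )\n")
  invisible(x)
}
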