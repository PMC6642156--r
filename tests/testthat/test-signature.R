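fcm_from <- function(fc) {
  st <- setNames(rep(c("ASCL1", "NEUROD1"), c(7, 5)), colnames(fc))
  fold_change_matrix(fc, st)
}

test_that("NE-LCSS rules follow the fold-change and balance thresholds", {
  fc <- rbind(
    up_flat = rep(2, 12),                       # AveFC 2, balance 0
    skewed = c(rep(2.8, 7), rep(1.2, 5)),       # AveFC 2.13, balance 1.22
    down_flat = rep(0.5, 12),                   # down candidate
    null = rep(1, 12))
  colnames(fc) <- paste0("s", 1:12)
  res <- derive_ne_lcss(fcm_from(fc))
  expect_identical(res$up_ids, "up_flat")
  expect_identical(res$down_ids, "down_flat")
  sk <- res$stats[res$stats$protein == "skewed", ]
  expect_equal(sk$AveFC_all, (2.8 * 7 + 1.2 * 5) / 12)
  expect_equal(sk$balance, log2(2.8 / 1.2))
  expect_gt(abs(sk$balance), 0.2)  # excluded by the subtype-balance rule
  # single-subtype input errors
  one <- fold_change_matrix(fc[, 1:7],
                            setNames(rep("ASCL1", 7), paste0("s", 1:7)))
  expect_error(derive_ne_lcss(one), "subtype")
})

test_that("NE-LCSS thresholds act monotonically and ignore row order", {
  sim <- simulate_fold_change_matrix(small_sim_config())
  base <- derive_ne_lcss(sim$matrix)
  stricter <- derive_ne_lcss(sim$matrix, up_threshold = 2)
  expect_true(all(stricter$up_ids %in% base$up_ids))
  looser_bal <- derive_ne_lcss(sim$matrix, balance_threshold = 0.5)
  expect_true(all(base$up_ids %in% looser_bal$up_ids))
  expect_true(all(base$down_ids %in% looser_bal$down_ids))
  perm <- sim$matrix
  ord <- rev(seq_len(nrow(perm$fc)))
  perm$fc <- perm$fc[ord, ]
  perm$log2fc <- perm$log2fc[ord, ]
  res_p <- derive_ne_lcss(perm)
  expect_setequal(res_p$up_ids, base$up_ids)
  expect_setequal(res_p$down_ids, base$down_ids)
})

test_that("variance prior fitting matches limma and handles the
           degenerate branch", {
  # constant variances: infinite prior df, scale equal to the common
  # variance up to the digamma bias offset of log-chi-square
  pr <- fit_variance_prior(rep(0.3, 50), d_g = 10)
  expect_identical(pr$d0, Inf)
  expect_equal(pr$s0_sq, 0.3 * exp(log(5) - digamma(5)))
  expect_equal(pr$s0_sq, 0.3, tolerance = 0.15)
  # random variances: equality with the independent limma fit
  skip_if_not_installed("limma")
  s2 <- withr::with_seed(11, exp(rnorm(500, -1, 0.8)))
  pr2 <- fit_variance_prior(s2, d_g = 10)
  lf <- limma::fitFDist(s2, df1 = 10)
  expect_equal(pr2$d0, lf$df2, tolerance = 1e-6)
  expect_equal(pr2$s0_sq, lf$scale, tolerance = 1e-6)
  expect_error(fit_variance_prior(c(0.1, 0.2), 4), "at least 10")
  expect_error(fit_variance_prior(c(rep(1, 20), -1), 4), "positive")
})

test_that("variance prior recovers simulating parameters", {
  est <- vapply(1:5, function(s) withr::with_seed(s, {
    sigma2 <- 1 * 4 / rchisq(3000, 4)
    s2 <- sigma2 * rchisq(3000, 10) / 10
    unlist(fit_variance_prior(s2, 10))
  }), numeric(2))
  expect_equal(mean(est["d0", ]), 4, tolerance = 0.2)
  expect_equal(mean(est["s0_sq", ]), 1, tolerance = 0.1)
})

test_that("moderated t reduces to the ordinary pooled t at d0 = 0", {
  x <- withr::with_seed(2, matrix(rnorm(50 * 12), 50, 12,
                                  dimnames = list(paste0("P", 1:50),
                                                  paste0("s", 1:12))))
  g <- rep(c("ASCL1", "NEUROD1"), c(7, 5))
  res <- moderated_t_test(x, g, prior = list(d0 = 0))
  for (i in c(1, 17, 50)) {
    tt <- t.test(x[i, 1:7], x[i, 8:12], var.equal = TRUE)
    expect_equal(res$t_mod[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-12)
  }
  expect_equal(unique(res$df_total), 10)
})

test_that("moderated t at d0 = Inf uses the common prior variance", {
  x <- withr::with_seed(3, matrix(rnorm(30 * 12), 30, 12,
                                  dimnames = list(paste0("P", 1:30),
                                                  paste0("s", 1:12))))
  g <- rep(c("ASCL1", "NEUROD1"), c(7, 5))
  res <- moderated_t_test(x, g, prior = list(d0 = Inf, s0_sq = 0.5))
  eff <- rowMeans(x[, 1:7]) - rowMeans(x[, 8:12])
  expect_equal(res$t_mod,
               unname(eff / (sqrt(0.5) * sqrt(1 / 7 + 1 / 5))))
  expect_equal(res$p, 2 * pnorm(-abs(res$t_mod)))
})

test_that("moderated t agrees with the limma implementation", {
  skip_if_not_installed("limma")
  # heteroscedastic rows so the fitted prior df is finite
  x <- withr::with_seed(4, {
    sds <- sqrt(0.1 * 4 / rchisq(300, 4))
    matrix(rnorm(300 * 12, sd = rep(sds, 12)), 300, 12,
           dimnames = list(sprintf("P%03d", 1:300), paste0("s", 1:12)))
  })
  g <- rep(c("ASCL1", "NEUROD1"), c(7, 5))
  res <- moderated_t_test(x, g)
  expect_true(is.finite(attr(res, "d0")))
  design <- model.matrix(~ 0 + factor(g, levels = c("ASCL1", "NEUROD1")))
  colnames(design) <- c("A", "N")
  fit <- limma::lmFit(x, design)
  fit <- limma::contrasts.fit(fit, limma::makeContrasts(A - N,
                                                        levels = design))
  fit <- limma::eBayes(fit)
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(res, "s0_sq"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t_mod, unname(fit$t[, 1]), tolerance = 1e-6)
  expect_equal(res$p, unname(fit$p.value[, 1]), tolerance = 1e-6)
  expect_equal(res$s2_post, unname(fit$s2.post), tolerance = 1e-6)
  # shrinkage: posterior variance lies between s2 and s0_sq
  s0 <- attr(res, "s0_sq")
  expect_true(all(res$s2_post >= pmin(res$s2, s0) - 1e-12 &
                    res$s2_post <= pmax(res$s2, s0) + 1e-12))
})

test_that("a constant protein with a finite prior gives t = 0, p = 1", {
  x <- withr::with_seed(5, matrix(rnorm(20 * 12, sd = 0.3), 20, 12,
                                  dimnames = list(paste0("P", 1:20),
                                                  paste0("s", 1:12))))
  x[1, ] <- 0.7
  g <- rep(c("ASCL1", "NEUROD1"), c(7, 5))
  res <- moderated_t_test(x, g, prior = list(d0 = 4, s0_sq = 0.09))
  expect_equal(res$t_mod[1], 0)
  expect_equal(res$p[1], 1)
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  withr::with_seed(6, {
    for (i in 1:200) {
      p <- runif(sample(1:40, 1))
      expect_equal(bh_adjust(p), bh_oracle(p))
      expect_equal(bh_adjust(p), p.adjust(p, method = "BH"))
    }
  })
  p <- withr::with_seed(7, runif(100))
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_identical(order(q[order(p)]), seq_along(p))  # order preserved
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("AS/ND signature recovers planted subtype markers", {
  sim <- simulate_fold_change_matrix(small_sim_config(n_proteins = 400,
                                                      n_subtype_markers =
                                                        40))
  res <- derive_asnd_lcss(sim$matrix)
  found <- c(res$up_ascl1_ids, res$up_neurod1_ids)
  planted <- names(sim$truth$subtype_marker_ids)
  expect_gte(length(intersect(found, planted)) / length(planted), 0.95)
  # direction partition matches the planted direction
  dir_a <- names(sim$truth$subtype_marker_ids)[
    sim$truth$subtype_marker_ids == "ASCL1"]
  expect_true(all(intersect(res$up_ascl1_ids, planted) %in% dir_a))
  # significant set shrinks as alpha decreases
  res2 <- derive_asnd_lcss(sim$matrix, alpha = 0.001)
  expect_true(all(c(res2$up_ascl1_ids, res2$up_neurod1_ids) %in% found))
  # null matrix: nothing called
  null_sim <- simulate_fold_change_matrix(
    small_sim_config(n_proteins = 400, n_up_pan = 0, n_down_pan = 0,
                     n_subtype_markers = 0))
  null_res <- derive_asnd_lcss(null_sim$matrix)
  expect_lte(length(c(null_res$up_ascl1_ids, null_res$up_neurod1_ids)), 2)
})
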