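em_from <- function(values, subtype = NULL, platform = "fpkm",
                    probe_map = NULL) {
  if (is.null(subtype))
    subtype <- setNames(rep("ASCL1", ncol(values)), colnames(values))
  expression_matrix(values, subtype, platform, probe_map)
}

test_that("FPKM log transform is exact on reference points", {
  v <- matrix(c(0, 3, 1, 7), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  out <- log_transform_fpkm(em_from(v))
  expect_equal(out$values, matrix(c(0, 2, 1, 3), 2, 2,
                                  dimnames = dimnames(v)))
  expect_equal(out$platform, "log2fpkm")
  expect_error(log_transform_fpkm(out), "platform")
})

test_that("probe-to-gene averaging matches a brute-force per-gene loop", {
  v <- matrix(c(2, 4, 10), 3, 1,
              dimnames = list(c("pr1", "pr2", "pr3"), "s1"))
  pm <- data.frame(probe = c("pr1", "pr2", "pr3"),
                   gene = c("GA", "GA", "GB"))
  out <- probe_to_gene_average(em_from(v, platform = "intensity",
                                       probe_map = pm))
  expect_equal(out$values["GA", "s1"], 3)
  expect_equal(out$values["GB", "s1"], 10)  # single probe unchanged
  # unmapped probe is reported
  pm2 <- pm[1:2, ]
  expect_error(probe_to_gene_average(em_from(v, platform = "intensity",
                                             probe_map = pm2)), "pr3")
  # random fixture against a brute-force loop
  withr::with_seed(8, {
    probes <- sprintf("pr%02d", 1:50)
    genes <- sprintf("G%02d", 1:10)
    map <- data.frame(probe = probes, gene = sample(genes, 50,
                                                    replace = TRUE))
    vv <- matrix(rexp(50 * 6), 50, 6,
                 dimnames = list(probes, paste0("s", 1:6)))
    out2 <- probe_to_gene_average(em_from(vv, platform = "intensity",
                                          probe_map = map))
    for (g in unique(map$gene)) {
      rows <- map$probe[map$gene == g]
      expect_equal(out2$values[g, ],
                   colMeans(vv[rows, , drop = FALSE]))
    }
  })
})

test_that("Welch test matches the textbook formula and t.test", {
  res <- welch_t_test(c(1, 2, 3), c(2, 4, 6))
  expect_equal(res$t, -1.5491933, tolerance = 1e-6)
  expect_equal(res$df, 2.9411765, tolerance = 1e-6)
  tt <- t.test(c(1, 2, 3), c(2, 4, 6))
  expect_equal(res$p, tt$p.value)
  # identical groups: no effect
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # swapping groups flips the sign, p unchanged
  sw <- welch_t_test(c(2, 4, 6), c(1, 2, 3))
  expect_equal(sw$t, -res$t)
  expect_equal(sw$p, res$p)
  expect_error(welch_t_test(c(1, 1), c(2, 2)), "zero variance")
  # Welch df never exceeds the pooled df
  withr::with_seed(9, for (i in 1:20) {
    a <- rnorm(sample(3:8, 1))
    b <- rnorm(sample(3:8, 1))
    expect_lte(welch_t_test(a, b)$df, length(a) + length(b) - 2)
  })
})

test_that("pairwise Pearson matches the summation formula", {
  x <- cbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1))
  r <- pairwise_pearson(x)
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_equal(diag(r), setNames(rep(1, 3), colnames(x)))
  m <- withr::with_seed(10, matrix(rnorm(120), 20, 6,
                                   dimnames = list(NULL,
                                                   paste0("s", 1:6))))
  rm <- pairwise_pearson(m)
  expect_equal(rm, t(rm))
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(rm[i, j], pearson_formula_oracle(m[, i], m[, j]),
                 tolerance = 1e-12)
  # affine maps with positive slope leave the matrix unchanged
  m2 <- sweep(sweep(m, 2, runif(6, 0.5, 2), "*"), 2, rnorm(6), "+")
  expect_equal(pairwise_pearson(m2), rm, tolerance = 1e-12)
  bad <- cbind(s1 = c(1, 1, 1), s2 = c(1, 2, 3))
  expect_error(pairwise_pearson(bad), "s1")
})

test_that("driver-correlation ranking recovers planted genes", {
  sim <- simulate_expression_matrix(small_sim_config(expr_noise = 0))
  # noise-free planted genes are exact positive affine images: r = 1
  top <- top_correlated_genes(sim$em, "ASCL1", k = 4)
  expect_true(all(sim$truth$driver_correlated_gene_ids %in% top$gene))
  expect_equal(top$r[1], 1, tolerance = 1e-12)
  expect_false("ASCL1" %in% top$gene)
  em <- log_transform_fpkm(sim$em)
  expect_equal(nrow(top_correlated_genes(em, "ASCL1", k = 0)), 0L)
  expect_error(top_correlated_genes(em, "NOSUCH"), "NOSUCH")
  # noisy fixture: brute-force ranking agreement
  sim2 <- simulate_expression_matrix(small_sim_config(seed = 2))
  top2 <- top_correlated_genes(sim2$em, "ASCL1", k = 4)
  v <- sim2$em$values
  r <- apply(v[rownames(v) != "ASCL1", ], 1, cor, y = v["ASCL1", ])
  expect_setequal(top2$gene, names(sort(r, decreasing = TRUE))[1:4])
  expect_true(all(sim2$truth$driver_correlated_gene_ids %in% top2$gene))
})

test_that("complete-linkage clustering follows the definition", {
  x <- matrix(c(0, 1, 10), 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  cl <- hierarchical_cluster(x)
  expect_equal(cl$hclust$height, c(1, 10))
  expect_false(is.unsorted(cl$hclust$height))
  # identical items merge at height zero
  x2 <- matrix(c(5, 5, 9), 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(hierarchical_cluster(x2)$hclust$height[1], 0)
  expect_error(hierarchical_cluster(matrix(c(1, NA), 1, 2)), "2 items")
  expect_error(hierarchical_cluster(matrix(c(1, NA, 2, 3), 2, 2)),
               "finite")
  # two planted subtypes separate perfectly at moderate noise
  sim <- simulate_fold_change_matrix(small_sim_config(n_proteins = 200,
                                                      n_subtype_markers =
                                                        30))
  markers <- names(sim$truth$subtype_marker_ids)
  cl2 <- hierarchical_cluster(t(sim$matrix$log2fc[markers, ]))
  expect_equal(cluster_concordance(cl2, 2, sim$matrix$subtype), 1)
})

test_that("adjusted Rand index matches its definition and mclust", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("b", "b", "a", "a")),
               1)
  withr::with_seed(12, {
    ari <- replicate(500, adjusted_rand_index(sample(1:2, 20, TRUE),
                                              sample(1:2, 20, TRUE)))
    expect_lt(abs(mean(ari)), 0.05)
  })
  skip_if_not_installed("mclust")
  withr::with_seed(13, for (i in 1:20) {
    a <- sample(1:3, 30, TRUE)
    b <- sample(1:4, 30, TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b))
  })
})

test_that("Fisher enrichment equals exhaustive enumeration", {
  u <- sprintf("g%02d", 1:20)
  res <- fisher_enrichment(u[1:5], u[1:5], u)
  expect_equal(res$p, 1 / choose(20, 5))
  expect_equal(res$a + res$b + res$c + res$d, 20)
  # overlap equal to selection size when term covers the universe
  expect_equal(fisher_enrichment(character(), u, u)$p, 1)
  expect_error(fisher_enrichment(c(u[1], "zz"), u[1:5], u), "universe")
  # equality with fisher.test and the combinatorial oracle
  withr::with_seed(14, for (i in 1:8) {
    usize <- sample(c(8, 12, 18, 25), 1)
    uu <- sprintf("x%02d", seq_len(usize))
    term <- sample(uu, sample(2:(usize - 1), 1))
    sel <- sample(uu, sample(2:5, 1))
    r <- fisher_enrichment(sel, term, uu)
    ft <- fisher.test(matrix(c(r$a, r$b, r$c, r$d), 2, 2,
                             byrow = TRUE), alternative = "greater")
    expect_equal(r$p, ft$p.value, tolerance = 1e-12)
    expect_equal(r$p, fisher_enum_oracle(sel, term, uu),
                 tolerance = 1e-12)
  })
  # multiple terms: BH across terms
  multi <- fisher_enrichment(u[1:5], list(t1 = u[1:5], t2 = u[6:10]), u)
  expect_equal(multi$p_adj, bh_adjust(multi$p))
})

test_that("E-box scanning reports all overlapping forward matches", {
  hit <- scan_ebox("AACAGCTGTT")
  expect_equal(hit$position, 2L)
  expect_equal(hit$motif, "CAGCTG")
  expect_equal(nrow(scan_ebox("TTTTTT")), 0L)
  # overlapping motifs all reported
  expect_equal(scan_ebox("CACATGTG")$position, c(0L, 2L))
  expect_error(scan_ebox("ACGTXA"), "invalid")
  # N matches only the free middle positions
  expect_equal(nrow(scan_ebox("CANNTG")), 1L)
  expect_equal(nrow(scan_ebox("NANNTG")), 0L)
  withr::with_seed(15, for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    expect_equal(scan_ebox(s)$position, ebox_oracle(s))
    # motif class is reverse-complement symmetric
    rc <- reverse_complement(s)
    expect_setequal(300 - 6 - scan_ebox(s)$position,
                    scan_ebox(rc)$position)
  })
})
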