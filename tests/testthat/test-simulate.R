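test_that("invalid configurations are rejected with the offending field", {
  expect_error(sim_config(effect_fold = 0.5), "effect_fold")
  expect_error(sim_config(cv = -0.1), "cv")
  expect_error(sim_config(decoy_fraction = 1.5), "decoy_fraction")
  expect_error(sim_config(plasma_fraction = -0.1), "plasma_fraction")
  expect_error(sim_config(n_proteins = 10, n_up_pan = 8, n_down_pan = 8,
                          n_subtype_markers = 0), "n_proteins")
  d <- default_tmt_design()
  d$subtype[d$subtype == "REF"] <- "ASCL1"
  expect_error(sim_config(design = d), "reference")
})

test_that("identical seed and config reproduce identical outputs", {
  cfg <- small_sim_config(seed = 7)
  a <- simulate_quant_experiment(cfg)
  b <- simulate_quant_experiment(cfg)
  expect_identical(a, b)
  expect_identical(simulate_spectra(cfg), simulate_spectra(cfg))
  expect_identical(simulate_psm_table(cfg), simulate_psm_table(cfg))
  expect_identical(simulate_expression_matrix(cfg),
                   simulate_expression_matrix(cfg))
  expect_identical(simulate_fold_change_matrix(cfg),
                   simulate_fold_change_matrix(cfg))
  # a different seed changes the draw
  expect_false(identical(
    a, simulate_quant_experiment(small_sim_config(seed = 8))))
})

test_that("noise-free planted effects are exact fold changes", {
  cfg <- small_sim_config(cv = 0, effect_fold = 2)
  sim <- simulate_quant_experiment(cfg)
  for (tab in sim$tables) {
    dsn <- tab$design
    ref_ch <- dsn$channel[dsn$subtype == "REF"][1]
    for (p in sim$truth$up_pan_ids) {
      for (ch in dsn$channel[dsn$subtype != "REF"])
        expect_equal(tab$sn[p, ch], 2 * tab$sn[p, ref_ch])
    }
    for (p in sim$truth$down_pan_ids)
      expect_equal(tab$sn[p, dsn$channel[3]],
                   tab$sn[p, ref_ch] *
                     (if (dsn$subtype[3] == "REF") 1 else 0.5))
  }
  fcm <- simulate_fold_change_matrix(cfg)
  expect_true(all(fcm$matrix$fc[fcm$truth$up_pan_ids, ] == 2))
  expect_true(all(fcm$matrix$fc[fcm$truth$down_pan_ids, ] == 0.5))
})

test_that("ground truth has the configured study sizes and is disjoint", {
  sim <- simulate_quant_experiment(sim_config(seed = 3, n_proteins = 1000,
                                              n_up_pan = 58,
                                              n_down_pan = 18,
                                              n_spectra = 1, n_psms = 100))
  tr <- sim$truth
  expect_length(tr$up_pan_ids, 58)
  expect_length(tr$down_pan_ids, 18)
  expect_length(tr$subtype_marker_ids, 65)
  all_ids <- c(tr$up_pan_ids, tr$down_pan_ids,
               names(tr$subtype_marker_ids))
  expect_false(anyDuplicated(all_ids) > 0)
  # every planted id exists in every generated table
  for (tab in sim$tables)
    expect_true(all(all_ids %in% rownames(tab$sn)))
  expect_true(all(all_ids %in% tr$plasma_ids))
})

test_that("shared-core construction controls the cross-set intersection", {
  sim <- simulate_quant_experiment(
    sim_config(seed = 2, n_proteins = 1000, n_shared = 800,
               n_up_pan = 10, n_down_pan = 5, n_subtype_markers = 10))
  common <- Reduce(intersect, lapply(sim$tables,
                                     function(t) rownames(t$sn)))
  expect_length(common, 800)
})

test_that("simulated spectra have the constructed peak layout", {
  cfg0 <- small_sim_config(n_noise_peaks = 0)
  sp0 <- simulate_spectra(cfg0)
  expect_true(all(vapply(sp0$spectra, function(s) length(s$mz),
                         integer(1)) == 6L))
  cfg <- small_sim_config(n_noise_peaks = 12)
  sp <- simulate_spectra(cfg)
  centers <- reporter_channels()$theoretical_mz
  for (s in sp$spectra) {
    expect_false(is.unsorted(s$mz, strictly = TRUE))
    near <- vapply(s$mz, function(m) min(abs(m - centers)), numeric(1))
    # noise peaks at >= 0.05 Th from every center; planted within jitter
    expect_true(all(near <= 0.010 + 1e-12 | near >= 0.05))
    expect_equal(sum(near <= 0.015), 6L)
  }
  # planted intensities recorded per scan and channel
  s1 <- sp$spectra[[1]]
  for (j in seq_along(centers)) {
    k <- which.min(abs(s1$mz - centers[j]))
    expect_equal(s1$intensity[k],
                 sp$truth$true_reporter_intensities[s1$scan_id, j])
  }
})

test_that("PSM tables have the configured composition", {
  tab <- simulate_psm_table(small_sim_config(n_psms = 100,
                                             decoy_fraction = 0.5))
  expect_equal(sum(tab$psms$is_decoy), 50L)
  expect_true(all(tab$psms$charge %in% 1:4))
  expect_true(all(tab$psms$missed_cleavages %in% 0:2))
  expect_true(all(tab$psms$fraction_ions_matched >= 0 &
                    tab$psms$fraction_ions_matched <= 1))
  expect_true(all(grepl("^rev_", tab$psms$proteins[tab$psms$is_decoy])))
  # wide class separation makes the Xcorr feature perfectly separating
  wide <- simulate_psm_table(small_sim_config(n_psms = 400,
                                              score_separation = 8))
  true_x <- wide$psms$xcorr[wide$truth$psm_labels[wide$psms$psm_id]]
  decoy_x <- wide$psms$xcorr[wide$psms$is_decoy]
  expect_gt(min(true_x), max(decoy_x))
})

test_that("expression simulation plants recoverable driver correlations", {
  noise0 <- simulate_expression_matrix(small_sim_config(expr_noise = 0))
  v <- noise0$em$values
  for (g in noise0$truth$driver_correlated_gene_ids)
    expect_equal(cor(v[g, ], v["ASCL1", ]), 1)
  sim <- simulate_expression_matrix(small_sim_config())
  expect_true(all(sim$em$values >= 0))
  # brute-force correlation ranking: planted genes fill the top ranks
  r <- apply(sim$em$values[rownames(sim$em$values) != "ASCL1", ], 1,
             cor, y = sim$em$values["ASCL1", ])
  top4 <- names(sort(r, decreasing = TRUE))[1:4]
  expect_true(all(sim$truth$driver_correlated_gene_ids %in% top4))
})
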