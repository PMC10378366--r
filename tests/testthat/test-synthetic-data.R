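test_that("profile generator is deterministic, valid, and centred on anchors", {
  cfg <- synthetic_config(seed = 101)
  reps <- generate_profiles(cfg)
  expect_identical(reps, generate_profiles(synthetic_config(seed = 101)))
  expect_equal(nrow(reps), 8 * 4 * 9)
  # every replicate renormalised to exactly 100
  sums <- reps |>
    dplyr::summarise(s = sum(percent), .by = c("blend", "replicate"))
  expect_equal(sums$s, rep(100, nrow(sums)), tolerance = 1e-9)

  # zero noise: replicates differ from anchors only by renormalisation
  quiet <- generate_profiles(synthetic_config(seed = 1,
                                              profile_noise_scale = 0))
  anchors <- oil_blend_profiles()
  one <- quiet |>
    dplyr::filter(blend == "BcH", replicate == 1)
  anch <- dplyr::filter(anchors, blend == "BcH")
  expect_equal(one$percent[match(anch$acid, one$acid)],
               anch$percent / sum(anch$percent) * 100, tolerance = 1e-9)
})

test_that("replicate means converge to the anchors (law of large numbers)", {
  cfg <- synthetic_config(seed = 77, n_replicates = 1000)
  reps <- generate_profiles(cfg)
  anchors <- oil_blend_profiles()
  means <- reps |>
    dplyr::summarise(m = mean(percent), .by = c("blend", "acid")) |>
    dplyr::left_join(anchors[c("blend", "acid", "percent", "sd")],
                     by = c("blend", "acid"))
  # within 3 standard errors for acids with meaningful SD (truncation at
  # zero and renormalisation shift near-zero acids slightly)
  big <- means[dplyr::coalesce(means$sd, 0) > 0.05, ]
  se <- big$sd / sqrt(1000)
  expect_true(all(abs(big$m - big$percent) < 3 * se + 0.02))
})

test_that("heating generator encodes the degradation structure", {
  cfg0 <- synthetic_config(seed = 5, heating_noise_sd = 0)
  exact <- generate_heating_table(cfg0)
  w <- exact |>
    dplyr::summarise(tpc = mean(tpc), dimer = mean(dimer),
                     trimer = mean(trimer), .by = c("blend", "condition")) |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("tpc", "dimer", "trimer"))
  expect_true(all(w$tpc_unheated < w$`tpc_170C`))
  expect_true(all(w$`tpc_170C` < w$`tpc_200C`))
  expect_true(all(w$dimer_unheated == 0))
  expect_true(all(w$`dimer_170C` < w$`dimer_200C`))
  # trimers only at 200C and only in the configured subset
  expect_true(all(w$trimer_unheated == 0) && all(w$`trimer_170C` == 0))
  expect_equal(sort(w$blend[w$`trimer_200C` > 0]),
               sort(c("HRbR", "RBc", "RMt")))

  none <- generate_heating_table(
    synthetic_config(seed = 5, trimer_blends = character(0))
  )
  expect_true(all(none$trimer == 0))

  noisy <- generate_heating_table(synthetic_config(seed = 6))
  expect_identical(noisy, generate_heating_table(synthetic_config(seed = 6)))
})

test_that("generated replicates separate unheated from 200C at alpha 0.05", {
  cfg <- synthetic_config(seed = 13)
  recs <- generate_heating_table(cfg)
  summ <- summarize_heating(recs) |>
    dplyr::filter(measure == "tpc")
  for (bl in unique(summ$blend)) {
    g <- summ |>
      dplyr::filter(blend == bl) |>
      dplyr::transmute(label = condition, mean, sd, n)
    cld <- tukey_cld(g, alpha = 0.05)
    expect_length(
      intersect(
        strsplit(cld$letters[cld$label == "unheated"], "")[[1]],
        strsplit(cld$letters[cld$label == "200C"], "")[[1]]
      ),
      0
    )
  }
})

test_that("NMR generator round-trips and preserves the tau_c ranking", {
  ref <- oil_blend_relaxometry()
  clean <- generate_nmr_dataset(synthetic_config(seed = 1, nmr_noise_sd = 0))
  fits <- clean |>
    dplyr::mutate(fit = purrr::map(curve, fit_relaxation)) |>
    dplyr::mutate(est = purrr::map_dbl(fit, "relaxation_time"))
  ir <- dplyr::filter(fits, kind == "inversion_recovery")
  cp <- dplyr::filter(fits, kind == "cpmg")
  expect_equal(ir$est, ref$t1_ms[match(ir$blend, ref$blend)],
               tolerance = 1e-6)
  expect_equal(cp$est, ref$t2_ms[match(cp$blend, ref$blend)],
               tolerance = 1e-6)

  # noisy dataset: recovered pairs still reproduce the published ranking
  noisy <- generate_nmr_dataset(synthetic_config(seed = 21))
  est <- noisy |>
    dplyr::mutate(est = purrr::map_dbl(curve, \(cv)
      fit_relaxation(cv)$relaxation_time)) |>
    dplyr::select(-"curve") |>
    tidyr::pivot_wider(names_from = "kind", values_from = "est")
  tc <- invert_tau_c(est$inversion_recovery, est$cpmg)
  expect_identical(order(tc$tau_c_s),
                   order(ref$tau_c_s[match(est$blend, ref$blend)]))

  expect_identical(generate_nmr_dataset(synthetic_config(seed = 21)), noisy)
  expect_error(
    generate_nmr_dataset(synthetic_config(seed = 1),
                         true_params = data.frame(blend = "x", t1_ms = 50,
                                                  t2_ms = 80)),
    class = "oilblendr_parameter_error"
  )
})
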