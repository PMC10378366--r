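heating <- oil_blend_heating()
tpc_wide <- heating |>
  dplyr::filter(measure == "tpc") |>
  tidyr::pivot_wider(id_cols = "blend", names_from = "condition",
                     values_from = "mean")

test_that("fold change is plain division with a zero-baseline guard", {
  expect_equal(fold_change(1.84, 7.96), 4.326087, tolerance = 1e-6)
  expect_equal(fold_change(3.5, 3.5), 1)
  expect_error(fold_change(0, 1.2), class = "oilblendr_zero_baseline")
})

test_that("TPC rises monotonically with heating temperature in every blend", {
  expect_true(all(tpc_wide$unheated < tpc_wide$`170C`))
  expect_true(all(tpc_wide$`170C` < tpc_wide$`200C`))
})

test_that("all heated records comply with the 24% TPC limit", {
  heated <- heating |>
    dplyr::filter(measure == "tpc") |>
    dplyr::rename(tpc = "mean")
  res <- compliance_check(heated, limit = 24)
  expect_true(all(res$pass))
  hmtr <- res[res$blend == "HMtR" & res$condition == "200C", ]
  expect_equal(hmtr$margin, 24 - 14.98, tolerance = 1e-9)
  # strict inequality at the boundary
  expect_false(compliance_check(data.frame(tpc = 24))$pass)
  expect_false(compliance_check(data.frame(tpc = 30))$pass)
})

test_that("Tukey letters separate clearly distinct groups and merge identical ones", {
  wide <- tukey_cld(data.frame(label = c("lo", "mid", "hi"),
                               mean = c(0, 10, 20), sd = 0.1, n = 4))
  expect_equal(wide$letters, c("a", "b", "c"))

  same <- tukey_cld(data.frame(label = c("x", "y", "z"),
                               mean = c(5, 5, 5), sd = 1, n = 4))
  expect_equal(same$letters, rep("a", 3))

  expect_error(tukey_cld(data.frame(label = "a", mean = 1, sd = 1, n = 4)),
               class = "oilblendr_validation_error")
  expect_error(
    tukey_cld(data.frame(label = c("a", "b"), mean = c(1, 2),
                         sd = c(0.1, 0.1), n = c(1, 1))),
    class = "oilblendr_insufficient_replication"
  )
})

test_that("unheated LRb and RP differ, matching the published superscripts", {
  un <- heating |>
    dplyr::filter(measure == "tpc", condition == "unheated") |>
    dplyr::rename(label = "blend")
  cld <- tukey_cld(un, alpha = 0.05)
  l_lrb <- strsplit(cld$letters[cld$label == "LRb"], "")[[1]]
  l_rp <- strsplit(cld$letters[cld$label == "RP"], "")[[1]]
  expect_length(intersect(l_lrb, l_rp), 0)
})

test_that("CLD letters agree with the all-pairs oracle on random problems", {
  set.seed(31)
  for (rep in 1:20) {
    k <- sample(3:8, 1)
    groups <- data.frame(
      label = paste0("g", seq_len(k)),
      mean = runif(k, 0, 10),
      sd = runif(k, 0.2, 1.5),
      n = sample(3:6, k, replace = TRUE)
    )
    cld <- tukey_cld(groups, alpha = 0.05)
    expect_true(cld_matches_all_pairs(groups, cld, alpha = 0.05))
  }
})

test_that("CLD letters are invariant to group order", {
  groups <- data.frame(
    label = c("a", "b", "c", "d", "e"),
    mean = c(1, 1.2, 4, 4.1, 9),
    sd = c(0.4, 0.5, 0.4, 0.6, 0.5),
    n = 4
  )
  base <- tukey_cld(groups)
  perm <- groups[c(4, 1, 5, 3, 2), ]
  shuffled <- tukey_cld(perm)
  expect_equal(shuffled$letters[match(base$label, shuffled$label)],
               base$letters)
})

test_that("standardised PCA matches the closed-form 2x2 eigen oracle", {
  z <- withr::with_seed(12, matrix(rnorm(16), nrow = 8,
                                   dimnames = list(NULL, c("u", "v"))))
  res <- pca_standardized(z)
  r <- cor(z)[1, 2]
  # eigenvalues of a 2x2 correlation matrix are 1 +/- |r|
  expect_equal(res$eigenvalues, c(1 + abs(r), 1 - abs(r)),
               tolerance = 1e-12)
  expect_equal(res$explained, c(1 + abs(r), 1 - abs(r)) / 2 * 100,
               tolerance = 1e-12)

  # rank-1 case: perfectly correlated columns
  x <- cbind(a = 1:8, b = (1:8) * 3 + 2)
  expect_equal(pca_standardized(x)$explained[1], 100, tolerance = 1e-9)
})

test_that("PCA reconstruction, ordering, and error handling", {
  x <- withr::with_seed(3, matrix(rnorm(8 * 5), nrow = 8,
                                  dimnames = list(NULL, letters[1:5])))
  res <- pca_standardized(x)
  expect_true(all(diff(res$explained) <= 1e-12))
  expect_equal(sum(res$explained), 100, tolerance = 1e-9)
  # unit-norm loadings, orthonormal; full reconstruction of scaled data
  expect_equal(colSums(res$loadings^2), rep(1, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(res$scores %*% t(res$loadings), scale(x),
               tolerance = 1e-9, ignore_attr = TRUE)
  # sign convention: largest-magnitude loading positive per component
  for (j in 1:5) {
    col <- res$loadings[, j]
    expect_gt(col[which.max(abs(col))], 0)
  }

  bad <- cbind(x, const = 1)
  expect_error(pca_standardized(bad), class = "oilblendr_zero_variance")
  expect_error(pca_standardized(x[1, , drop = FALSE]),
               class = "oilblendr_validation_error")
})

test_that("PCA of the blend means shows PUFA and CIV loading together on Dim1", {
  prof <- oil_blend_profiles()
  shares <- class_shares(prof) |> omega_ratio()
  relax <- oil_blend_relaxometry()
  mat <- shares |>
    dplyr::left_join(calculated_iodine_value(prof), by = "blend") |>
    dplyr::left_join(relax[c("blend", "water_ppm", "t1_ms", "t2_ms",
                             "oit_min")], by = "blend") |>
    dplyr::select("blend", "sfa", "mufa", "pufa", "civ", "omega_ratio",
                  "water_ppm", "t1_ms", "t2_ms", "oit_min")
  res <- pca_standardized(mat)
  l1 <- res$loadings[, 1]
  # PUFA and CIV co-vary (they load on the same side of Dim1), and MUFA
  # opposes them — the sign structure of the reported correlations
  expect_gt(l1[["pufa"]] * l1[["civ"]], 0)
  expect_lt(l1[["mufa"]] * l1[["pufa"]], 0)
  expect_s3_class(autoplot(res), "ggplot")
})
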