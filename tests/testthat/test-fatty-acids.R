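test_that("acid shorthand parses and classifies correctly", {
  key <- parse_fa_key(c("C16:0", "C16:1", "C18:1", "C18:2", "C18:3", "C20:4"))
  expect_equal(key$carbons, c(16, 16, 18, 18, 18, 20))
  expect_equal(key$double_bonds, c(0, 1, 1, 2, 3, 4))
  expect_equal(
    key$omega_class,
    c("saturated", "omega9", "omega9", "omega6", "omega3",
      "other_unsaturated")
  )
  expect_error(parse_fa_key("18:2"), class = "oilblendr_parse_error")
  expect_error(parse_fa_key("C2:0"), class = "oilblendr_parse_error")
})

test_that("profile validation accepts real rows and rejects bad sums", {
  # the bundled RBc row sums to 100.01 and must validate
  rbc <- dplyr::filter(oil_blend_profiles(), blend == "RBc")
  expect_equal(sum(rbc$percent), 100.01, tolerance = 1e-12)
  expect_equal(rbc$percent[rbc$acid == "C20:1"], 0)  # nd -> 0

  one <- parse_profile(data.frame(acid = "C18:0", percent = 100))
  expect_equal(one$omega_class, "saturated")

  expect_error(
    parse_profile(data.frame(acid = c("C18:0", "C18:1"),
                             percent = c(45, 45))),
    class = "oilblendr_validation_error"
  )
  expect_error(
    parse_profile(data.frame(acid = "C18:0", percent = 120)),
    class = "oilblendr_validation_error"
  )
})

test_that("class shares partition the profile and match printed values", {
  p <- oil_blend_profiles()
  s <- class_shares(p)
  # partition: sfa + mufa + pufa equals the profile sum, every blend
  expect_equal(s$sfa + s$mufa + s$pufa, s$total, tolerance = 1e-12)
  expect_equal(s$ufa, s$mufa + s$pufa, tolerance = 1e-12)
  expect_true(all(s$omega3 + s$omega6 <= s$pufa + 1e-9))
  # published shares for the hemp-rich blend
  bch <- s[s$blend == "BcH", ]
  expect_equal(bch$mufa, 20.42, tolerance = 1e-9)
  expect_equal(bch$pufa, 67.83, tolerance = 1e-9)

  only_sat <- parse_profile(data.frame(acid = "C18:0", percent = 100))
  ss <- class_shares(only_sat)
  expect_equal(c(ss$sfa, ss$mufa, ss$pufa), c(100, 0, 0))
})

test_that("omega ratio reproduces the printed blend ratios", {
  s <- class_shares(oil_blend_profiles()) |> omega_ratio()
  expect_equal(s$omega_ratio[s$blend == "RMt"], 5.25, tolerance = 0.01)
  expect_equal(s$omega_ratio[s$blend == "PLRb"], 5.20, tolerance = 0.01)
  eq <- tibble::tibble(blend = "x", sfa = 0, mufa = 0, pufa = 20,
                       omega3 = 10, omega6 = 10, ufa = 20, total = 100)
  expect_equal(omega_ratio(eq)$omega_ratio, 1)
  eq$omega3 <- 0
  expect_error(omega_ratio(eq), class = "oilblendr_undefined_ratio")
})

test_that("mixing is the weighted per-acid mean, symmetric, with identity", {
  p <- oil_blend_profiles()
  a <- dplyr::filter(p, blend == "RBc")
  b <- dplyr::filter(p, blend == "BcH")

  id <- mix_profiles(list(a, b), c(1, 0))
  expect_equal(
    dplyr::arrange(id, acid)$percent[dplyr::arrange(id, acid)$percent > 0],
    dplyr::arrange(a, acid)$percent[dplyr::arrange(a, acid)$percent > 0],
    tolerance = 1e-12
  )

  half <- mix_profiles(list(a, b), c(0.5, 0.5))
  manual <- dplyr::full_join(
    a[c("acid", "percent")], b[c("acid", "percent")], by = "acid"
  )
  manual_pct <- (dplyr::coalesce(manual$percent.x, 0) +
                   dplyr::coalesce(manual$percent.y, 0)) / 2
  expect_equal(half$percent[match(manual$acid, half$acid)], manual_pct,
               tolerance = 1e-12)

  flipped <- mix_profiles(list(b, a), c(0.5, 0.5))
  expect_equal(dplyr::arrange(half, acid)$percent,
               dplyr::arrange(flipped, acid)$percent, tolerance = 1e-12)

  expect_error(mix_profiles(list(a, b), c(0.6, 0.6)),
               class = "oilblendr_validation_error")
})

test_that("mixing commutes with class shares (linearity)", {
  p <- oil_blend_profiles()
  blends <- unique(p$blend)
  set.seed(42)
  for (i in 1:5) {
    pick <- sample(blends, 2)
    w <- runif(1)
    a <- dplyr::filter(p, blend == pick[1])
    b <- dplyr::filter(p, blend == pick[2])
    mixed <- class_shares(mix_profiles(list(a, b), c(w, 1 - w)))
    sa <- class_shares(a); sb <- class_shares(b)
    for (col in c("sfa", "mufa", "pufa", "omega3", "omega6")) {
      expect_equal(mixed[[col]], w * sa[[col]] + (1 - w) * sb[[col]],
                   tolerance = 1e-9)
    }
  }
})

test_that("binary blend solver matches grid search and rejects infeasible targets", {
  a <- toy_profile("A", 60, 5)
  b <- toy_profile("B", 20, 15)
  w <- formulate_binary_blend(a, b, 5)
  expect_equal(w, 55 / 90, tolerance = 1e-9)
  expect_equal(w, grid_search_blend_w(60, 5, 20, 15, 5), tolerance = 1e-4)

  # substituting w back reproduces the target exactly
  mixed <- mix_profiles(list(a, b), c(w, 1 - w))
  got <- omega_ratio(class_shares(mixed))$omega_ratio
  expect_equal(got, 5, tolerance = 1e-9)

  # component already on target
  expect_equal(formulate_binary_blend(toy_profile("A", 50, 10), b, 5), 1)

  # both components above the target: infeasible
  expect_error(
    formulate_binary_blend(toy_profile("A", 60, 5), toy_profile("B", 70, 5), 5),
    class = "oilblendr_infeasible"
  )
})

test_that("solver round-trips on random feasible problems", {
  set.seed(7)
  for (i in 1:20) {
    o6 <- runif(2, 10, 60); o3 <- runif(2, 2, 20)
    r <- sort(o6 / o3)
    target <- runif(1, r[1] + 0.01, r[2] - 0.01)
    a <- toy_profile("A", o6[1], o3[1])
    b <- toy_profile("B", o6[2], o3[2])
    w <- formulate_binary_blend(a, b, target)
    mixed <- mix_profiles(list(a, b), c(w, 1 - w))
    expect_equal(omega_ratio(class_shares(mixed))$omega_ratio, target,
                 tolerance = 1e-9)
  }
})
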