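# Per-acid iodine contribution factors (g I2 per 100 g per percent),
# AOCS-style calculated iodine value from composition.
civ_factors <- c(
  "C16:1" = 0.95, "C18:1" = 0.86, "C18:2" = 1.732,
  "C18:3" = 2.616, "C20:1" = 0.785, "C22:1" = 0.723
)

# percent of a named acid per blend, 0 when absent
acid_percent <- function(profile, acid) {
  profile |>
    dplyr::summarise(
      value = sum(.data$percent[.data$acid == .env$acid]),
      .by = "blend"
    )
}

acid_percents <- function(profile, acids) {
  vals <- purrr::map(acids, \(a) acid_percent(profile, a)$value)
  out <- acid_percent(profile, acids[1])["blend"]
  for (i in seq_along(acids)) out[[acids[i]]] <- vals[[i]]
  out
}

#' PUFA/SFA ratio
#'
#' @param shares A class-shares tibble from [class_shares()].
#' @return A tibble with columns `blend`, `pufa_sfa`.
#' @examples
#' oil_blend_profiles() |> class_shares() |> pufa_sfa()
#' @export
pufa_sfa <- function(shares) {
  if (any(shares$sfa <= 0)) {
    rlang::abort("PUFA/SFA undefined: SFA share is zero",
                 class = "oilblendr_undefined_index")
  }
  tibble::tibble(blend = shares$blend,
                 pufa_sfa = shares$pufa / shares$sfa)
}

#' Index of atherogenicity (IA)
#'
#' IA = (C12:0 + 4 x C14:0 + C16:0) / sum(UFA). Lauric and myristic acids
#' weigh more heavily than palmitic; unsaturates are protective. Absent
#' acids contribute 0.
#'
#' @param profile A parsed profile tibble.
#' @param shares Optional precomputed [class_shares()] of `profile`.
#' @return A tibble with columns `blend`, `ia`.
#' @examples
#' oil_blend_profiles() |> atherogenicity_index()
#' @export
atherogenicity_index <- function(profile, shares = class_shares(profile)) {
  ap <- acid_percents(profile, c("C12:0", "C14:0", "C16:0"))
  d <- dplyr::left_join(ap, shares, by = "blend")
  if (any(d$ufa <= 0)) {
    rlang::abort("IA undefined: no unsaturated fatty acids",
                 class = "oilblendr_undefined_index")
  }
  tibble::tibble(
    blend = d$blend,
    ia = (d[["C12:0"]] + 4 * d[["C14:0"]] + d[["C16:0"]]) / d$ufa
  )
}

#' Index of thrombogenicity (IT)
#'
#' IT = (C14:0 + C16:0 + C18:0) /
#'   (0.5 x MUFA + 0.5 x omega-6 + 3 x omega-3 + omega-3/omega-6).
#' Pro-thrombogenic saturates over anti-thrombogenic unsaturates, with
#' omega-3 acids weighted most strongly protective.
#'
#' @inheritParams atherogenicity_index
#' @return A tibble with columns `blend`, `it`.
#' @examples
#' oil_blend_profiles() |> thrombogenicity_index()
#' @export
thrombogenicity_index <- function(profile, shares = class_shares(profile)) {
  ap <- acid_percents(profile, c("C14:0", "C16:0", "C18:0"))
  d <- dplyr::left_join(ap, shares, by = "blend")
  den <- 0.5 * d$mufa + 0.5 * d$omega6 + 3 * d$omega3 +
    ifelse(d$omega6 > 0, d$omega3 / d$omega6, 0)
  if (any(den <= 0)) {
    rlang::abort("IT undefined: zero denominator",
                 class = "oilblendr_undefined_index")
  }
  tibble::tibble(
    blend = d$blend,
    it = (d[["C14:0"]] + d[["C16:0"]] + d[["C18:0"]]) / den
  )
}

#' Hypocholesterolemic/hypercholesterolemic (HH) ratio
#'
#' HH = (cis-C18:1 + PUFA) / (C12:0 + C14:0 + C16:0): cholesterol-lowering
#' oleic acid and polyunsaturates over the cholesterol-raising C12-C16
#' saturates. The C18:1 column of a GC profile is taken as cis-oleic.
#'
#' @inheritParams atherogenicity_index
#' @return A tibble with columns `blend`, `hh`.
#' @examples
#' oil_blend_profiles() |> hh_ratio()
#' @export
hh_ratio <- function(profile, shares = class_shares(profile)) {
  ap <- acid_percents(profile, c("C18:1", "C12:0", "C14:0", "C16:0"))
  d <- dplyr::left_join(ap, shares, by = "blend")
  den <- d[["C12:0"]] + d[["C14:0"]] + d[["C16:0"]]
  if (any(den <= 0)) {
    rlang::abort("HH undefined: no C12:0/C14:0/C16:0 saturates",
                 class = "oilblendr_undefined_index")
  }
  tibble::tibble(blend = d$blend, hh = (d[["C18:1"]] + d$pufa) / den)
}

#' Calculated iodine value (CIV)
#'
#' Estimates the iodine value (g I2 per 100 g oil) from composition as a
#' weighted sum of unsaturated-acid percentages:
#' CIV = 0.95 C16:1 + 0.86 C18:1 + 1.732 C18:2 + 2.616 C18:3 +
#' 0.785 C20:1 + 0.723 C22:1. Higher CIV means more double bonds and
#' greater susceptibility to oxidation.
#'
#' @param profile A parsed profile tibble.
#' @return A tibble with columns `blend`, `civ`.
#' @examples
#' oil_blend_profiles() |> calculated_iodine_value()
#' @export
calculated_iodine_value <- function(profile) {
  profile |>
    dplyr::summarise(
      civ = sum(.data$percent *
                  dplyr::coalesce(unname(civ_factors[.data$acid]), 0)),
      .by = "blend"
    )
}

#' All nutritional-quality indices of a profile set
#'
#' Convenience wrapper computing PUFA/SFA, IA, IT, HH, CIV and the
#' omega-6/omega-3 ratio per blend, from mean composition.
#'
#' @param profile A parsed profile tibble (one or more blends).
#' @return A tibble with columns `blend`, `pufa_sfa`, `ia`, `it`, `hh`,
#'   `civ`, `omega_ratio`.
#' @examples
#' oil_blend_profiles() |> nutrition_indices()
#' @export
nutrition_indices <- function(profile) {
  shares <- class_shares(profile)
  list(
    pufa_sfa(shares),
    atherogenicity_index(profile, shares),
    thrombogenicity_index(profile, shares),
    hh_ratio(profile, shares),
    calculated_iodine_value(profile),
    omega_ratio(shares)[c("blend", "omega_ratio")]
  ) |>
    purrr::reduce(dplyr::left_join, by = "blend")
}
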