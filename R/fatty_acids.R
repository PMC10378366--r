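#' Classify a fatty acid into an omega family
#'
#' Assigns each acid to one of `saturated`, `omega3`, `omega6`, `omega9`
#' or `other_unsaturated`. The classification reflects cold-pressed
#' vegetable-oil chemistry: the only polyunsaturates present at measurable
#' levels are linoleic acid (C18:2, omega-6) and alpha-linolenic acid
#' (C18:3, omega-3); all monounsaturates (palmitoleic, oleic, gondoic, ...)
#' are grouped in the omega-9 bucket.
#'
#' @param carbons Integer vector, carbon chain length (>= 4).
#' @param double_bonds Integer vector, number of double bonds (>= 0).
#' @return Character vector of omega classes.
#' @examples
#' fa_omega_class(18, 0:3)
#' @export
fa_omega_class <- function(carbons, double_bonds) {
  dplyr::case_when(
    double_bonds == 0 ~ "saturated",
    carbons == 18 & double_bonds == 2 ~ "omega6",
    carbons == 18 & double_bonds == 3 ~ "omega3",
    double_bonds == 1 ~ "omega9",
    .default = "other_unsaturated"
  )
}

#' Parse fatty-acid shorthand
#'
#' Parses strings of the form `"C18:2"` into chain length and number of
#' double bonds, and classifies each acid via [fa_omega_class()].
#'
#' @param acid Character vector of shorthand names, `"C<carbons>:<bonds>"`.
#' @return A tibble with columns `acid`, `carbons`, `double_bonds`,
#'   `omega_class`.
#' @examples
#' parse_fa_key(c("C16:0", "C18:3"))
#' @export
parse_fa_key <- function(acid) {
  m <- stringr::str_match(acid, "^C(\\d+):(\\d+)$")
  bad <- acid[is.na(m[, 1])]
  if (length(bad) > 0) {
    rlang::abort(
      paste0("Malformed fatty-acid shorthand: ",
             paste(unique(bad), collapse = ", "),
             " (expected \"C<carbons>:<double_bonds>\", e.g. \"C18:2\")"),
      class = "oilblendr_parse_error"
    )
  }
  carbons <- as.integer(m[, 2])
  double_bonds <- as.integer(m[, 3])
  if (any(carbons < 4)) {
    rlang::abort(
      paste0("Implausible chain length (< 4 carbons) in: ",
             paste(unique(acid[carbons < 4]), collapse = ", ")),
      class = "oilblendr_parse_error"
    )
  }
  tibble::tibble(
    acid = acid,
    carbons = carbons,
    double_bonds = double_bonds,
    omega_class = fa_omega_class(carbons, double_bonds)
  )
}

#' Parse and validate fatty-acid composition profiles
#'
#' Ingests tabular records of fatty-acid percentages (one row per blend x
#' acid), parses the acid shorthand, maps `"nd"` (not detected) to 0, and
#' validates that each blend's percentages lie in \[0, 100\] and sum to
#' 100 within tolerance.
#'
#' @param rows A data frame with columns `acid` and `percent`, optionally
#'   `blend` (defaults to a single `"blend"` label) and `sd`. `percent`
#'   (and `sd`) may be numeric or character with `"nd"` entries.
#' @param sum_range Numeric length-2, admissible range for the per-blend
#'   percentage sum. Default `c(98, 102)`.
#' @return A tibble with columns `blend`, `acid`, `carbons`,
#'   `double_bonds`, `omega_class`, `percent`, `sd`.
#' @examples
#' parse_profile(data.frame(acid = "C18:0", percent = 100))
#' @export
parse_profile <- function(rows, sum_range = c(98, 102)) {
  rows <- tibble::as_tibble(rows)
  stopifnot(all(c("acid", "percent") %in% names(rows)))
  if (!"blend" %in% names(rows)) rows$blend <- "blend"
  if (!"sd" %in% names(rows)) rows$sd <- NA_real_
  rows$percent <- nd_to_zero(rows$percent, "percent")
  rows$sd <- nd_to_zero(rows$sd, "sd", allow_na = TRUE)

  key <- parse_fa_key(rows$acid)
  out <- dplyr::bind_cols(
    rows["blend"], key, rows[c("percent", "sd")]
  )

  if (any(out$percent < 0 | out$percent > 100)) {
    bad <- out[out$percent < 0 | out$percent > 100, ]
    rlang::abort(
      paste0("Percentages outside [0, 100] for: ",
             paste(bad$blend, bad$acid, sep = "/", collapse = ", ")),
      class = "oilblendr_validation_error"
    )
  }
  sums <- out |>
    dplyr::summarise(total = sum(.data$percent), .by = "blend")
  off <- sums[sums$total < sum_range[1] | sums$total > sum_range[2], ]
  if (nrow(off) > 0) {
    rlang::abort(
      paste0("Profile percentages must sum to [", sum_range[1], ", ",
             sum_range[2], "]; got ",
             paste0(off$blend, " = ", signif(off$total, 6),
                    collapse = ", ")),
      class = "oilblendr_validation_error"
    )
  }
  out
}

nd_to_zero <- function(x, what, allow_na = FALSE) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- as.character(x)
  x[trimws(tolower(x)) == "nd"] <- "0"
  val <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(val)
  if (any(bad)) {
    rlang::abort(
      paste0("Non-numeric ", what, " values: ",
             paste(unique(x[bad]), collapse = ", ")),
      class = "oilblendr_parse_error"
    )
  }
  if (!allow_na) val[is.na(val)] <- 0
  val
}

#' Fatty-acid class shares of a profile
#'
#' Partitions each blend's composition into saturated (SFA),
#' monounsaturated (MUFA, exactly one double bond) and polyunsaturated
#' (PUFA, two or more double bonds) shares, with the omega-3 and omega-6
#' subtotals and total unsaturates (UFA = MUFA + PUFA).
#'
#' @param profile A parsed profile tibble from [parse_profile()].
#' @return A tibble with one row per blend and columns `blend`, `sfa`,
#'   `mufa`, `pufa`, `omega3`, `omega6`, `ufa`, `total`.
#' @examples
#' oil_blend_profiles() |> class_shares()
#' @export
class_shares <- function(profile) {
  profile |>
    dplyr::summarise(
      sfa = sum(.data$percent[.data$double_bonds == 0]),
      mufa = sum(.data$percent[.data$double_bonds == 1]),
      pufa = sum(.data$percent[.data$double_bonds >= 2]),
      omega3 = sum(.data$percent[.data$omega_class == "omega3"]),
      omega6 = sum(.data$percent[.data$omega_class == "omega6"]),
      total = sum(.data$percent),
      .by = "blend"
    ) |>
    dplyr::mutate(ufa = .data$mufa + .data$pufa, .after = "omega6")
}

#' Omega-6/omega-3 ratio
#'
#' @param shares A class-shares tibble from [class_shares()].
#' @return The input with an `omega_ratio` column appended
#'   (omega-6 percent / omega-3 percent).
#' @examples
#' oil_blend_profiles() |> class_shares() |> omega_ratio()
#' @export
omega_ratio <- function(shares) {
  if (any(shares$omega3 <= 0)) {
    rlang::abort(
      paste0("omega-6/omega-3 ratio undefined (omega3 = 0) for: ",
             paste(shares$blend[shares$omega3 <= 0], collapse = ", ")),
      class = "oilblendr_undefined_ratio"
    )
  }
  dplyr::mutate(shares, omega_ratio = .data$omega6 / .data$omega3)
}

#' Mix fatty-acid profiles by mass fraction
#'
#' Computes the composition of a physical mixture of component oils: each
#' acid's percentage is the mass-fraction-weighted mean of the component
#' percentages (union of acids, absentees contributing 0).
#'
#' @param components A list of single-blend profile tibbles
#'   (from [parse_profile()]).
#' @param weights Numeric mass fractions, same length as `components`,
#'   summing to 1 within 1e-9.
#' @param label Blend label for the mixture. Default `"mix"`.
#' @return A single-blend profile tibble for the mixture.
#' @examples
#' p <- oil_blend_profiles()
#' a <- dplyr::filter(p, blend == "RBc")
#' b <- dplyr::filter(p, blend == "BcH")
#' mix_profiles(list(a, b), c(0.5, 0.5))
#' @export
mix_profiles <- function(components, weights, label = "mix") {
  stopifnot(length(components) == length(weights), length(components) >= 1)
  if (abs(sum(weights) - 1) > 1e-9) {
    rlang::abort(
      paste0("Mass fractions must sum to 1; got ", sum(weights)),
      class = "oilblendr_validation_error"
    )
  }
  long <- purrr::map2(components, weights, \(p, w) {
    tibble::tibble(acid = p$acid, part = p$percent * w)
  }) |>
    purrr::list_rbind() |>
    dplyr::summarise(percent = sum(.data$part), .by = "acid")
  parse_profile(
    tibble::tibble(blend = label, acid = long$acid, percent = long$percent)
  )
}

#' Solve a binary blend for a target omega-6/omega-3 ratio
#'
#' Finds the mass fraction `w` of component `a` such that the mixture
#' `w * a + (1 - w) * b` has omega-6/omega-3 ratio exactly equal to
#' `target_ratio`. The ratio constraint is linear in `w`, so the solution
#' is closed-form.
#'
#' @param a,b Single-blend profile tibbles (from [parse_profile()]).
#' @param target_ratio Dimensionless target omega-6/omega-3 ratio.
#' @return Mass fraction of `a` in `[0, 1]`.
#' @examples
#' p <- oil_blend_profiles()
#' formulate_binary_blend(
#'   dplyr::filter(p, blend == "RBc"),
#'   dplyr::filter(p, blend == "RMt"),
#'   target_ratio = 5
#' )
#' @export
formulate_binary_blend <- function(a, b, target_ratio) {
  sa <- class_shares(a)
  sb <- class_shares(b)
  # (o6a w + o6b (1-w)) = target * (o3a w + o3b (1-w)), linear in w
  num <- target_ratio * sb$omega3 - sb$omega6
  den <- (sa$omega6 - sb$omega6) - target_ratio * (sa$omega3 - sb$omega3)
  ra <- sa$omega6 / sa$omega3
  rb <- sb$omega6 / sb$omega3
  infeasible <- function() {
    rlang::abort(
      paste0("Target ratio ", target_ratio,
             " is not attainable; component ratios span [",
             signif(min(ra, rb), 6), ", ", signif(max(ra, rb), 6), "]"),
      class = "oilblendr_infeasible"
    )
  }
  if (abs(den) < 1e-12) {
    if (abs(ra - target_ratio) < 1e-9) return(1)
    infeasible()
  }
  w <- num / den
  if (w < -1e-9 || w > 1 + 1e-9) infeasible()
  min(max(w, 0), 1)
}
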