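extdata <- function(file) {
  path <- system.file("extdata", file, package = "oilblendr")
  if (path == "") {
    rlang::abort(paste0("Bundled file not found: ", file),
                 class = "oilblendr_io_error")
  }
  path
}

#' Bundled reference tables
#'
#' Accessors for the small reference tables shipped with the package:
#' mean fatty-acid compositions (% of total, per-acid SDs, `nd` = 0),
#' published nutritional indices and calculated iodine values, total
#' polar compounds per blend and heating condition, relaxometry/DSC
#' summaries, and the blend recipes. All are transcribed replicate
#' summaries (means, SD, n = 4) for the eight cold-pressed oil blends;
#' see `inst/extdata/README.md`.
#'
#' @return A tibble; `oil_blend_profiles()` returns a parsed, validated
#'   profile tibble (see [parse_profile()]).
#' @examples
#' oil_blend_profiles()
#' @export
oil_blend_profiles <- function() {
  read_profile_csv(extdata("blend_fatty_acid_profiles.csv"))
}

#' @rdname oil_blend_profiles
#' @export
oil_blend_reference_indices <- function() {
  readr::read_csv(extdata("blend_reference_indices.csv"),
                  show_col_types = FALSE)
}

#' @rdname oil_blend_profiles
#' @export
oil_blend_heating <- function() {
  read_heating_csv(extdata("blend_heating_tpc.csv"))
}

#' @rdname oil_blend_profiles
#' @export
oil_blend_relaxometry <- function() {
  readr::read_csv(extdata("blend_relaxometry_dsc.csv"),
                  show_col_types = FALSE)
}

#' @rdname oil_blend_profiles
#' @export
oil_blend_recipes <- function() {
  readr::read_csv(extdata("blend_recipes.csv"), show_col_types = FALSE)
}

#' Read and write fatty-acid profile CSVs
#'
#' The profile dialect has columns `blend,acid,percent,sd`, acids in
#' `"C18:2"` shorthand, UTF-8, header required; `percent`/`sd` entries
#' may be `"nd"` (not detected, read as 0).
#'
#' @param path File path.
#' @param sum_range Passed to [parse_profile()].
#' @return `read_profile_csv()` a parsed profile tibble;
#'   `write_profile_csv()` the path, invisibly.
#' @export
read_profile_csv <- function(path, sum_range = c(98, 102)) {
  readr::read_csv(path, col_types = readr::cols(.default = "c")) |>
    parse_profile(sum_range = sum_range)
}

#' @rdname read_profile_csv
#' @param profile A parsed profile tibble.
#' @export
write_profile_csv <- function(profile, path) {
  readr::write_csv(profile[c("blend", "acid", "percent", "sd")], path)
  invisible(path)
}

#' Read and write relaxation-curve CSVs
#'
#' One curve per file, columns `time_ms,signal`; the pulse-sequence kind
#' travels as an argument (or a JSON sidecar in larger workflows).
#'
#' @param path File path.
#' @param kind `"inversion_recovery"` or `"cpmg"`.
#' @return `read_curve_csv()` a [relaxation_curve()];
#'   `write_curve_csv()` the path, invisibly.
#' @export
read_curve_csv <- function(path, kind = c("inversion_recovery", "cpmg")) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  relaxation_curve(d$time_ms, d$signal, kind = match.arg(kind))
}

#' @rdname read_curve_csv
#' @param curve A [relaxation_curve()].
#' @export
write_curve_csv <- function(curve, path) {
  readr::write_csv(tibble::as_tibble(curve), path)
  invisible(path)
}

#' Read and write DSC trace CSVs
#'
#' Columns `time_min,heat_flow`, one isothermal trace per file.
#'
#' @param path File path.
#' @param temperature Isothermal set point (degrees C). Default 130.
#' @return `read_trace_csv()` a [dsc_trace()]; `write_trace_csv()` the
#'   path, invisibly.
#' @export
read_trace_csv <- function(path, temperature = 130) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  dsc_trace(d$time_min, d$heat_flow, temperature = temperature)
}

#' @rdname read_trace_csv
#' @param trace A [dsc_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  readr::write_csv(tibble::as_tibble(trace), path)
  invisible(path)
}

#' Read and write heating-summary CSVs
#'
#' Columns `blend,condition,measure,mean,sd,n`, with `condition` in
#' `{unheated, 170C, 200C}` and `measure` in `{tpc, dimer, trimer}`.
#'
#' @param path File path.
#' @return `read_heating_csv()` a tibble; `write_heating_csv()` the path,
#'   invisibly.
#' @export
read_heating_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("blend", "condition", "measure", "mean", "sd", "n")
                %in% names(d)))
  d
}

#' @rdname read_heating_csv
#' @param records A heating-summary tibble.
#' @export
write_heating_csv <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' Run the full analysis report
#'
#' Orchestrates every analysis stage on a profile set, a heating summary
#' and a relaxometry/DSC summary, writing one CSV per stage plus a JSON
#' summary: class shares with CIV and omega ratios; nutritional indices;
#' TPC with Tukey compact letters (per condition, across blends) and the
#' regulatory compliance check; T1/T2 with the BPP-inverted mean
#' correlation time. CSVs are rounded for display; the JSON carries full
#' precision.
#'
#' @param out_dir Output directory (created if missing).
#' @param profiles Parsed profile tibble. Default [oil_blend_profiles()].
#' @param heating Heating summary tibble. Default [oil_blend_heating()].
#' @param relaxometry Relaxometry summary with `blend`, `t1_ms`, `t2_ms`
#'   (optionally `oit_min`). Default [oil_blend_relaxometry()].
#' @param alpha Significance level for the Tukey letters. Default 0.05.
#' @param tpc_limit Regulatory TPC limit (%). Default 24.
#' @param larmor_hz Spectrometer frequency (Hz). Default 15e6.
#' @param digits Display rounding for CSVs. Default 2.
#' @return Invisibly, a list of the report tibbles and file paths.
#' @export
run_full_report <- function(out_dir,
                            profiles = oil_blend_profiles(),
                            heating = oil_blend_heating(),
                            relaxometry = oil_blend_relaxometry(),
                            alpha = 0.05, tpc_limit = 24,
                            larmor_hz = 15e6, digits = 2) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  shares <- class_shares(profiles) |> omega_ratio()
  civ <- calculated_iodine_value(profiles)
  shares_civ <- dplyr::left_join(shares, civ, by = "blend")
  indices <- nutrition_indices(profiles)

  tpc <- heating |>
    dplyr::filter(.data$measure == "tpc")
  cld <- tpc |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(\(d, key) {
      tukey_cld(dplyr::rename(d, label = "blend"), alpha = alpha) |>
        dplyr::rename(blend = "label")
    }) |>
    dplyr::ungroup()
  tpc_report <- tpc |>
    dplyr::left_join(cld[c("blend", "condition", "letters")],
                     by = c("blend", "condition")) |>
    dplyr::rename(tpc = "mean") |>
    compliance_check(limit = tpc_limit, tpc = "tpc")

  tc <- invert_tau_c(relaxometry$t1_ms, relaxometry$t2_ms,
                     larmor_hz = larmor_hz)
  relax_report <- relaxometry |>
    dplyr::bind_cols(
      t1_t2_ratio = tc$ratio, tau_c_bpp_s = tc$tau_c_s
    )

  round_df <- function(d) {
    dplyr::mutate(d, dplyr::across(
      dplyr::where(\(x) is.numeric(x) && !all(x == round(x), na.rm = TRUE)),
      \(x) round(x, digits)
    ))
  }
  paths <- list(
    class_shares = file.path(out_dir, "class_shares_civ.csv"),
    indices = file.path(out_dir, "nutrition_indices.csv"),
    tpc = file.path(out_dir, "tpc_report.csv"),
    relaxometry = file.path(out_dir, "relaxometry_report.csv"),
    summary = file.path(out_dir, "summary.json")
  )
  readr::write_csv(round_df(shares_civ), paths$class_shares)
  readr::write_csv(round_df(indices), paths$indices)
  readr::write_csv(round_df(tpc_report), paths$tpc)
  readr::write_csv(
    dplyr::mutate(relax_report,
                  dplyr::across(dplyr::where(is.numeric) &
                                  !dplyr::any_of(c("tau_c_s", "tau_c_bpp_s")),
                                \(x) round(x, digits))),
    paths$relaxometry
  )
  jsonlite::write_json(
    list(
      class_shares = shares_civ, indices = indices,
      tpc = tpc_report, relaxometry = relax_report,
      parameters = list(alpha = alpha, tpc_limit = tpc_limit,
                        larmor_hz = larmor_hz)
    ),
    paths$summary, auto_unbox = TRUE, digits = NA
  )
  invisible(list(
    class_shares = shares_civ, indices = indices, tpc = tpc_report,
    relaxometry = relax_report, paths = paths
  ))
}
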