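#' Configuration for the synthetic-data generators
#'
#' Bundles the seed, replication and noise scales used by
#' [generate_profiles()], [generate_heating_table()] and
#' [generate_nmr_dataset()]. Defaults emulate the study design the
#' bundled reference tables come from: duplicate determinations in two
#' independent experiments (n = 4), per-acid SDs at the printed scale,
#' heating-table SDs of about 0.15% absolute, NMR noise of about 1% of
#' the equilibrium magnetization, and TPC increments that reproduce the
#' observed unheated < 170C < 200C ordering.
#'
#' @param seed Integer seed; every generator is a pure function of
#'   (config, anchors).
#' @param n_replicates Replicates per blend/condition (>= 2). Default 4.
#' @param profile_noise_scale Multiplier on the per-acid anchor SDs.
#'   Default 1; 0 gives noiseless replicates.
#' @param nmr_noise_sd NMR signal noise SD (a.u., amplitude 100).
#'   Default 1.
#' @param dsc_noise_sd DSC heat-flow noise SD (a.u., amplitude 10).
#'   Default 0.1.
#' @param heating_noise_sd Replicate SD for TPC/dimer/trimer draws (%).
#'   Default 0.15.
#' @param tpc_increment_170,tpc_increment_200 Mean TPC gain (%) over the
#'   unheated level at each temperature. Defaults 3.7 and 8.4.
#' @param dimer_mean_170,dimer_mean_200 Mean TAG dimer content (%) at each
#'   temperature. Defaults 1.4 and 4.5.
#' @param trimer_blends Blends forming TAG trimers at 200C. Default
#'   `c("HRbR", "RBc", "RMt")`.
#' @param trimer_mean Mean trimer content (%) in those blends. Default
#'   0.47.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed,
                             n_replicates = 4,
                             profile_noise_scale = 1,
                             nmr_noise_sd = 1,
                             dsc_noise_sd = 0.1,
                             heating_noise_sd = 0.15,
                             tpc_increment_170 = 3.7,
                             tpc_increment_200 = 8.4,
                             dimer_mean_170 = 1.4,
                             dimer_mean_200 = 4.5,
                             trimer_blends = c("HRbR", "RBc", "RMt"),
                             trimer_mean = 0.47) {
  stopifnot(is.numeric(seed), length(seed) == 1, n_replicates >= 2,
            profile_noise_scale >= 0, nmr_noise_sd >= 0, dsc_noise_sd >= 0,
            heating_noise_sd >= 0, tpc_increment_170 > 0,
            tpc_increment_200 > 0, dimer_mean_170 > 0, dimer_mean_200 > 0)
  structure(
    list(
      seed = as.integer(seed), n_replicates = as.integer(n_replicates),
      profile_noise_scale = profile_noise_scale,
      nmr_noise_sd = nmr_noise_sd, dsc_noise_sd = dsc_noise_sd,
      heating_noise_sd = heating_noise_sd,
      tpc_increment_170 = tpc_increment_170,
      tpc_increment_200 = tpc_increment_200,
      dimer_mean_170 = dimer_mean_170, dimer_mean_200 = dimer_mean_200,
      trimer_blends = trimer_blends, trimer_mean = trimer_mean
    ),
    class = "synthetic_config"
  )
}

#' Generate replicate fatty-acid profiles
#'
#' Draws `n_replicates` profiles per blend as Gaussian perturbations of
#' the anchor means with the anchors' per-acid SDs (scaled by
#' `profile_noise_scale`), truncates negatives at 0 and renormalises each
#' replicate to sum exactly 100.
#'
#' @param config A [synthetic_config()].
#' @param anchors Anchor mean profiles with `sd` column; defaults to the
#'   bundled eight-blend reference set, [oil_blend_profiles()].
#' @return A tibble with columns `blend`, `replicate`, `acid`, `percent`.
#' @examples
#' generate_profiles(synthetic_config(seed = 1))
#' @export
generate_profiles <- function(config, anchors = oil_blend_profiles()) {
  stopifnot(inherits(config, "synthetic_config"))
  sums <- anchors |>
    dplyr::summarise(total = sum(.data$percent), .by = "blend")
  if (any(sums$total < 98 | sums$total > 102)) {
    rlang::abort("Anchor profiles must sum to 100 within tolerance",
                 class = "oilblendr_validation_error")
  }
  sd_vec <- dplyr::coalesce(anchors$sd, 0) * config$profile_noise_scale
  withr::with_seed(config$seed, {
    purrr::map(seq_len(config$n_replicates), \(r) {
      pct <- pmax(0, stats::rnorm(nrow(anchors), anchors$percent, sd_vec))
      tibble::tibble(
        blend = anchors$blend, replicate = r,
        acid = anchors$acid, percent = pct
      ) |>
        dplyr::mutate(
          percent = .data$percent / sum(.data$percent) * 100,
          .by = "blend"
        )
    }) |>
      purrr::list_rbind()
  }) |>
    dplyr::arrange(match(.data$blend, unique(anchors$blend)),
                   .data$replicate)
}

#' Generate a synthetic heating/degradation table
#'
#' Emulates a pan-heating experiment: per blend and replicate, total
#' polar compounds rise monotonically (in expectation) from the unheated
#' level through 170C to 200C; TAG dimers are absent unheated and larger
#' at 200C than at 170C; trimers appear only at 200C and only in the
#' configured subset of blends.
#'
#' @param config A [synthetic_config()].
#' @param base_tpc Named numeric vector of unheated TPC means per blend;
#'   defaults to the bundled reference table's unheated column.
#' @return A tibble with columns `blend`, `condition`, `replicate`,
#'   `tpc`, `dimer`, `trimer`.
#' @examples
#' generate_heating_table(synthetic_config(seed = 1))
#' @export
generate_heating_table <- function(config, base_tpc = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(base_tpc)) {
    ref <- oil_blend_heating()
    un <- ref[ref$condition == "unheated" & ref$measure == "tpc", ]
    base_tpc <- stats::setNames(un$mean, un$blend)
  }
  blends <- names(base_tpc)
  grid <- tidyr::expand_grid(
    blend = blends,
    condition = c("unheated", "170C", "200C"),
    replicate = seq_len(config$n_replicates)
  )
  inc <- c(unheated = 0, "170C" = config$tpc_increment_170,
           "200C" = config$tpc_increment_200)
  dim_mu <- c(unheated = 0, "170C" = config$dimer_mean_170,
              "200C" = config$dimer_mean_200)
  withr::with_seed(config$seed + 1L, {
    grid |>
      dplyr::mutate(
        tpc = pmax(0, stats::rnorm(
          dplyr::n(),
          base_tpc[.data$blend] + inc[.data$condition],
          config$heating_noise_sd
        )),
        dimer = ifelse(
          .data$condition == "unheated", 0,
          pmax(0.05, stats::rnorm(dplyr::n(), dim_mu[.data$condition],
                                  config$heating_noise_sd))
        ),
        trimer = ifelse(
          .data$condition == "200C" & .data$blend %in% config$trimer_blends,
          pmax(0.05, stats::rnorm(dplyr::n(), config$trimer_mean,
                                  config$heating_noise_sd / 3)),
          0
        )
      )
  })
}

#' Summarise replicate heating records
#'
#' @param records Replicate records from [generate_heating_table()].
#' @return A tibble with columns `blend`, `condition`, `measure`, `mean`,
#'   `sd`, `n` (the long summary dialect used by [oil_blend_heating()]).
#' @export
summarize_heating <- function(records) {
  records |>
    tidyr::pivot_longer(c("tpc", "dimer", "trimer"),
                        names_to = "measure", values_to = "value") |>
    dplyr::summarise(
      mean = mean(.data$value), sd = stats::sd(.data$value),
      n = dplyr::n(),
      .by = c("blend", "condition", "measure")
    )
}

#' Generate a synthetic LF NMR dataset
#'
#' For each (T1, T2) pair, simulates an inversion-recovery curve on the
#' 0.2-90 ms delay grid and a CPMG echo train (100 echoes, 2 ms spacing)
#' with seeded Gaussian noise — the acquisition layout of a benchtop
#' 15 MHz relaxometer.
#'
#' @param config A [synthetic_config()].
#' @param true_params A data frame with columns `blend`, `t1_ms`, `t2_ms`
#'   (`t1_ms >= t2_ms > 0`); defaults to the bundled reference table,
#'   [oil_blend_relaxometry()].
#' @param amplitude Equilibrium magnetization (a.u.). Default 100.
#' @return A tibble with columns `blend`, `kind` and a `curve` list
#'   column of [relaxation_curve()] objects.
#' @examples
#' generate_nmr_dataset(synthetic_config(seed = 1))
#' @export
generate_nmr_dataset <- function(config,
                                 true_params = oil_blend_relaxometry(),
                                 amplitude = 100) {
  stopifnot(inherits(config, "synthetic_config"),
            all(c("blend", "t1_ms", "t2_ms") %in% names(true_params)))
  if (any(true_params$t2_ms <= 0) ||
      any(true_params$t1_ms < true_params$t2_ms)) {
    rlang::abort("Unphysical parameters: need T1 >= T2 > 0",
                 class = "oilblendr_parameter_error")
  }
  k <- nrow(true_params)
  seeds <- config$seed + 1000L + seq_len(2 * k)
  rows <- purrr::map(seq_len(k), \(i) {
    tibble::tibble(
      blend = rep(true_params$blend[i], 2),
      kind = c("inversion_recovery", "cpmg"),
      curve = list(
        simulate_inversion_recovery(
          true_params$t1_ms[i], amplitude = amplitude,
          noise_sd = config$nmr_noise_sd,
          seed = if (config$nmr_noise_sd > 0) seeds[2 * i - 1] else NULL
        ),
        simulate_cpmg(
          true_params$t2_ms[i], amplitude = amplitude,
          noise_sd = config$nmr_noise_sd,
          seed = if (config$nmr_noise_sd > 0) seeds[2 * i] else NULL
        )
      )
    )
  })
  purrr::list_rbind(rows)
}
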