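#' Construct an isothermal DSC trace
#'
#' @param times Minutes, strictly increasing, length >= 50; t = 0 at the
#'   switch to oxygen.
#' @param heat_flow Signal (a.u.), oxidation exotherm positive.
#' @param temperature Isothermal set point in degrees C. Default 130.
#' @return A tibble of class `dsc_trace` with columns `time_min`,
#'   `heat_flow` and a `temperature` attribute.
#' @export
dsc_trace <- function(times, heat_flow, temperature = 130) {
  if (length(times) < 50) {
    rlang::abort("A DSC trace needs at least 50 points",
                 class = "oilblendr_validation_error")
  }
  if (length(heat_flow) != length(times)) {
    rlang::abort("times and heat_flow must have equal length",
                 class = "oilblendr_validation_error")
  }
  if (any(diff(times) <= 0)) {
    rlang::abort("times must be strictly increasing",
                 class = "oilblendr_validation_error")
  }
  out <- tibble::tibble(time_min = as.numeric(times),
                        heat_flow = as.numeric(heat_flow))
  attr(out, "temperature") <- temperature
  class(out) <- c("dsc_trace", class(out))
  out
}

#' Simulate an isothermal DSC oxidation trace
#'
#' Produces a flat zero baseline followed by an oxidation exotherm whose
#' baseline-tangent intersection is analytically equal to `true_oit`,
#' plus optional seeded Gaussian noise.
#'
#' Shapes: `"linear"` ramps at `onset_sharpness` a.u./min starting exactly
#' at `true_oit`; `"sigmoid"` is a logistic of rate `onset_sharpness`
#' (1/min) positioned so the tangent at its inflection point crosses the
#' baseline at `true_oit` (midpoint at `true_oit + 2/onset_sharpness`).
#'
#' @param true_oit Analytic oxidation induction time (min), < `duration`.
#' @param onset_sharpness Exotherm steepness. Slope (a.u./min) for
#'   `"linear"`; logistic rate (1/min) for `"sigmoid"`. Default 1.
#' @param amplitude Exotherm plateau height (a.u.), sigmoid only.
#'   Default 10.
#' @param duration Trace length (min). Default 90.
#' @param sampling Sampling density (points/min). Default 10.
#' @param noise_sd Gaussian noise SD (a.u.). Default 0.
#' @param seed Integer seed, required when `noise_sd > 0`.
#' @param shape `"sigmoid"` (default) or `"linear"`.
#' @param temperature Isothermal set point (degrees C). Default 130.
#' @return A [dsc_trace()].
#' @examples
#' simulate_dsc_trace(40)
#' @export
simulate_dsc_trace <- function(true_oit, onset_sharpness = 1, amplitude = 10,
                               duration = 90, sampling = 10, noise_sd = 0,
                               seed = NULL, shape = c("sigmoid", "linear"),
                               temperature = 130) {
  shape <- match.arg(shape)
  if (true_oit >= duration) {
    rlang::abort("true_oit must be smaller than duration",
                 class = "oilblendr_parameter_error")
  }
  if (onset_sharpness <= 0) {
    rlang::abort("onset_sharpness must be > 0",
                 class = "oilblendr_parameter_error")
  }
  t <- seq(0, duration, by = 1 / sampling)
  hf <- if (shape == "linear") {
    pmax(0, t - true_oit) * onset_sharpness
  } else {
    # inflection at tm; tangent there has slope A k / 4 and value A / 2,
    # so it meets the zero baseline at tm - 2/k = true_oit
    tm <- true_oit + 2 / onset_sharpness
    amplitude / (1 + exp(-onset_sharpness * (t - tm)))
  }
  dsc_trace(t, add_noise(hf, noise_sd, seed), temperature = temperature)
}

#' Detect the oxidation induction time by the tangent method
#'
#' Locates the onset of the oxidation exotherm in an isothermal DSC trace
#' the way instrument software does: estimate the pre-oxidation baseline
#' level, anchor a tangent at the point of maximum (smoothed) slope on the
#' rising flank of the exotherm, and report the time where that tangent
#' crosses the baseline level.
#'
#' The baseline window is the first `baseline_frac` of the trace, or all
#' points before the first sustained `noise_mult`-sigma excursion,
#' whichever is shorter; the level is the window median. Local slopes come
#' from centered moving-window linear fits (window `slope_window_frac` of
#' the trace, at least 5 points).
#'
#' @param trace A [dsc_trace()].
#' @param invert Set `TRUE` if the input uses the exotherm-negative
#'   convention. Default `FALSE`.
#' @param baseline_frac Fraction of the trace used for the baseline
#'   window. Default 0.2.
#' @param noise_mult Multiple of baseline noise a sustained excursion (and
#'   the exotherm maximum) must exceed. Default 5.
#' @param slope_window_frac Moving-window width for slope estimation, as a
#'   fraction of trace length. Default 0.02.
#' @return An object of class `oit_result`: list with `oit` (min),
#'   `baseline_level`, `tangent_point` (time, heat_flow), `tangent_slope`
#'   and the trace. Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @examples
#' simulate_dsc_trace(40) |> detect_oit()
#' @export
detect_oit <- function(trace, invert = FALSE, baseline_frac = 0.2,
                       noise_mult = 5, slope_window_frac = 0.02) {
  t <- trace$time_min
  y <- if (invert) -trace$heat_flow else trace$heat_flow
  n <- length(y)
  span <- max(diff(range(y)), 1)

  i_base <- max(5L, floor(baseline_frac * n))
  level0 <- stats::median(y[1:i_base])
  sigma0 <- stats::sd(y[1:i_base])
  eps <- 1e-9 * span
  thr <- level0 + noise_mult * max(sigma0, eps)
  above <- y > thr
  # first index opening a run of >= 5 consecutive points above threshold
  run <- stats::filter(as.numeric(above), rep(1, 5), sides = 1)
  first_exc <- which(run == 5)[1] - 4L
  if (!is.na(first_exc) && first_exc <= 10L) {
    rlang::abort(
      "Exotherm onset falls inside the baseline window; shorten baseline_frac or record a longer pre-oxidation segment",
      class = "oilblendr_window_error"
    )
  }
  if (!is.na(first_exc) && first_exc - 1L < i_base) {
    i_base <- first_exc - 1L
    level0 <- stats::median(y[1:i_base])
    sigma0 <- stats::sd(y[1:i_base])
  }
  if (max(y) - level0 <= noise_mult * max(sigma0, eps)) {
    rlang::abort("No oxidation exotherm detected above the baseline noise",
                 class = "oilblendr_no_onset")
  }

  w <- max(5L, round(slope_window_frac * n))
  if (w %% 2 == 0) w <- w + 1L
  half <- (w - 1L) %/% 2L
  idx <- (half + 1L):(n - half)
  # centered moving-window linear fit: slope and fitted value at the center
  slope <- vapply(idx, function(i) {
    ii <- (i - half):(i + half)
    stats::cov(t[ii], y[ii]) / stats::var(t[ii])
  }, numeric(1))
  center_val <- vapply(idx, function(i) mean(y[(i - half):(i + half)]),
                       numeric(1))
  smooth_y <- center_val
  # rising flank only: at or before the smoothed maximum
  i_max <- which.max(smooth_y)
  cand <- which(idx <= idx[i_max])
  i_pk <- cand[which.max(slope[cand])]
  slope_pk <- slope[i_pk]
  t_pk <- t[idx[i_pk]]
  y_pk <- center_val[i_pk]
  if (!is.finite(slope_pk) || slope_pk <= 0) {
    rlang::abort("No rising exotherm flank found",
                 class = "oilblendr_no_onset")
  }
  # a clean pre-oxidation baseline is flat; a substantial trend there
  # means the exotherm started before the baseline window closed
  tw <- t[1:i_base]; yw <- y[1:i_base]
  slope_base <- stats::cov(tw, yw) / stats::var(tw)
  if (slope_base > 0.1 * slope_pk) {
    rlang::abort(
      "Exotherm onset falls inside the baseline window; shorten baseline_frac or record a longer pre-oxidation segment",
      class = "oilblendr_window_error"
    )
  }
  oit <- t_pk - (y_pk - level0) / slope_pk
  structure(
    list(
      oit = oit,
      baseline_level = level0,
      tangent_point = c(time = t_pk, heat_flow = y_pk),
      tangent_slope = slope_pk,
      temperature = attr(trace, "temperature"),
      trace = trace
    ),
    class = "oit_result"
  )
}

#' @export
print.oit_result <- function(x, ...) {
  cat("Isothermal DSC oxidation induction time (tangent method)\n",
      "  OIT = ", sprintf("%.2f", x$oit), " min",
      "  (tangent slope ", signif(x$tangent_slope, 4),
      " a.u./min at t = ", sprintf("%.2f", x$tangent_point[["time"]]),
      " min)\n", sep = "")
  invisible(x)
}

#' @method tidy oit_result
#' @export
tidy.oit_result <- function(x, ...) {
  tibble::tibble(
    term = c("oit", "baseline_level", "tangent_slope", "tangent_time"),
    estimate = c(x$oit, x$baseline_level, x$tangent_slope,
                 x$tangent_point[["time"]])
  )
}

#' @method glance oit_result
#' @export
glance.oit_result <- function(x, ...) {
  tibble::tibble(
    oit = x$oit,
    baseline_level = x$baseline_level,
    tangent_slope = x$tangent_slope,
    temperature = x$temperature %||% NA_real_,
    n = nrow(x$trace)
  )
}
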