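#' Fold change between paired degradation measurements
#'
#' @param before,after Numeric vectors of equal length, e.g. total polar
#'   compounds before and after heating. `before` must be positive: a
#'   zero baseline (typical for TAG polymers absent from fresh oil) has no
#'   fold change and is reported as formation instead.
#' @return Numeric vector `after / before`.
#' @examples
#' fold_change(1.84, 7.96)
#' @export
fold_change <- function(before, after) {
  stopifnot(length(before) == length(after))
  if (any(before <= 0)) {
    rlang::abort(
      "Fold change undefined for a zero baseline: the species formed on heating; report its absolute level instead",
      class = "oilblendr_zero_baseline"
    )
  }
  after / before
}

#' Check records against a regulatory TPC limit
#'
#' Frying-oil regulations discard oil above a total-polar-compounds
#' threshold, commonly 24-25%. A record passes iff its TPC is strictly
#' below the limit.
#'
#' @param records A data frame with a `tpc` column (percent), e.g. from
#'   [oil_blend_heating()] reshaped, or any tibble of measurements.
#' @param limit Limit in percent, > 0. Default 24.
#' @param tpc Name of the TPC column. Default `"tpc"`.
#' @return The input tibble with `pass` (logical) and `margin`
#'   (`limit - tpc`) columns appended.
#' @examples
#' compliance_check(data.frame(tpc = c(14.98, 30)))
#' @export
compliance_check <- function(records, limit = 24, tpc = "tpc") {
  stopifnot(limit > 0, tpc %in% names(records))
  records |>
    tibble::as_tibble() |>
    dplyr::mutate(
      pass = .data[[tpc]] < limit,
      margin = limit - .data[[tpc]]
    )
}

#' Tukey HSD compact letter display from group summaries
#'
#' One-way ANOVA reconstructed from per-group summary statistics (mean,
#' SD, n), followed by Tukey's honestly-significant-difference test on all
#' pairs via the studentized-range distribution, rendered as a compact
#' letter display: groups sharing a letter are not significantly
#' different at level `alpha`.
#'
#' The pooled within-group variance is
#' `sum((n_i - 1) s_i^2) / sum(n_i - 1)`, and each pair is compared with
#' `q = |m_i - m_j| / sqrt(MSw/2 (1/n_i + 1/n_j))` against the
#' studentized range with `k` means and `sum(n_i - 1)` degrees of
#' freedom. Letters are assigned by the insert-and-absorb algorithm in
#' order of increasing mean.
#'
#' @param groups A data frame with columns `label`, `mean`, `sd`, `n`.
#' @param alpha Significance level in (0, 1). Default 0.05.
#' @return A tibble with columns `label`, `mean`, `letters`, in the input
#'   row order.
#' @examples
#' tukey_cld(data.frame(label = c("a", "b", "c"),
#'                      mean = c(0, 10, 20), sd = 0.5, n = 4))
#' @export
tukey_cld <- function(groups, alpha = 0.05) {
  groups <- tibble::as_tibble(groups)
  stopifnot(all(c("label", "mean", "sd", "n") %in% names(groups)),
            alpha > 0, alpha < 1)
  k <- nrow(groups)
  if (k < 2) {
    rlang::abort("Need at least 2 groups",
                 class = "oilblendr_validation_error")
  }
  df_w <- sum(groups$n - 1)
  if (df_w < 1 || all(groups$n < 2)) {
    rlang::abort("Insufficient replication: need n >= 2 in some group",
                 class = "oilblendr_insufficient_replication"
    )
  }
  ms_w <- sum((groups$n - 1) * groups$sd^2) / df_w
  sig <- tukey_significant_pairs(groups$mean, groups$n, ms_w, df_w, alpha)

  ord <- order(groups$mean)
  # significant pairs in mean-rank coordinates
  rank_of <- match(seq_len(k), ord)
  sig_ranked <- unique(lapply(sig, function(p) sort(rank_of[p])))
  letters_ranked <- cld_insert_absorb(k, sig_ranked)
  out_letters <- character(k)
  out_letters[ord] <- letters_ranked
  tibble::tibble(label = groups$label, mean = groups$mean,
                 letters = out_letters)
}

# all significant pairs (list of index pairs) under Tukey HSD
tukey_significant_pairs <- function(means, n, ms_w, df_w, alpha) {
  k <- length(means)
  pairs <- utils::combn(k, 2, simplify = FALSE)
  Filter(function(p) {
    i <- p[1]; j <- p[2]
    se <- sqrt(ms_w / 2 * (1 / n[i] + 1 / n[j]))
    if (se == 0) return(means[i] != means[j])
    q <- abs(means[i] - means[j]) / se
    stats::ptukey(q, nmeans = k, df = df_w, lower.tail = FALSE) < alpha
  }, pairs)
}

# insert-and-absorb compact letter display; groups assumed ordered by mean,
# sig_pairs given in that ordering
cld_insert_absorb <- function(k, sig_pairs) {
  cols <- list(rep(TRUE, k))
  for (p in sig_pairs) {
    i <- p[1]; j <- p[2]
    new_cols <- list()
    for (col in cols) {
      if (col[i] && col[j]) {
        c1 <- col; c1[i] <- FALSE
        c2 <- col; c2[j] <- FALSE
        new_cols <- c(new_cols, list(c1, c2))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    # absorb columns whose membership is a subset of another's
    keep <- rep(TRUE, length(new_cols))
    for (a in seq_along(new_cols)) {
      for (b in seq_along(new_cols)) {
        if (a != b && keep[a] &&
            all(new_cols[[a]] <= new_cols[[b]]) &&
            !identical(new_cols[[a]], new_cols[[b]])) {
          keep[a] <- FALSE
        }
      }
    }
    cols <- new_cols[keep]
    cols <- cols[!duplicated(cols)]
  }
  first_member <- vapply(cols, function(col) which(col)[1], numeric(1))
  cols <- cols[order(first_member)]
  vapply(seq_len(k), function(g) {
    paste0(letters[which(vapply(cols, `[`, logical(1), g))], collapse = "")
  }, character(1))
}

#' Standardised principal component analysis
#'
#' Centers and scales every variable to unit variance, then
#' eigen-decomposes the correlation matrix. Explained variance per
#' dimension is `eigenvalue / sum(eigenvalues) * 100`; loadings are the
#' unit-norm eigenvectors, each oriented so its largest-magnitude entry is
#' positive (a deterministic sign convention); scores are the projections
#' of the standardised data.
#'
#' @param x A numeric matrix or data frame, samples in rows, variables in
#'   columns (>= 2 of each, no missing values). Non-numeric columns named
#'   in `id_cols` are carried through as sample labels.
#' @param id_cols Character vector of label columns to exclude from the
#'   decomposition. Default `"blend"` if present.
#' @return An object of class `pca_std`: list with `explained` (percent
#'   per dimension), `loadings` (variables x dimensions), `scores`
#'   (samples x dimensions), `eigenvalues`, and sample labels. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' pca_standardized(datasets::USArrests)
#' @export
pca_standardized <- function(x, id_cols = intersect("blend", colnames(x))) {
  labs <- NULL
  if (is.data.frame(x)) {
    if (length(id_cols) > 0) {
      labs <- do.call(paste, c(x[id_cols], sep = "/"))
      x <- x[setdiff(names(x), id_cols)]
    }
    x <- as.matrix(x)
  }
  if (is.null(labs)) {
    labs <- rownames(x) %||% as.character(seq_len(nrow(x)))
  }
  stopifnot(is.numeric(x))
  if (nrow(x) < 2 || ncol(x) < 2) {
    rlang::abort("PCA needs at least 2 samples and 2 variables",
                 class = "oilblendr_validation_error")
  }
  if (anyNA(x)) {
    rlang::abort("PCA input contains missing values",
                 class = "oilblendr_validation_error")
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    rlang::abort(
      paste0("Zero-variance column(s): ",
             paste(colnames(x)[sds == 0], collapse = ", ")),
      class = "oilblendr_zero_variance"
    )
  }
  z <- scale(x)
  e <- eigen(stats::cor(x), symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  # deterministic sign: largest-magnitude loading positive, per component
  for (j in seq_len(ncol(vecs))) {
    m <- which.max(abs(vecs[, j]))
    if (vecs[m, j] < 0) vecs[, j] <- -vecs[, j]
  }
  dimnames(vecs) <- list(colnames(x), paste0("Dim", seq_len(ncol(vecs))))
  scores <- z %*% vecs
  rownames(scores) <- labs
  structure(
    list(
      explained = vals / sum(vals) * 100,
      eigenvalues = vals,
      loadings = vecs,
      scores = scores,
      labels = labs
    ),
    class = "pca_std"
  )
}

#' @export
print.pca_std <- function(x, ...) {
  cat("Standardised PCA: ", nrow(x$scores), " samples x ",
      nrow(x$loadings), " variables\n", sep = "")
  ev <- sprintf("%.1f%%", x$explained[1:min(3, length(x$explained))])
  cat("  Explained: ", paste(ev, collapse = ", "), " ...\n", sep = "")
  invisible(x)
}

#' @method tidy pca_std
#' @export
tidy.pca_std <- function(x, matrix = c("eigenvalues", "loadings", "scores"),
                         ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    eigenvalues = tibble::tibble(
      dimension = seq_along(x$explained),
      eigenvalue = x$eigenvalues,
      explained = x$explained,
      cumulative = cumsum(x$explained)
    ),
    loadings = x$loadings |>
      tibble::as_tibble(rownames = "variable") |>
      tidyr::pivot_longer(-"variable", names_to = "dimension",
                          values_to = "loading"),
    scores = x$scores |>
      tibble::as_tibble(rownames = "sample") |>
      tidyr::pivot_longer(-"sample", names_to = "dimension",
                          values_to = "score")
  )
}

#' @method glance pca_std
#' @export
glance.pca_std <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_variables = nrow(x$loadings),
    dim1_explained = x$explained[1],
    dim2_explained = x$explained[2],
    dim12_explained = x$explained[1] + x$explained[2]
  )
}
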