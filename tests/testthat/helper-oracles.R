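# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain arithmetic, grid search, brute force.

# grid search for the binary-blend mass fraction, 1e-5 resolution
grid_search_blend_w <- function(o6a, o3a, o6b, o3b, target) {
  w <- seq(0, 1, by = 1e-5)
  ratio <- (o6a * w + o6b * (1 - w)) / (o3a * w + o3b * (1 - w))
  w[which.min(abs(ratio - target))]
}

# direct arithmetic on the closed-form BPP ratio
bpp_ratio_oracle <- function(x) {
  j0 <- 1
  j1 <- 1 / (1 + x^2)
  j2 <- 1 / (1 + 4 * x^2)
  r1 <- j1 + 4 * j2
  r2 <- (3 * j0 + 5 * j1 + 2 * j2) / 2
  r2 / r1
}

# brute-force Tukey HSD significance for a pair, straight from the
# studentized-range distribution
tukey_pair_significant <- function(groups, i, j, alpha = 0.05) {
  df_w <- sum(groups$n - 1)
  ms_w <- sum((groups$n - 1) * groups$sd^2) / df_w
  se <- sqrt(ms_w / 2 * (1 / groups$n[i] + 1 / groups$n[j]))
  q <- abs(groups$mean[i] - groups$mean[j]) / se
  stats::ptukey(q, nmeans = nrow(groups), df = df_w,
                lower.tail = FALSE) < alpha
}

# letters valid iff sharing a letter <=> pair not significant
cld_matches_all_pairs <- function(groups, cld, alpha = 0.05) {
  k <- nrow(groups)
  lets <- strsplit(cld$letters[match(groups$label, cld$label)], "")
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      share <- length(intersect(lets[[i]], lets[[j]])) > 0
      sig <- tukey_pair_significant(groups, i, j, alpha)
      if (share == sig) return(FALSE)
    }
  }
  TRUE
}

# a small two-oil system used in blend-formulation tests
toy_profile <- function(label, o6, o3, filler_acid = "C18:0") {
  parse_profile(data.frame(
    blend = label,
    acid = c("C18:2", "C18:3", filler_acid),
    percent = c(o6, o3, 100 - o6 - o3)
  ))
}
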