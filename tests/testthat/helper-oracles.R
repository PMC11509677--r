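# Independent brute-force oracles used to check the package's implementations.

# Presence rule evaluated literally: keep a protein iff some (bait, condition)
# group has >= k non-missing values.
oracle_presence_keep <- function(present_row, design, k) {
  for (g in unique(design$group)) {
    cols <- design$sample_id[design$group == g]
    if (sum(present_row[cols]) >= k) return(TRUE)
  }
  FALSE
}

# Benjamini-Hochberg step-up from the definition: sort, p * n / rank,
# cumulative minimum from the largest rank down, cap at 1.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Hypergeometric upper tail P(X >= k) by direct enumeration with choose().
oracle_hyper_upper <- function(k, K, n, N) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# All-pairs MSD from the definition, pooling tracks at each lag.
oracle_msd <- function(tracks, max_lag, dt) {
  sp <- split(as.data.frame(tracks), tracks$track_id)
  sp <- sp[vapply(sp, nrow, 1L) >= 3]
  lags <- seq(dt, max_lag, by = dt)
  vapply(lags, function(tau) {
    tot <- 0; cnt <- 0
    for (df in sp) {
      df <- df[order(df$t_min), ]
      for (i in seq_len(nrow(df))) {
        j <- which(abs(df$t_min - (df$t_min[i] + tau)) < 1e-9)
        if (length(j) == 1) {
          tot <- tot + (df$x_um[j] - df$x_um[i])^2 + (df$y_um[j] - df$y_um[i])^2
          cnt <- cnt + 1
        }
      }
    }
    tot / cnt
  }, 1)
}

# Random small intensity table for round-trip and filter tests.
random_intensity_table <- function(n = 20, seed = 1, design = default_design()) {
  set.seed(seed)
  raw <- matrix(2^stats::rnorm(n * nrow(design), 24, 2), n,
                dimnames = list(sprintf("P%03d", 1:n), design$sample_id))
  raw[sample(length(raw), round(0.15 * length(raw)))] <- NA
  flags <- data.frame(contaminant = rep(FALSE, n), reverse = FALSE,
                      only_by_site = FALSE)
  new_intensity_table(raw, flags, design)
}
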