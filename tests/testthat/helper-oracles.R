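# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each quantity and never call the
# package's fast paths.

# O(N^2) direct-sum autocorrelation: r_k = sum_i (y_i - m)(y_{i+k} - m) / ss
acf_direct_sum <- function(y, max_lag) {
  m <- mean(y)
  ss <- sum((y - m)^2)
  n <- length(y)
  vapply(0:max_lag, function(k) {
    acc <- 0
    for (i in seq_len(n - k)) acc <- acc + (y[i] - m) * (y[i + k] - m)
    acc / ss
  }, 1)
}

# hand sum-of-squares one-way ANOVA F
anova_F_by_hand <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  k <- length(groups)
  n <- length(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  (ssb / (k - 1)) / (ssw / (n - k))
}

# direct-formula pooled two-sample t
t_by_hand <- function(a, b) {
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}

# random valid activity series for property tests
random_series <- function(n_days = 1, bin_width = 1, lambda = 2,
                          id = "rnd") {
  n <- n_days * 1440 / bin_width
  activity_series(id, "2020-01-01 00:00", rpois(n, lambda),
                  bin_width = bin_width)
}

default_schedule <- function(ld = 5, dd = 5)
  light_schedule(ld, dd, reference_start = "2020-01-01 00:00")
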