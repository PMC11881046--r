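# Independent oracles, deliberately written as plain loops / closed forms
# so they share no code path with the package implementation.

# Kendall tau-b by exhaustive enumeration of all n(n-1)/2 pairs.
tau_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- tie_x <- tie_y <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      sx <- sign(x[j] - x[i])
      sy <- sign(y[j] - y[i])
      if (sx * sy > 0) conc <- conc + 1L
      if (sx * sy < 0) disc <- disc + 1L
      if (sx == 0) tie_x <- tie_x + 1L
      if (sy == 0) tie_y <- tie_y + 1L
    }
  }
  n0 <- n * (n - 1L) / 2L
  (conc - disc) / sqrt((n0 - tie_x) * (n0 - tie_y))
}

# OLS slope of y on x via lm(), an independent route to the closed form.
slope_oracle <- function(y, x) unname(coef(stats::lm(y ~ x))[2L])

# Elementwise-loop mean/max absolute deviation.
mad_oracle <- function(calc, exp) {
  s <- 0
  for (i in seq_along(calc)) s <- s + abs(calc[i] - exp[i])
  s / length(calc)
}
max_oracle <- function(calc, exp) {
  m <- 0
  for (i in seq_along(calc)) m <- max(m, abs(calc[i] - exp[i]))
  m
}

# Sort-based rank oracle (ties averaged) for a lower-is-better vector.
rank_oracle <- function(v) {
  r <- numeric(length(v))
  for (i in seq_along(v)) {
    less <- sum(v < v[i])
    eq <- sum(v == v[i])
    r[i] <- less + (eq + 1) / 2
  }
  r
}

# Small panel of hand-built metric rows used by ranking tests.
toy_metrics <- function() {
  tibble::tibble(
    method_id = c("A", "B", "C"),
    madtr     = c(0.10, 0.20, 0.15),
    maxtr     = c(0.30, 0.25, 0.40),
    r2        = c(0.90, 0.50, 0.70),
    tau       = c(0.80, 0.40, 0.60),
    rel_range = c(0.05, 0.30, 0.10),
    rel_slope = c(0.10, 0.50, 0.20)
  )
}
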