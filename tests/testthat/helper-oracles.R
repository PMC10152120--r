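# Independent numerical oracles used across the suite. These deliberately
# avoid the code paths they are checking.

# TIA of A0 * 2^(-t/T) by composite trapezoid on [0, 20 T] plus the exact
# analytic tail beyond 20 half-lives.
tia_numeric_oracle <- function(A0, T, n_grid = 20000) {
  tt <- seq(0, 20 * T, length.out = n_grid)
  a <- A0 * 2^(-tt / T)
  trap <- sum((a[-1] + a[-n_grid]) / 2 * diff(tt))
  tail <- A0 * T / log(2) * 2^(-20)
  trap + tail
}

# Two-sided exact Wilcoxon signed-rank p-value by brute-force enumeration of
# all 2^n sign assignments (mid-ranks for tied magnitudes). Returns the
# statistic and p for the observed signs.
wilcoxon_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.vector(signs %*% r)
  p_le <- mean(W_all <= W_obs + 1e-9)
  p_ge <- mean(W_all >= W_obs - 1e-9)
  list(W = W_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Dense grid search for the extrema / roots of the Hanscheid relative error
# e(x) = 2 x 2^-x - 1, independent of the package's closed form.
hanscheid_error_grid <- function(from = 0.01, to = 10, n = 2e6) {
  x <- seq(from, to, length.out = n)
  e <- 2 * x * 2^(-x) - 1
  list(x = x, e = e,
       x_max = x[which.max(e)], e_max = max(e))
}

# Noiseless curve helper.
exact_tac <- function(A0, T, times, patient = "p", cycle = 2L,
                      voi = "v", type = "lesion") {
  tac(patient, cycle, voi, type, times, A0 * 2^(-times / T))
}
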