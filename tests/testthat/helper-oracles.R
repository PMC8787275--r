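# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive: they share no code with the implementation paths
# they check.

# Naive spectral-index estimate: full-length raw periodogram (no Welch
# segmenting, no taper) + OLS of log10 power on log10 frequency over all
# positive-frequency bins.
naive_periodogram_beta <- function(values, sampling_interval = 1) {
  n <- length(values)
  X <- stats::fft(values - mean(values))
  m <- floor(n / 2)
  P <- (2 * sampling_interval / n) * Mod(X[2:(m + 1)])^2
  f <- (1:m) / (n * sampling_interval)
  keep <- P > 0
  -unname(stats::coef(stats::lm(log10(P[keep]) ~ log10(f[keep])))[2])
}

# Holm's step-down procedure as a level-alpha sequential-rejection rule
# (not an adjusted-p formula): walk the sorted p-values, reject while
# p_(i) <= alpha / (m - i + 1), stop at the first failure.
holm_reject_at <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  rejected <- rep(FALSE, m)
  for (i in seq_len(m)) {
    if (p[o[i]] <= alpha / (m - i + 1)) {
      rejected[o[i]] <- TRUE
    } else {
      break
    }
  }
  rejected
}

# Check that adjusted p-values and the sequential-rejection rule agree:
# adj_i <= alpha iff hypothesis i is rejected at level alpha, probed at
# each adjusted value +- eps and at conventional levels.
holm_consistent <- function(p, adj, eps = 1e-9) {
  # alpha = 1 is excluded: capping adjusted values at 1 loses the
  # information the sequential rule at level 1 would use
  alphas <- unique(pmax(0, c(adj - eps, adj + eps, 0.05, 0.01, 0.5)))
  alphas <- alphas[alphas < 1]
  for (a in alphas) {
    if (!identical(unname(adj <= a), unname(holm_reject_at(p, a)))) {
      return(FALSE)
    }
  }
  TRUE
}

# ICC(2,1) via R's two-way ANOVA table rather than closed-form sums.
aov_icc_2_1 <- function(tab) {
  n <- nrow(tab)
  k <- ncol(tab)
  df <- data.frame(
    y = as.vector(tab),
    subj = factor(as.vector(row(tab))),
    rater = factor(as.vector(col(tab)))
  )
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]
  msc <- ms[2]
  mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Simulated rater table: value = subject effect + noise.
sim_rater_table <- function(n, k, subject_var, noise_var) {
  subj <- stats::rnorm(n, 0, sqrt(subject_var))
  matrix(subj, n, k) + matrix(stats::rnorm(n * k, 0, sqrt(noise_var)), n, k)
}
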