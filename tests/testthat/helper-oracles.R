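# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops, base lm(), and direct numerical
# integration.

# literal transcription of the first-peak definition: earliest interior
# point >= both neighbours whose subsequent minimum drops by >= prominence;
# otherwise the global maximum with a boundary flag
first_peak_scan <- function(s, prominence) {
  n <- length(s)
  for (i in 2:(n - 1)) {
    if (s[i] >= s[i - 1] && s[i] >= s[i + 1] &&
        min(s[i:n]) <= s[i] - prominence) {
      return(list(index = i, boundary = FALSE))
    }
  }
  list(index = which.max(s), boundary = TRUE)
}

# windowed running median/mean with symmetric edge shrinkage, plain loop
running_stat_scan <- function(x, window, stat) {
  n <- length(x)
  half <- (window - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(half, i - 1, n - i)
    out[i] <- stat(x[(i - h):(i + h)])
  }
  out
}

# sequential sums of squares by brute-force nested refits with base lm()
nested_rss_anova <- function(formulas, data) {
  rss <- vapply(formulas, function(f) {
    sum(residuals(lm(f, data = data))^2)
  }, numeric(1))
  -diff(rss)
}

# studentized range CDF by direct double numerical integration:
# P(Q <= q) = int_0^inf dchi(s; df) * k * int phi(z) (Phi(z) - Phi(z - q s))^(k-1) dz ds
ptukey_numeric <- function(q, k, df) {
  inner <- function(s) {
    vapply(s, function(si) {
      f <- function(z) {
        k * dnorm(z) * pmax(pnorm(z) - pnorm(z - q * si), 0)^(k - 1)
      }
      integrate(f, -8, 8, rel.tol = 1e-9)$value
    }, numeric(1))
  }
  # density of s = sqrt(chi2_df / df)
  dens <- function(s) {
    exp(df / 2 * log(df) - lgamma(df / 2) - (df / 2 - 1) * log(2) +
          (df - 1) * log(s) - df * s^2 / 2)
  }
  integrate(function(s) dens(s) * inner(s), 0, 10,
            rel.tol = 1e-8, subdivisions = 400L)$value
}

# small random survival-like dataset with per-stratum linear decay
random_survival_data <- function(n_strata = 3, n_dur = 4, sd = 0.2) {
  strata <- paste0("s", seq_len(n_strata))
  slopes <- runif(n_strata, -0.03, 0)
  icpts <- runif(n_strata, 1, 3)
  d <- expand.grid(level = strata, duration_min = seq(0, 90, length.out = n_dur),
                   stringsAsFactors = FALSE)
  i <- match(d$level, strata)
  d$log10_percent <- icpts[i] + slopes[i] * d$duration_min +
    rnorm(nrow(d), 0, sd)
  d$censored <- FALSE
  tibble::as_tibble(d)
}

with_tmpdir <- function(code) {
  dir <- tempfile("phagestress_test_")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  force(code(dir))
}
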