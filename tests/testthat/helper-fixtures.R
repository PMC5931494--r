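# Shared fixtures: small configurations and independent oracles used across
# test files. Everything is generated in code; no stored data.

# A small, fast cohort configuration (all individuals measured)
small_config <- function(n = 2000, ...) {
  generator_config(n_individuals = n, measured_subset_fraction = 1, ...)
}

# Noise-free single-area configuration: exposure is an exact linear function
# of dosage (used for machine-precision checks)
noiseless_config <- function(n = 400, betas = c(2.84, 0.95)) {
  panel <- ckb_snp_panel()[seq_along(betas), ]
  panel$beta_exposure <- betas
  generator_config(
    n_individuals = n, snps = panel, n_areas = 1, latitude_slope = 0,
    season_effects = c(winter = 0, spring = 0, summer = 0, autumn = 0),
    exposure_residual_sd = 0,
    confounder_exposure_effects = numeric(0),
    measured_subset_fraction = 1
  )
}

# Weighted-least-squares oracle for fixed-effect IVW: intercept-only WLS of
# the estimates with weights 1/se^2
wls_oracle <- function(beta, se) {
  fit <- lm(beta ~ 1, weights = 1 / se^2)
  s <- summary(fit)
  list(beta = unname(coef(fit)[1]),
       se = unname(s$coefficients[1, "Std. Error"] / s$sigma))
}

# Brute-force interpolated weighted median (direct enumeration of the
# cumulative-weight convention)
wmedian_oracle <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o] / sum(w)
  p <- numeric(length(w))
  for (i in seq_along(w)) p[i] <- sum(w[seq_len(i)]) - w[i] / 2
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  for (i in seq_len(length(p) - 1)) {
    if (p[i] < 0.5 && 0.5 <= p[i + 1]) {
      return(r[i] + (r[i + 1] - r[i]) * (0.5 - p[i]) / (p[i + 1] - p[i]))
    }
  }
}
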