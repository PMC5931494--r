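#' Construct an effect estimate on the log odds-ratio scale
#'
#' The common result container used across the package: a one-row data frame
#' holding a log odds ratio with its standard error, Wald 95% confidence
#' interval on the OR scale, two-sided p-value from the normal approximation,
#' a unit tag and a method label.
#'
#' @param beta Log odds ratio (or linear effect when `unit` says so).
#' @param se Standard error of `beta`; must be positive (zero is accepted but
#'   flagged degenerate via `p = NA`).
#' @param unit One of `"per-allele"`, `"per-25-nmol/l"`, `"per-tertile"`, or
#'   another descriptive unit tag.
#' @param method Character label of the producing method.
#' @param n,n_cases Optional sample sizes.
#' @return A one-row `data.frame` of class `"vitdmr_estimate"` with columns
#'   `method`, `unit`, `beta`, `se`, `or`, `ci_low`, `ci_high`, `p`, `n`,
#'   `n_cases`.
#' @examples
#' new_estimate(log(0.91), 0.05, unit = "per-25-nmol/l", method = "example")
#' @export
new_estimate <- function(beta, se, unit = "per-25-nmol/l", method = "unspecified",
                         n = NA_integer_, n_cases = NA_integer_) {
  stopifnot(is.numeric(beta), is.numeric(se), length(beta) == length(se))
  if (any(se < 0, na.rm = TRUE)) stop("standard errors must be non-negative")
  p <- ifelse(se > 0, 2 * pnorm(-abs(beta / se)), NA_real_)
  out <- data.frame(
    method = method, unit = unit, beta = beta, se = se,
    or = exp(beta),
    ci_low = exp(beta - Z95 * se),
    ci_high = exp(beta + Z95 * se),
    p = p, n = n, n_cases = n_cases,
    stringsAsFactors = FALSE
  )
  class(out) <- c("vitdmr_estimate", "data.frame")
  out
}

#' @export
print.vitdmr_estimate <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  df$or <- round(df$or, digits)
  df$ci_low <- round(df$ci_low, digits)
  df$ci_high <- round(df$ci_high, digits)
  cat("Effect estimate(s):\n")
  print(df[, c("method", "unit", "or", "ci_low", "ci_high", "p", "n", "n_cases")],
        row.names = FALSE)
  invisible(x)
}

# Fixed-effect inverse-variance pooling of (beta, se) pairs.
# Returns beta, se, Q (Cochran heterogeneity), df and I^2 (%).
.ivw_pool <- function(beta, se) {
  if (length(beta) < 1L) stop("no estimates to pool")
  if (any(!is.finite(beta)) || any(!is.finite(se)) || any(se <= 0))
    stop("all estimates must be finite with positive standard errors")
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- sqrt(1 / sum(w))
  q <- sum(((beta - b) / se)^2)
  df <- length(beta) - 1L
  i2 <- if (df > 0 && q > df) 100 * (q - df) / q else 0
  list(beta = b, se = s, Q = q, df = df, I2 = i2)
}

# Convert a percent-lower-risk to log OR and back
.pct_lower <- function(beta) 100 * (1 - exp(beta))

# Seed a block of code without clobbering the caller's RNG stream: the
# global .Random.seed is restored on exit. A NULL seed leaves the current
# stream untouched.
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
      else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
    }, add = TRUE)
    set.seed(seed)
  }
  code
}
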