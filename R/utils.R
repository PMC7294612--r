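`%||%` <- function(a, b) if (is.null(a)) b else a

#' Truncated normal draws
#'
#' Samples from a Normal(mean, sd) restricted to the open interval
#' (lower, upper), by inversion of the CDF. Used by the synthetic-data
#' generator to keep triglyceride values positive and to draw
#' class-consistent TG changes.
#'
#' @param n number of draws.
#' @param mean,sd normal parameters (recycled).
#' @param lower,upper truncation bounds; `-Inf`/`Inf` allowed.
#' @return numeric vector of length `n`.
#' @keywords internal
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  if (any(sd < 0)) stop("sd must be non-negative")
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (any(phi <= plo)) stop("empty truncation interval")
  u <- plo + stats::runif(n) * (phi - plo)
  # clamp away from 0/1 so qnorm never returns the bound itself
  u <- pmin(pmax(u, .Machine$double.xmin), 1 - .Machine$double.eps)
  stats::qnorm(u, mean, sd)
}

# location mu such that a Normal(mu, sd) truncated below at `lower` has
# the requested mean; keeps simulated TG marginals on target despite the
# positivity floor
truncnorm_location <- function(target_mean, sd, lower) {
  if (!is.finite(lower) || stats::pnorm(lower, target_mean, sd) < 1e-12)
    return(target_mean)
  tmean <- function(mu) {
    a <- (lower - mu) / sd
    mu + sd * stats::dnorm(a) / stats::pnorm(a, lower.tail = FALSE)
  }
  stats::uniroot(function(mu) tmean(mu) - target_mean,
                 interval = c(target_mean - 6 * sd, target_mean),
                 tol = 1e-10)$root
}

# c4 unbiasedness constant: E[s] = c4(n) * sigma for a sample SD of n
# iid normal draws
c4_constant <- function(n) {
  sqrt(2 / (n - 1)) * exp(lgamma(n / 2) - lgamma((n - 1) / 2))
}

stop_n3 <- function(...) stop(..., call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
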