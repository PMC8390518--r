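#' Derive a stage-local seed from a master seed
#'
#' All stochastic stages draw their seed deterministically from one master
#' seed so that a whole pipeline run is reproducible from a single integer.
#' Results stay below 2^31 - 1 so they are valid R integer seeds.
#'
#' @param seed master integer seed.
#' @param stage character stage label (e.g. "simulate", "bootstrap").
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

#' Moment-matched lower-truncated normal parameters
#'
#' Finds the location/scale (mu, sigma) of a normal distribution such that,
#' after truncation below `lower`, the resulting distribution has the
#' requested mean and standard deviation. Used for the per-segment speed
#' distribution, whose published mean and SD describe measured (hence
#' positive) speeds.
#'
#' @param mean,sd target mean and SD of the truncated distribution.
#' @param lower truncation point (same units).
#' @return list with `mu`, `sigma`, `lower`.
#' @export
tnorm_params <- function(mean, sd, lower) {
  stopifnot(mean > lower, sd > 0)
  moments <- function(mu, sigma) {
    a <- (lower - mu) / sigma
    Z <- 1 - stats::pnorm(a)
    lam <- stats::dnorm(a) / Z
    m <- mu + sigma * lam
    v <- sigma^2 * (1 + a * lam - lam^2)
    c(m, sqrt(v))
  }
  obj <- function(p) {
    mm <- moments(p[1], exp(p[2]))
    (mm[1] - mean)^2 + (mm[2] - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]), lower = lower)
}

#' Sample from a lower-truncated normal by inverse CDF
#'
#' @param n number of draws.
#' @param par list from [tnorm_params()].
#' @return numeric vector of length `n`, all `>= par$lower`.
#' @export
rtnorm <- function(n, par) {
  p0 <- stats::pnorm((par$lower - par$mu) / par$sigma)
  u <- stats::runif(n, p0, 1)
  par$mu + par$sigma * stats::qnorm(u)
}

# md5 of an R object via its serialized JSON; used for run manifests
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}
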