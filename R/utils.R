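# Internal helpers shared across modules.

# Instrument ranges for all bounded scales handled by the package.
INSTRUMENT_RANGES <- list(
  phq9_baseline     = c(0, 27),
  phq9_post         = c(0, 27),
  hamd_baseline     = c(0, 52),
  nrs_pain          = c(0, 10),
  aqol              = c(0, 100),
  pseq              = c(0, 60),
  spe               = c(0, 3),
  odi               = c(0, 100),
  internet_affinity = c(4, 20),
  age               = c(18, 80)
)

#' @keywords internal
instrument_range <- function(name) {
  r <- INSTRUMENT_RANGES[[name]]
  if (is.null(r)) stop("no instrument range known for column '", name, "'")
  r
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

logit <- function(p) log(p / (1 - p))

is_binary01 <- function(x) is.numeric(x) && all(x %in% c(0, 1))

# Symmetric inverse square root of a symmetric PSD matrix via eigen
# decomposition; eigenvalues below tol are truncated (Moore-Penrose style).
sym_inv_sqrt <- function(M, tol = 1e-12) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  vals <- e$values
  inv <- ifelse(vals > tol * max(abs(vals), 1), 1 / sqrt(vals), 0)
  e$vectors %*% (inv * t(e$vectors))
}

sym_sqrt_inv <- sym_inv_sqrt

# Moments of a N(mu, sd) truncated to [lo, hi].
truncnorm_moments <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  pa <- stats::dnorm(a); pb <- stats::dnorm(b)
  m <- mu + sd * (pa - pb) / Z
  v <- sd^2 * (1 + (a * pa - b * pb) / Z - ((pa - pb) / Z)^2)
  list(mean = m, var = v)
}

.mobcate_cache <- new.env(parent = emptyenv())

# Find latent (mu, sd) so that N(mu, sd) truncated to [lo, hi] has the target
# mean and sd. Used so configured instrument marginals survive truncation.
# Memoised: generation loops hit the same few parameter sets repeatedly.
calibrate_truncnorm <- function(mean, sd, lo, hi) {
  key <- paste("tn", mean, sd, lo, hi, sep = "|")
  hit <- .mobcate_cache[[key]]
  if (!is.null(hit)) return(hit)
  obj <- function(par) {
    m <- truncnorm_moments(par[1], exp(par[2]), lo, hi)
    if (!is.finite(m$mean) || !is.finite(m$var) || m$var <= 0) return(1e10)
    (m$mean - mean)^2 + (sqrt(m$var) - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  res <- list(mu = fit$par[1], sd = exp(fit$par[2]))
  .mobcate_cache[[key]] <- res
  res
}

rtruncnorm <- function(n, mu, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mu, sd), stats::pnorm(hi, mu, sd))
  stats::qnorm(u, mu, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
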