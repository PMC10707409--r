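# Internal helpers: seeded evaluation and moment-matched truncated sampling.

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Mean and SD of N(mu, sigma^2) truncated to [a, b]; stable far into the tail
# (log-scale normalising constant, Mills-ratio form for b = Inf).
.truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  lZ <- if (is.finite(be)) {
    z <- pnorm(be) - pnorm(al)
    if (z <= 0) return(c(NaN, NaN))
    log(z)
  } else {
    pnorm(al, lower.tail = FALSE, log.p = TRUE)
  }
  if (!is.finite(lZ)) return(c(NaN, NaN))
  da <- exp(dnorm(al, log = TRUE) - lZ)
  db <- if (is.finite(be)) exp(dnorm(be, log = TRUE) - lZ) else 0
  h <- da - db
  m <- mu + sigma * h
  aa <- if (is.finite(a)) al * da else 0
  bb <- if (is.finite(be)) be * db else 0
  v <- sigma^2 * (1 + aa - bb - h^2)
  c(m, sqrt(max(v, 0)))
}

# Solve for (mu, sigma) so the [a, b]-truncated normal has the requested mean
# and SD. If no truncated normal attains the target coefficient of variation
# (sup CV on a half-line is 1), fall back to a moment-matched gamma, clipped
# at b (negligible mass in all uses here). Fits are cached: cohort simulation
# re-solves the same six targets many times.
.fit_cache <- new.env(parent = emptyenv())

.fit_trunc_family <- function(mean, sd, a = 0, b = Inf, rel_tol = 1e-5) {
  stopifnot(is.finite(mean), is.finite(sd), sd > 0, mean > a)
  key <- paste(format(c(mean, sd, a, b), digits = 15), collapse = "|")
  hit <- .fit_cache[[key]]
  if (!is.null(hit)) return(hit)
  obj <- function(p) {
    mm <- .truncnorm_moments(p[1], exp(p[2]), a, b)
    if (!all(is.finite(mm))) return(1e10)
    (mm[1] / mean - 1)^2 + (mm[2] / sd - 1)^2
  }
  best <- NULL
  for (mu0 in c(mean, a, a - sd, a - 3 * sd, a - 8 * sd)) {
    r <- suppressWarnings(
      optim(c(mu0, log(sd)), obj, control = list(maxit = 10000, reltol = 1e-15)))
    if (is.null(best) || r$value < best$value) best <- r
  }
  fit <- if (sqrt(best$value) < rel_tol) {
    list(family = "truncnorm", mu = best$par[1], sigma = exp(best$par[2]),
         a = a, b = b)
  } else {
    shape <- (mean / sd)^2
    list(family = "gamma", shape = shape, rate = shape / mean, a = a, b = b)
  }
  .fit_cache[[key]] <- fit
  fit
}

.draw_trunc_family <- function(n, fit) {
  if (n == 0L) return(numeric(0))
  x <- if (fit$family == "truncnorm") {
    lo <- pnorm((fit$a - fit$mu) / fit$sigma)
    hi <- pnorm((fit$b - fit$mu) / fit$sigma)
    fit$mu + fit$sigma * qnorm(runif(n, lo, hi))
  } else {
    rgamma(n, shape = fit$shape, rate = fit$rate)
  }
  pmin(pmax(x, fit$a), fit$b)
}

.draw_moments <- function(n, mean, sd, a = 0, b = Inf) {
  if (sd == 0) return(rep(mean, n))
  .draw_trunc_family(n, .fit_trunc_family(mean, sd, a, b))
}

.stop_invalid <- function(...) stop(..., call. = FALSE)
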