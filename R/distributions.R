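#' Sample from a named distribution specification
#'
#' Distribution specs are small lists (usually read from a generator config
#' JSON file) with a `name` element plus parameters. Supported names:
#'
#' * `normal`: `mean`, `sd`, optional truncation `min`/`max` (resampling),
#'   optional `integer = TRUE` to round to whole numbers.
#' * `lognormal`: `meanlog`, `sdlog`, optional `min`/`max`, optional `digits`
#'   to round the result.
#' * `poisson`: `lambda`, optional `max` (truncation by resampling).
#' * `categorical`: `values`, `probs` (same length, probs sum to 1).
#' * `uniform_int`: integers drawn uniformly from `min..max`.
#' * `bernoulli`: `prob`; draws are logical.
#' * `constant`: every draw equals `value`.
#'
#' Truncation by resampling keeps the draw inside `[min, max]`; it is a
#' simulation convenience, not a claim about clinical distributions.
#'
#' @param spec a list with at least `name`; see above.
#' @param n number of draws.
#' @param field label used in error messages (the config field being sampled).
#' @return numeric (or value-typed, for `categorical`) vector of length `n`.
#' @export
sample_dist <- function(spec, n, field = "distribution") {
  if (!is.list(spec) || is.null(spec$name)) {
    stop(sprintf("configuration error in '%s': distribution spec must be a list with a 'name'", field),
         call. = FALSE)
  }
  need <- function(par) {
    if (is.null(spec[[par]])) {
      stop(sprintf("configuration error in '%s': distribution '%s' requires parameter '%s'",
                   field, spec$name, par), call. = FALSE)
    }
    spec[[par]]
  }
  resample_trunc <- function(draw_fun) {
    lo <- if (is.null(spec$min)) -Inf else spec$min
    hi <- if (is.null(spec$max)) Inf else spec$max
    x <- draw_fun(n)
    bad <- which(x < lo | x > hi)
    tries <- 0L
    while (length(bad) > 0L && tries < 1000L) {
      x[bad] <- draw_fun(length(bad))
      bad <- bad[x[bad] < lo | x[bad] > hi]
      tries <- tries + 1L
    }
    if (length(bad) > 0L) x[bad] <- pmin(pmax(x[bad], lo), hi)
    x
  }
  x <- switch(
    spec$name,
    normal = {
      m <- need("mean"); s <- need("sd")
      out <- resample_trunc(function(k) stats::rnorm(k, m, s))
      if (isTRUE(spec$integer)) out <- round(out)
      out
    },
    lognormal = {
      ml <- need("meanlog"); sl <- need("sdlog")
      out <- resample_trunc(function(k) stats::rlnorm(k, ml, sl))
      if (!is.null(spec$digits)) out <- round(out, spec$digits)
      out
    },
    poisson = {
      lam <- need("lambda")
      resample_trunc(function(k) stats::rpois(k, lam))
    },
    categorical = {
      v <- need("values"); p <- need("probs")
      if (length(v) != length(p)) {
        stop(sprintf("configuration error in '%s': 'values' and 'probs' differ in length", field),
             call. = FALSE)
      }
      v[sample.int(length(v), n, replace = TRUE, prob = p)]
    },
    uniform_int = {
      lo <- need("min"); hi <- need("max")
      if (hi < lo) stop(sprintf("configuration error in '%s': max < min", field), call. = FALSE)
      lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
    },
    bernoulli = {
      p <- need("prob")
      if (p < 0 || p > 1) {
        stop(sprintf("configuration error in '%s': prob must be in [0,1]", field), call. = FALSE)
      }
      stats::runif(n) < p
    },
    constant = rep(need("value"), n),
    stop(sprintf("configuration error in '%s': unknown distribution '%s'", field, spec$name),
         call. = FALSE)
  )
  if (n == 0L) x[0] else x
}
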