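#' Create labelled independent random streams
#'
#' Builds one self-contained L'Ecuyer-CMRG generator per label, so that each
#' stochastic subsystem of the simulator (supply noise, breakage, consumer
#' arrivals, departure jitter) draws from its own stream. A stream's draw
#' sequence is a deterministic function of `(seed, label)` only, which is
#' what makes, e.g., the production-multiplier linearity exact: changing the
#' multiplier perturbs the breakage stream's consumption but cannot touch
#' the supply stream. Drawing from a stream never disturbs the global
#' `.Random.seed`.
#'
#' @param seed Integer seed.
#' @param labels Character vector of unique stream labels.
#' @return Named list of `rng_stream` objects, one per label.
#' @examples
#' s <- make_rng_streams(42, c("breakage", "arrivals"))
#' rs_unif(s$breakage, 3)
#' @export
make_rng_streams <- function(seed, labels) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("stream labels must be unique")
  streams <- lapply(labels, function(lb) rng_stream(seed, lb))
  names(streams) <- labels
  streams
}

#' @rdname make_rng_streams
#' @param label Single stream label.
#' @export
rng_stream <- function(seed, label) {
  s <- stream_seed(seed, label)
  e <- new.env(parent = emptyenv())
  e$label <- label
  old <- global_seed_get()
  set.seed(s, kind = "L'Ecuyer-CMRG")
  e$state <- .GlobalEnv$.Random.seed
  global_seed_set(old)
  class(e) <- "rng_stream"
  e
}

# Deterministic 31-bit combination of the user seed and a string label.
# Base R offers no keyed substream API; a string hash keeps the stream a
# function of the label itself rather than of its position in a list.
stream_seed <- function(seed, label) {
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% 2147483647
  s <- (as.numeric(seed) %% 2147483647) * 48271 + h
  as.integer(s %% 2147483647)
}

global_seed_get <- function() {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
}

global_seed_set <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  } else {
    assign(".Random.seed", state, envir = .GlobalEnv)
  }
}

# Run `fn()` with the stream's state installed, then capture the advanced
# state and restore the caller's global RNG state.
with_stream <- function(stream, fn) {
  old <- global_seed_get()
  assign(".Random.seed", stream$state, envir = .GlobalEnv)
  on.exit(global_seed_set(old), add = TRUE)
  out <- fn()
  stream$state <- get(".Random.seed", envir = .GlobalEnv)
  out
}

#' Draw from a labelled random stream
#'
#' Thin wrappers over the base distributions that draw from an
#' [rng_stream()] without touching the global RNG state.
#'
#' @param stream An `rng_stream`.
#' @param n Number of draws.
#' @param lambda,mean,sd,sdlog Distribution parameters.
#' @return Numeric vector of draws.
#' @export
rs_unif <- function(stream, n) with_stream(stream, function() runif(n))

#' @rdname rs_unif
#' @export
rs_pois <- function(stream, n, lambda) {
  with_stream(stream, function() rpois(n, lambda))
}

#' @rdname rs_unif
#' @export
rs_norm <- function(stream, n, mean = 0, sd = 1) {
  with_stream(stream, function() rnorm(n, mean, sd))
}

#' @rdname rs_unif
#' @description `rs_lnorm_unit` draws lognormal noise with unit mean
#'   (`exp(N(-sdlog^2/2, sdlog))`), the day-to-day noise law of supply
#'   entries.
#' @export
rs_lnorm_unit <- function(stream, n, sdlog) {
  if (sdlog == 0) return(rep(1, n))
  with_stream(stream, function() exp(rnorm(n, -sdlog^2 / 2, sdlog)))
}
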