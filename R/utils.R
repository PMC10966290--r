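# Internal helpers shared across modules.

#' Run code with a temporary RNG seed
#'
#' Restores (or removes) `.Random.seed` afterwards so callers see no RNG
#' side effects. With `seed = NULL` the expression runs against the current
#' RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage-specific seed from one root seed
#'
#' Named substreams keep every pipeline stage individually reproducible.
#' Result stays below 2^31 - 1.
#' @noRd
derive_seed <- function(seed, stage) {
  offsets <- c(
    cohort = 101L, curves = 211L, noise = 307L, extract = 401L,
    summary = 503L, association = 601L, pipeline = 701L
  )
  off <- offsets[[stage]]
  if (is.null(off)) stop("unknown seed stage: ", stage)
  as.integer((as.double(seed) * 48271 + off) %% 2147483647)
}

# First upward crossing of `level`, linearly interpolated between the
# bracketing samples. NA when never crossed.
cross_up <- function(time, value, level) {
  idx <- which(value >= level)
  if (length(idx) == 0L) return(NA_real_)
  i <- idx[1L]
  if (i == 1L) return(time[1L])
  t0 <- time[i - 1L]; t1 <- time[i]
  v0 <- value[i - 1L]; v1 <- value[i]
  if (v1 == v0) return(t1)
  t0 + (level - v0) / (v1 - v0) * (t1 - t0)
}

# First downward crossing of `level` (value falls to or below it).
cross_down <- function(time, value, level) {
  idx <- which(value <= level)
  if (length(idx) == 0L) return(NA_real_)
  i <- idx[1L]
  if (i == 1L) return(time[1L])
  t0 <- time[i - 1L]; t1 <- time[i]
  v0 <- value[i - 1L]; v1 <- value[i]
  if (v1 == v0) return(t1)
  t0 + (level - v0) / (v1 - v0) * (t1 - t0)
}

# Trapezoidal integral of y over t restricted to [t0, t1], interpolating
# the endpoints so partial segments are included exactly.
trapz_between <- function(time, value, t0, t1) {
  if (t1 <= t0) return(0)
  inside <- time > t0 & time < t1
  tt <- c(t0, time[inside], t1)
  vv <- c(
    stats::approx(time, value, xout = t0, rule = 2)$y,
    value[inside],
    stats::approx(time, value, xout = t1, rule = 2)$y
  )
  sum(diff(tt) * (utils::head(vv, -1) + utils::tail(vv, -1)) / 2)
}

# Tiny FNV-1a hash of a character scalar, hex string. Used only to tag
# pipeline outputs with a stable configuration fingerprint.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_finite <- function(x, name) {
  if (!all(is.finite(x))) stop("`", name, "` must be finite", call. = FALSE)
  invisible(x)
}
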