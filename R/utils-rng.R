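#' @keywords internal
"_PACKAGE"

# Seed plumbing. Every stochastic entry point takes an explicit integer seed;
# nested stages derive named child seeds so that results are independent of
# iteration order and of which stages are enabled.

#' Run code under a temporary RNG seed
#'
#' Evaluates `code` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so library functions never perturb user randomness.
#'
#' @param seed Integer seed, or `NULL` to run with the current RNG state.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

#' Derive a deterministic child seed from a master seed and a key
#'
#' Uses a 32-bit FNV-1a hash of the key string folded with the master seed,
#' reduced modulo a Mersenne prime so the result is a valid positive R
#' integer. Child streams for different keys are effectively independent,
#' and per-taxon / per-window results do not depend on iteration order.
#'
#' @param seed Integer master seed.
#' @param key Character scalar naming the stream (e.g. `"diff/genus/Blautia"`).
#' @return A positive integer seed below 2^31.
#' @export
#' @examples
#' derive_seed(1L, "windows")
derive_seed <- function(seed, key) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(key),
            length(key) == 1L)
  h <- 2166136261
  for (b in utf8ToInt(key)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2147483647
  }
  h <- (h + (as.double(seed) %% 2147483647) * 2654435761) %% 2147483629
  as.integer(h + 1)
}

# FNV-1a hash of a deparsed R object; used for config provenance stamps.
hash_object <- function(x) {
  txt <- paste(deparse(x, control = c("keepNA", "keepInteger")),
               collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# days per month used for all month<->day conversions
DAYS_PER_MONTH <- 30.44

months_to_days <- function(m) m * DAYS_PER_MONTH
days_to_months <- function(d) d / DAYS_PER_MONTH
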