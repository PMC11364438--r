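#' @useDynLib flytrauma, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rgamma rexp rnorm runif rbinom median quantile pchisq
#'   pnorm sd ks.test
#' @importFrom utils combn write.csv read.csv
NULL

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All generators route randomness through
# this so that (params, seed) -> bit-identical output without clobbering the
# user's RNG stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stop_invalid <- function(...) {
  stop(structure(class = c("flytrauma_invalid_input", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

stop_undefined_stat <- function(...) {
  stop(structure(class = c("flytrauma_undefined_statistic", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("`", name, "` must be a single finite number")
  }
  if (strict_lower && x <= lower) {
    stop_invalid("`", name, "` must be > ", lower)
  }
  if (!strict_lower && x < lower) {
    stop_invalid("`", name, "` must be >= ", lower)
  }
  if (x > upper) stop_invalid("`", name, "` must be <= ", upper)
  invisible(x)
}

# degrees wrapped into (-180, 180]
wrap_degrees <- function(theta) {
  out <- theta - 360 * floor((theta + 180) / 360)
  out[out == -180] <- 180
  out
}
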