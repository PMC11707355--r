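# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so that seeded generators do
#' not perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# index of the axis channel nearest a target wavenumber (ties -> lower index)
#' @noRd
nearest_channel <- function(wavenumber, target) which.min(abs(wavenumber - target))

# logical mask of channels inside a closed wavenumber interval
#' @noRd
in_range <- function(wavenumber, range) {
  wavenumber >= range[1] & wavenumber <= range[2]
}

#' @noRd
fmt_num <- function(x) sprintf("%.17g", x)
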