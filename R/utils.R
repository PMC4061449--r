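# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(...) stop(..., call. = FALSE)

#' Parse DNA masses with unit suffixes into picograms
#'
#' Accepts numeric values (assumed already in pg) or strings with an
#' fg/pg/ng/ug/µg suffix, e.g. `"21 ng"` or `"0.350pg"`.
#'
#' @param x Numeric vector (pg) or character vector with unit suffixes.
#' @return Numeric vector of masses in picograms.
#' @examples
#' parse_mass(c("21 ng", "0.350 pg", "10.9 ug"))
#' @export
parse_mass <- function(x) {
  if (is.numeric(x)) {
    return(as.numeric(x))
  }
  scale <- c(fg = 1e-3, pg = 1, ng = 1e3, ug = 1e6, "µg" = 1e6)
  x <- trimws(x)
  m <- regmatches(x, regexec("^([0-9.eE+-]+)\\s*([a-zµ]+)$", x))
  out <- vapply(seq_along(x), function(i) {
    parts <- m[[i]]
    if (length(parts) != 3L || !parts[3] %in% names(scale)) {
      stop_invalid("cannot parse mass: '", x[i],
                   "' (expected e.g. '21 ng', units fg/pg/ng/ug)")
    }
    as.numeric(parts[2]) * scale[[parts[3]]]
  }, numeric(1))
  out
}
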