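#' Round half away from zero
#'
#' Rounding used for all report files, matching the arithmetic of published
#' expression tables (e.g. 11.65 - 9.18 = 2.47): exact halves move away from
#' zero rather than to the even digit as in base [round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# stop() with the offending field named, for parameter validation
stop_param <- function(field, msg) {
  stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
}

check_flag <- function(cond, field, msg) {
  if (!isTRUE(cond)) stop_param(field, msg)
  invisible(TRUE)
}

# seeded RNG scope: run expr under a seed without clobbering the caller's stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# deterministic per-unit substream seeds derived from a master seed, kept
# below 2^31 so they are valid R integers
derive_seeds <- function(seed, n) {
  (as.numeric(seed) * 48271 + seq_len(n) * 9973) %% 2147483629
}
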