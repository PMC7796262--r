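# Internal helpers shared across modules.

AA_STANDARD <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_CHARGED <- c("D", "E", "K", "R")
DNA_BASES <- c("A", "C", "G", "T")

#' Round half away from zero
#'
#' Fixed-point rounding with ties going up, matching how printed tables are
#' conventionally rounded (base R's `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

# Evaluate `expr` under a fixed RNG seed without touching global RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# sample() without the length-1 surprise.
sample_one <- function(x) x[sample.int(length(x), 1L)]

sample_vec <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
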