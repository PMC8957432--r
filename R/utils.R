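# internal helpers shared across modules

logit <- function(p) log(p / (1 - p))
expit <- function(x) 1 / (1 + exp(-x))

#' Express a count as a percentage of a total
#'
#' Convenience used throughout the reports: `100 * n / total`, rounded to a
#' fixed number of decimals.
#'
#' @param n numerator count.
#' @param total denominator count; must be positive.
#' @param digits decimals to keep (default 2, the precision used in the reports).
#' @return numeric percentage.
#' @examples
#' pct(241, 1079)  # 22.34
#' @export
pct <- function(n, total, digits = 2) {
  if (any(!is.finite(total)) || any(total <= 0)) {
    stop("pct(): 'total' must be a positive finite number")
  }
  round(100 * n / total, digits)
}

# stop() with a consistent prefix; keeps error classes greppable in tests
abort2 <- function(class, msg) {
  stop(structure(
    class = c(class, "nodeconcord_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_flag01 <- function(x, what) {
  if (!all(x %in% c(0L, 1L, TRUE, FALSE))) {
    abort2("nodeconcord_format_error",
           sprintf("column '%s' must contain only 0/1 flags", what))
  }
  as.logical(x)
}

# run code with the global RNG state untouched
with_preserved_seed <- function(code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  force(code)
}

# deterministic 31-bit substream seed for (master seed, index); Lehmer-style
# multiplicative hashing so per-patient streams do not depend on patient count
substream_seed <- function(seed, index) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) * 48271 %% m
  as.integer((s + as.numeric(index) * 1299721) %% m)
}
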