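#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves moving away from zero
#' (so 0.05 -> 0.1), the convention used for the percentage columns of the
#' summary tables. Base [round()] rounds halves to even, which differs on
#' exact-half cases.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_away(c(6.14, 5.65, -5.65), 1)
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Trim outer whitespace and collapse internal runs to a single space.
normalize_label <- function(x) {
  gsub("[[:space:]]+", " ", trimws(as.character(x)))
}

# Deterministic 31-bit hash of a label, used to derive per-area seeds from a
# master seed so adding an area never perturbs another area's stream.
stable_hash <- function(label) {
  codes <- utf8ToInt(label)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
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
  set.seed(as.integer(seed %% 2147483647), kind = "Mersenne-Twister")
  expr
}

stop_hostpref <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "hostpref_error")))
}
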