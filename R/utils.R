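#' Round half away from zero
#'
#' Fixed-point rounding where .5 always rounds up, matching how clinical
#' tables conventionally present percentages (base R's `round()` rounds
#' half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @examples
#' round_half_up(100 * 142 / 528, 1) # 26.9
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # small epsilon guards against representation error (e.g. 2.675 * 100)
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# number of days in five years, the conventional OS landmark
DAYS_5YR <- 1826L

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("survscreen_config_error", "error")))
}

stop_onegroup <- function(msg, kind = c("one-group-logrank", "one-group-cox")) {
  kind <- match.arg(kind)
  stop(errorCondition(msg, class = c(
    paste0("survscreen_", gsub("-", "_", kind)),
    "survscreen_one_group_error", "error"
  ), category = kind))
}
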