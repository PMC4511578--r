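# Shared helpers: rounding/display conventions and error classes.

#' Round half-up
#'
#' Rounds to `digits` decimal places with ties going away from zero for
#' positive input (the convention the benchmark tables use), unlike base
#' [round()] which rounds half to even. A small epsilon guards against
#' binary representation artefacts (e.g. 80.357 * 100 stored as
#' 8035.6999...).
#'
#' @param x numeric vector (non-negative in all package uses).
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(80.357, 2) # 80.36
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Format a percentage the way the evaluation tables print it
#'
#' Two decimals, zero-padded to two integer digits, so that 4.2 renders as
#' "04.20" and 0 as "00.00".
#'
#' @param x numeric vector of percentages.
#' @return character vector.
#' @export
format_pct <- function(x) {
  sprintf("%05.2f", round_half_up(x, 2))
}

# thousands separator for count display (6449 -> "6,449")
format_count <- function(n) {
  formatC(n, format = "d", big.mark = ",")
}

stop_parse <- function(msg, line = NULL) {
  if (!is.null(line)) msg <- sprintf("line %d: %s", line, msg)
  abort(msg, class = "geniakb_parse_error")
}

stop_reference <- function(msg) abort(msg, class = "geniakb_reference_error")
stop_bounds <- function(msg) abort(msg, class = "geniakb_bounds_error")
stop_validation <- function(msg) abort(msg, class = "geniakb_validation_error")
stop_conversion <- function(msg) abort(msg, class = "geniakb_conversion_error")
stop_usage <- function(msg) abort(msg, class = "geniakb_usage_error")
stop_config <- function(msg) abort(msg, class = "geniakb_config_error")

# Run code with a private RNG stream seeded from `seed`, restoring the
# caller's .Random.seed afterwards, so generators are reproducible without
# clobbering user state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
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
  set.seed(seed)
  force(code)
}

#' Strip the coordination suffix from an argument role label
#'
#' Event arguments that share a role are distinguished by number suffixes
#' (Theme, Theme2, Theme3, ...). The suffix is surface syntax only; the
#' base role carries the semantics. Stripping is idempotent.
#'
#' @param role character vector of role labels.
#' @return character vector of base role labels.
#' @export
#' @examples
#' role_base(c("Theme", "Theme2", "Cause"))
role_base <- function(role) {
  sub("[0-9]+$", "", role)
}
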