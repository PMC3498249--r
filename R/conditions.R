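# Structured error conditions. Every user-facing failure carries a class so
# callers (and the CLI) can map error kinds to exit codes without string
# matching.

abort_bcri <- function(message, class) {
  stop(errorCondition(message, class = c(class, "bcri_error", "error")))
}

abort_format     <- function(msg) abort_bcri(msg, "bcri_format_error")
abort_validation <- function(msg) abort_bcri(msg, "bcri_validation_error")
abort_referential<- function(msg) abort_bcri(msg, "bcri_referential_error")
abort_lookup     <- function(msg) abort_bcri(msg, "bcri_lookup_error")
abort_shape      <- function(msg) abort_bcri(msg, "bcri_shape_error")
abort_undefined  <- function(msg) abort_bcri(msg, "bcri_undefined_input_error")
abort_design     <- function(msg) abort_bcri(msg, "bcri_design_error")
abort_domain     <- function(msg) abort_bcri(msg, "bcri_domain_error")
abort_config     <- function(msg) abort_bcri(msg, "bcri_config_error")
abort_usage      <- function(msg) abort_bcri(msg, "bcri_usage_error")

#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for displayed percentages and
#' similarities, as opposed to [base::round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded half-up to `digits` places.
#' @examples
#' round_half_up(0.5)   # 1, where round(0.5) is 0
#' round_half_up(47.435, 2)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
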