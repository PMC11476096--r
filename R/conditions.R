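# Classed conditions shared by all modules. Tests assert on these classes,
# so every user-facing failure funnels through one of the helpers below.

h2d_stop <- function(message, class) {
  stop(errorCondition(message, class = c(class, "hjorth2d_error")))
}

#' @noRd
input_error <- function(message) h2d_stop(message, "hjorth2d_input_error")

#' @noRd
dimension_error <- function(message) h2d_stop(message, "hjorth2d_dimension_error")

#' @noRd
degenerate_error <- function(message) h2d_stop(message, "hjorth2d_degenerate_error")

#' @noRd
config_error <- function(message) h2d_stop(message, "hjorth2d_config_error")
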