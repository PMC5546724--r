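#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
ggplot2::autoplot

#' @importFrom rlang .data
#' @importFrom dplyr bind_rows
NULL
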