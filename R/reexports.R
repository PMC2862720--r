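#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' @export
rlang::`%||%`
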