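#' Turn a fitted object into a tidy tibble
#'
#' @param x object to tidy.
#' @param ... passed to methods.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model summary
#'
#' @param x object to summarise.
#' @param ... passed to methods.
#' @return A one-row tibble.
#' @export
glance <- function(x, ...) UseMethod("glance")
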