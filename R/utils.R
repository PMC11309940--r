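#' @importFrom rlang .data %||%
#' @importFrom stats median t.test cor.test setNames runif rnorm rbinom
#' @importFrom utils head
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# fixed 12-significant-digit formatting so repeated runs write identical CSVs
num12 <- function(x) signif(x, 12)
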