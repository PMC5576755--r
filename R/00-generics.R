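#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor optimize qt rexp rlnorm rmultinom
#'   rnorm runif sd setNames var predict
#' @importFrom utils head read.delim write.table modifyList packageVersion
#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_hline
#'   geom_col facet_wrap labs theme_bw
NULL

#' @importFrom broom tidy glance
#' @export
broom::tidy

#' @export
broom::glance

#' @export
ggplot2::autoplot
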