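#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor lm median pchisq phyper rexp rnbinom rnorm rpois
#'   runif p.adjust quantile var sd setNames ave coef complete.cases pnorm
#' @importFrom utils read.delim write.table head
NULL

# round half away from zero at `digits` decimals (base round() is banker's)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# canonical unordered-pair key for edge identity
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

stop_argument <- function(...) {
  stop(..., call. = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
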