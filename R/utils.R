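`%||%` <- function(a, b) if (is.null(a)) b else a

pn_log <- function(...) message("[phyloniche] ", sprintf(...))

# log-sum-exp, numerically safe
lse <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Standard error of the mean
#' @param x numeric vector.
#' @return `sd(x)/sqrt(length(x))`; `NA` for fewer than two values.
#' @keywords internal
sem <- function(x) if (length(x) < 2) NA_real_ else stats::sd(x) / sqrt(length(x))
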