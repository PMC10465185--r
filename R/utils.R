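# Internal helpers: condition constructors and numeric utilities.

stopInput <- function(...) {
  stop(errorCondition(paste0(...), class = c("nkassay_input_error", "error")))
}

stopConfig <- function(...) {
  stop(errorCondition(paste0(...), class = c("nkassay_config_error", "error")))
}

stopSchema <- function(...) {
  stop(errorCondition(paste0(...), class = c("nkassay_schema_error", "error")))
}

stopDegenerate <- function(...) {
  stop(errorCondition(paste0(...), class = c("nkassay_degenerate_error", "error")))
}

stopUndefined <- function(...) {
  stop(errorCondition(paste0(...), class = c("nkassay_undefined_result", "error")))
}

## log10 fluorescence drop per cell division (dye halves every division)
LOG10_2 <- log10(2)

## row-wise log-sum-exp of a matrix, numerically stable
rowLogSumExp <- function(m) {
  mx <- do.call(pmax, c(as.data.frame(m), list(na.rm = FALSE)))
  mx + log(rowSums(exp(m - mx)))
}

clamp01 <- function(p) pmin(pmax(p, 0), 1)

## apply a logit-scale offset to a probability, passing 0/1 through unchanged
shiftLogit <- function(p, offset) {
  out <- p
  i <- p > 0 & p < 1
  out[i] <- stats::plogis(stats::qlogis(p[i]) + offset)
  out
}

isProportion <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0 & x <= 1)

## type-7 (linear interpolation) sample quantiles, the convention used for all
## posterior interval reporting
etQuantile <- function(x, probs) unname(stats::quantile(x, probs, type = 7, names = FALSE))
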