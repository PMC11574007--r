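`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

#' @importFrom stats coef lm quantile rnorm runif rbinom sd setNames var median
#'   predict qnorm pnorm pt vcov AIC cor.test p.adjust resid anova wilcox.test
#'   chisq.test simulate residuals na.omit as.formula logLik qt aggregate
NULL

# softplus on a scale: s * log(1 + exp(u/s)), numerically stable for large |u|
softplus <- function(u, s) {
  ifelse(u / s > 30, u, s * log1p(exp(pmin(u / s, 30))))
}

sigmoid <- function(u) 1 / (1 + exp(-u))

# sample() without the scalar-x surprise
sample_vec <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}
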