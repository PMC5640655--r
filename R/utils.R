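`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop_("`%s` must be a single number in [%s, %s]", name, lower, upper)
  x
}

#' @noRd
collapse_ids <- function(x) paste(x, collapse = ";")

# logit-scale helpers used by the noise model; betas are kept strictly
# inside (0, 1) before transforming so qlogis never returns +/-Inf
.BETA_EPS <- 1e-6

#' @noRd
squeeze01 <- function(x, eps = .BETA_EPS) pmin(pmax(x, eps), 1 - eps)
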