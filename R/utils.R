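# Internal argument-checking helpers.

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

# numeric vector with every element finite and inside [lower, upper]
.checkAngles <- function(x, name, lower = 0, upper = 180) {
  if (!is.numeric(x) || length(x) == 0L)
    .stopf("'%s' must be a non-empty numeric vector", name)
  if (any(!is.finite(x)))
    .stopf("'%s' contains non-finite values", name)
  if (any(x < lower) || any(x > upper))
    .stopf("'%s' must lie within [%g, %g] degrees", name, lower, upper)
  invisible(x)
}

.checkScalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .stopf("'%s' must be a finite numeric scalar", name)
  if (x < lower || x > upper || (strict_lower && x <= lower))
    .stopf("'%s' must lie in %s%g, %g]", name,
           if (strict_lower) "(" else "[", lower, upper)
  invisible(x)
}

.checkSquareImage <- function(image, name = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    .stopf("'%s' must be a numeric matrix", name)
  if (nrow(image) != ncol(image))
    .stopf("'%s' must be square (got %d x %d)", name, nrow(image), ncol(image))
  if (nrow(image) %% 4L != 0L)
    .stopf("'%s' size must be divisible by 4", name)
  if (any(!is.finite(image)))
    .stopf("'%s' contains non-finite values", name)
  invisible(image)
}

.deg2rad <- function(x) x * pi / 180
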