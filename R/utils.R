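#' @keywords internal
"_PACKAGE"

#' @importFrom stats median pnorm pt qnorm rnorm runif sd var complete.cases
#' @importFrom utils read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Euclidean norm of a vector (or rows of a matrix)
vnorm <- function(x) {
  if (is.matrix(x)) sqrt(rowSums(x^2)) else sqrt(sum(x^2))
}

# normalize vector(s) to unit length; zero vectors raise an error
unitize <- function(x) {
  if (is.matrix(x)) {
    n <- vnorm(x)
    if (any(n == 0)) stop("cannot normalize zero vector")
    x / n
  } else {
    n <- vnorm(x)
    if (n == 0) stop("cannot normalize zero vector")
    x / n
  }
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# angle in degrees between unit vectors a and b
angle_deg <- function(a, b) {
  d <- clamp(sum(a * b), -1, 1)
  acos(d) * 180 / pi
}

# FWHM of a Gaussian kernel <-> its standard deviation
fwhm_to_sigma <- function(fwhm) fwhm / sqrt(8 * log(2))

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  invisible(x)
}
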