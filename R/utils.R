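# shared numeric helpers

#' Bilinear interpolation at fractional matrix indices
#'
#' Interior pixels are interpolated from the four surrounding pixel centers;
#' fractional indices outside `[1, nrow]` x `[1, ncol]` return `NA`.
#'
#' @param m numeric matrix
#' @param i,j fractional row/column indices (vectors, recycled to common length)
#' @return numeric vector of interpolated values
#' @keywords internal
bilinear_at <- function(m, i, j) {
  nr <- nrow(m); nc <- ncol(m)
  n <- max(length(i), length(j))
  i <- rep_len(i, n); j <- rep_len(j, n)
  ok <- !is.na(i) & !is.na(j) & i >= 1 & i <= nr & j >= 1 & j <= nc
  out <- rep(NA_real_, n)
  if (!any(ok)) return(out)
  i <- i[ok]; j <- j[ok]
  i0 <- pmin(pmax(floor(i), 1), max(nr - 1L, 1L))
  j0 <- pmin(pmax(floor(j), 1), max(nc - 1L, 1L))
  fi <- i - i0; fj <- j - j0
  i1 <- pmin(i0 + 1L, nr); j1 <- pmin(j0 + 1L, nc)
  v <- (1 - fi) * (1 - fj) * m[cbind(i0, j0)] +
       (1 - fi) * fj       * m[cbind(i0, j1)] +
       fi       * (1 - fj) * m[cbind(i1, j0)] +
       fi       * fj       * m[cbind(i1, j1)]
  out[ok] <- v
  out
}

#' Robust maximum of a dose distribution
#'
#' Mean of the top `top_fraction` of values (at least one value), which
#' resists single-pixel noise spikes when rescaling a measured film plane to
#' a reference maximum. With `exact = TRUE` the plain maximum is returned.
#'
#' @param x numeric vector or matrix
#' @param top_fraction fraction of the largest values to average (default 0.005)
#' @param exact use the exact maximum instead of the trimmed mean
#' @return scalar
#' @keywords internal
robust_max <- function(x, top_fraction = 0.005, exact = FALSE) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (!length(x)) stop("robust_max: no finite values")
  if (exact) return(max(x))
  k <- max(1L, ceiling(length(x) * top_fraction))
  mean(sort(x, decreasing = TRUE)[seq_len(k)])
}

# error function (and inverse) in terms of the normal CDF
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
erfinv <- function(y) stats::qnorm((y + 1) / 2) / sqrt(2)

`%||%` <- function(a, b) if (is.null(a)) b else a
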