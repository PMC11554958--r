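#' FFT-based 2-D convolution and focal statistics
#'
#' The foraging-kernel model and the focal natural-cover statistic both
#' reduce to normalized moving-window sums over the grid, computed here with
#' zero-padded FFT convolution. Zero padding together with an explicit
#' denominator (the kernel sum over in-extent cells) gives the exact
#' "denominators use only in-extent cells" semantics of a per-cell weighted
#' mean.
#'
#' @name convolve2d
#' @keywords internal
NULL

next_fast <- function(n) stats::nextn(n, c(2, 3, 5))

#' 2-D "same" convolution with zero padding
#'
#' @param x numeric matrix.
#' @param kernel odd-dimensioned numeric matrix, centered.
#' @param kernel_fft optional precomputed padded kernel FFT (from
#'   [precompute_kernel_fft()]) to amortize repeated convolutions.
#' @return matrix of `dim(x)`: `out[i,j] = sum_k x[i+di, j+dj] * kernel[k]`
#'   with out-of-extent cells treated as zero.
#' @export
conv2_same <- function(x, kernel, kernel_fft = NULL) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  stopifnot(kr %% 2 == 1, kc %% 2 == 1)
  nr <- nrow(x); nc <- ncol(x)
  pr <- next_fast(nr + kr - 1); pc <- next_fast(nc + kc - 1)
  X <- matrix(0, pr, pc); X[1:nr, 1:nc] <- x
  if (is.null(kernel_fft)) kernel_fft <- precompute_kernel_fft(kernel, pr, pc)
  out <- Re(stats::fft(stats::fft(X) * kernel_fft$fft, inverse = TRUE)) / (pr * pc)
  out[1:nr, 1:nc]
}

#' Precompute the padded, center-shifted FFT of a kernel
#'
#' @param kernel odd-dimensioned kernel matrix.
#' @param pr,pc padded dimensions (must satisfy `pr >= nrow(x)+nrow(kernel)-1`
#'   for the rasters it will be used with).
#' @return list with the padded FFT and the padding dimensions.
#' @export
precompute_kernel_fft <- function(kernel, pr, pc) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  K <- matrix(0, pr, pc)
  K[1:kr, 1:kc] <- kernel
  # shift so the kernel center sits at (1,1): circular convolution then
  # aligns output cell (i,j) with input cell (i,j)
  cr <- (kr - 1) / 2; cc <- (kc - 1) / 2
  K <- K[c((cr + 1):pr, seq_len(cr)), c((cc + 1):pc, seq_len(cc))]
  list(fft = stats::fft(K), pr = pr, pc = pc)
}

#' Kernel-weighted focal mean
#'
#' `out(x) = sum_m v(m) w(d(x,m)) / sum_m w(d(x,m))` with both sums running
#' over in-extent cells only.
#'
#' @param v value raster (finite).
#' @param kernel weight kernel (odd dimensions).
#' @param denom optional precomputed denominator raster (the convolution of
#'   an all-ones raster with the same kernel), reused across calls.
#' @return matrix of weighted means.
#' @export
focal_weighted_mean <- function(v, kernel, denom = NULL) {
  stopifnot(all(is.finite(v)))
  num <- conv2_same(v, kernel)
  if (is.null(denom)) denom <- conv2_same(matrix(1, nrow(v), ncol(v)), kernel)
  if (any(denom <= 0)) stop("empty kernel support inside the extent")
  num / denom
}

#' Circular (disc) kernel of ones
#'
#' Cell (i, j) is included when its center lies within `radius_m` of the
#' center cell's center.
#'
#' @param radius_m window radius in meters.
#' @param resolution_m cell size in meters.
#' @return 0/1 matrix with odd dimensions.
#' @export
disc_kernel <- function(radius_m, resolution_m) {
  r <- floor(radius_m / resolution_m)
  off <- (-r):r
  d <- sqrt(outer(off^2, off^2, "+")) * resolution_m
  (d <= radius_m) * 1
}
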