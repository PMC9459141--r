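# Single-level stationary (undecimated) separable 3D wavelet transform with
# periodic boundary extension. Undecimated so every sub-band keeps the input
# extents and the original ROI mask applies unchanged.

# Standard orthonormal decomposition filter banks. `lo` sums to sqrt(2),
# `hi` sums to 0.
wavelet_filters <- function(family = c("coif1", "haar")) {
  family <- match.arg(family)
  lo <- switch(family,
    coif1 = c(-0.015655728135465, -0.072732619512854, 0.384864846864203,
              0.852572020212255, 0.337897662457809, -0.072732619512854),
    haar = c(1, 1) / sqrt(2)
  )
  n <- length(lo)
  # quadrature mirror: hi[k] = (-1)^k * lo[n - k + 1]
  hi <- rev(lo) * (-1)^(seq_len(n) - 1)
  list(lo = lo, hi = hi, length = n)
}

# Circular correlation along the first dimension of a matrix, expressed as a
# circulant matrix product: y[n] = sum_k h[k] * x[(n + k - 2) mod N + 1].
circulant_filter_matrix <- function(n, h) {
  mat <- matrix(0, n, n)
  for (k in seq_along(h)) {
    cols <- ((seq_len(n) + k - 2L) %% n) + 1L
    mat[cbind(seq_len(n), cols)] <- mat[cbind(seq_len(n), cols)] + h[k]
  }
  mat
}

apply_filter_axis <- function(vol, h, axis) {
  d <- dim(vol)
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(vol, perm)
  dp <- dim(x)
  y <- circulant_filter_matrix(dp[1], h) %*% matrix(x, nrow = dp[1])
  y <- array(y, dp)
  aperm(y, order(perm))
}

#' Stationary 3D wavelet decomposition
#'
#' Computes the single-level undecimated separable 3D wavelet transform of a
#' grayscale volume with periodic boundary extension. Each of the 8 sub-bands
#' has the same extents as the input, so a segmentation mask defined on the
#' original grid applies directly. Sub-band keys are three letters, one per
#' axis in order: letter `i` names the filter applied along axis `i`
#' (`L` = low-pass, `H` = high-pass), e.g. `LHL` applies the low-pass filter
#' along axes 1 and 3 and the high-pass filter along axis 2.
#'
#' @param volume 3D numeric array.
#' @param family wavelet family: `"coif1"` (Coiflet-1, default) or `"haar"`.
#' @return Named list of 8 arrays keyed `LLL`, `LLH`, `LHL`, `LHH`, `HLL`,
#'   `HLH`, `HHL`, `HHH`, each with the extents of `volume`.
#' @export
#'
#' @examples
#' sb <- wavelet_decompose(array(rnorm(8^3), c(8, 8, 8)))
#' names(sb)
wavelet_decompose <- function(volume, family = c("coif1", "haar")) {
  if (!is.array(volume) || length(dim(volume)) != 3L) {
    abort("`volume` must be a 3D array.")
  }
  filt <- wavelet_filters(match.arg(family))
  d <- dim(volume)
  short <- which(d < filt$length)
  if (length(short)) {
    abort(sprintf("axis %d (extent %d) is shorter than the wavelet filter length %d.",
                  short[1], d[short[1]], filt$length))
  }
  # one pass per axis, branching into low/high
  pass1 <- list(L = apply_filter_axis(volume, filt$lo, 1L),
                H = apply_filter_axis(volume, filt$hi, 1L))
  out <- list()
  for (l1 in c("L", "H")) {
    pass2 <- list(L = apply_filter_axis(pass1[[l1]], filt$lo, 2L),
                  H = apply_filter_axis(pass1[[l1]], filt$hi, 2L))
    for (l2 in c("L", "H")) {
      for (l3 in c("L", "H")) {
        h3 <- if (l3 == "L") filt$lo else filt$hi
        out[[paste0(l1, l2, l3)]] <- apply_filter_axis(pass2[[l2]], h3, 3L)
      }
    }
  }
  out[c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
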