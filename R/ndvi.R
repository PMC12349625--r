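#' Normalized Difference Vegetation Index
#'
#' Elementwise `(NIR - RED) / (NIR + RED)` over two co-registered reflectance
#' arrays. Elements where both bands are zero (no signal) are masked `NA`.
#' Values lie in `[-1, 1]`; the index is invariant to a common positive
#' scaling of both bands.
#'
#' @param nir,red Numeric arrays of identical shape with non-negative
#'   reflectances. `NA` elements propagate.
#' @return Numeric array of the same shape; `NA` marks invalid elements.
#' @examples
#' compute_ndvi(0.9, 0.1)  # 0.8
#' @export
compute_ndvi <- function(nir, red) {
  if (!identical(dim(nir), dim(red)) || length(nir) != length(red))
    stop("nir and red must have identical shape")
  if (any(nir < 0, na.rm = TRUE) || any(red < 0, na.rm = TRUE))
    stop("reflectances must be non-negative")
  s <- nir + red
  out <- (nir - red) / s
  out[!is.na(s) & s == 0] <- NA_real_
  out
}

#' Mean NDVI over valid elements
#'
#' @param values Numeric array of NDVI values (`NA` = invalid/masked).
#' @return Arithmetic mean of the valid elements.
#' @export
mean_ndvi <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) == 0L) stop("no valid NDVI values")
  mean(v)
}
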