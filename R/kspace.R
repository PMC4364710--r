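# Centered unitary 2-D Fourier transforms between image and k-space.

# Swap the two half-planes in both dimensions. For even N the forward and
# inverse shifts coincide, so one helper serves both directions.
.fftshift2 <- function(m) {
  n <- nrow(m)
  i <- c((n / 2 + 1):n, 1:(n / 2))
  m[i, i, drop = FALSE]
}

#' Phase-encode index vector of a grid
#'
#' The ky (and kx) index convention used throughout: indices run over
#' \[-N/2, N/2 - 1\] along the matrix rows, with DC (ky = 0) at row
#' N/2 + 1.
#'
#' @param n grid size (divisible by 4).
#' @return Integer vector of length `n`.
#' @export
kyIndex <- function(n) {
  if (length(n) != 1L || n %% 4L != 0L)
    .stopf("'n' must be a single integer divisible by 4")
  seq.int(-n / 2, n / 2 - 1)
}

#' Forward centered unitary 2-D Fourier transform
#'
#' Transforms a real image to its centered k-space representation. The
#' transform is unitary (scaled by 1/N), so Parseval's identity holds
#' exactly: the total squared magnitude in k-space equals that of the image.
#'
#' @param image square numeric matrix with size divisible by 4. Rows are the
#'   phase-encode direction.
#' @return A [KSpaceGrid-class].
#' @seealso [reconstructImage()]
#' @export
forwardKspace <- function(image) {
  .checkSquareImage(image)
  n <- nrow(image)
  k <- .fftshift2(stats::fft(.fftshift2(image))) / n
  new("KSpaceGrid", data = k)
}

#' Magnitude image from centered k-space
#'
#' Inverse of [forwardKspace()]: applies the centered unitary inverse
#' transform and returns the pixelwise magnitude (the standard magnitude
#' reconstruction of MR imaging). Also accepts a [KSpaceAssembly-class],
#' reconstructing its combined grid.
#'
#' @param k a [KSpaceGrid-class] or [KSpaceAssembly-class].
#' @return A non-negative numeric matrix.
#' @export
setGeneric("reconstructImage", function(k) standardGeneric("reconstructImage"))

#' @rdname reconstructImage
setMethod("reconstructImage", "KSpaceGrid", function(k) {
  validObject(k)
  n <- nrow(k@data)
  Mod(.fftshift2(stats::fft(.fftshift2(k@data), inverse = TRUE)) / n)
})

#' @rdname reconstructImage
setMethod("reconstructImage", "KSpaceAssembly", function(k) {
  reconstructImage(k@kspace)
})

#' Export a k-space grid as two plain-text matrices
#'
#' Debug helper: writes the real and imaginary parts as whitespace-separated
#' text grids.
#'
#' @param k a [KSpaceGrid-class].
#' @param real_path,imag_path output file paths.
#' @export
writeKspaceText <- function(k, real_path, imag_path) {
  stopifnot(is(k, "KSpaceGrid"))
  utils::write.table(Re(k@data), real_path, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(Im(k@data), imag_path, row.names = FALSE,
                     col.names = FALSE)
  invisible(c(real_path, imag_path))
}
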