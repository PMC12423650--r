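# Discrete differential operators on periodic L x L lattices.
#
# Convention used throughout the package: a field is a numeric matrix whose
# FIRST index is x and SECOND index is y, with unit grid spacing and periodic
# wrap in both directions.

#' Periodic shift of a lattice field
#'
#' Returns the matrix `s` with `s[i, j] = m[i + dx, j + dy]`, indices wrapped
#' periodically.
#'
#' @param m numeric matrix.
#' @param dx,dy integer shifts along the first (x) and second (y) index.
#' @return shifted matrix of the same dimension.
#' @keywords internal
shift_field <- function(m, dx = 0L, dy = 0L) {
  n <- nrow(m)
  p <- ncol(m)
  if (dx != 0L) m <- m[((seq_len(n) - 1L + dx) %% n) + 1L, , drop = FALSE]
  if (dy != 0L) m <- m[, ((seq_len(p) - 1L + dy) %% p) + 1L, drop = FALSE]
  m
}

#' Second-order central difference along x
#' @param m numeric matrix (x is the first index).
#' @return matrix of the same dimension.
#' @keywords internal
ddx_central <- function(m) (shift_field(m, 1L, 0L) - shift_field(m, -1L, 0L)) / 2

#' Second-order central difference along y
#' @param m numeric matrix (y is the second index).
#' @return matrix of the same dimension.
#' @keywords internal
ddy_central <- function(m) (shift_field(m, 0L, 1L) - shift_field(m, 0L, -1L)) / 2

#' Five-point periodic Laplacian
#' @param m numeric matrix.
#' @return matrix of the same dimension.
#' @keywords internal
laplacian5 <- function(m) {
  shift_field(m, 1L, 0L) + shift_field(m, -1L, 0L) +
    shift_field(m, 0L, 1L) + shift_field(m, 0L, -1L) - 4 * m
}

# First-order upwind derivative of m for advection velocity component w along
# the given axis: backward difference where w > 0, forward difference where
# w < 0 (the stable choice for the hyperbolic self-advection term).
upwind_deriv <- function(m, w, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (axis == "x") {
    bwd <- m - shift_field(m, -1L, 0L)
    fwd <- shift_field(m, 1L, 0L) - m
  } else {
    bwd <- m - shift_field(m, 0L, -1L)
    fwd <- shift_field(m, 0L, 1L) - m
  }
  ifelse(w > 0, bwd, fwd)
}

# Spectral (exact trigonometric) derivative, used by oracles and fixtures,
# never by the solver itself. Physical wavenumbers assume box length nrow(m)
# unless box is given.
spectral_deriv <- function(m, axis = c("x", "y"), box = nrow(m)) {
  axis <- match.arg(axis)
  n <- nrow(m)
  k <- fft_wavenumbers(n, box)
  mh <- stats::fft(m)
  if (axis == "x") mh <- mh * (1i * k) else mh <- mh * rep(1i * k, each = n)
  out <- stats::fft(mh, inverse = TRUE) / length(m)
  if (is.complex(m)) out else Re(out)
}

# Wavenumbers 2*pi*j/box in FFT order for an n-point grid spanning box.
fft_wavenumbers <- function(n, box = n) {
  j <- c(0:(floor(n / 2)), (-(ceiling(n / 2) - 1)):(-1))
  2 * pi * j[seq_len(n)] / box
}
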