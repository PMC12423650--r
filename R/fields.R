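#' Nematic order-parameter field
#'
#' In two dimensions the symmetric traceless order tensor
#' `Q_ij = 2 q (n_i n_j - delta_ij / 2)` has two independent components;
#' the field is stored as the pair of matrices `(Qxx, Qxy)` with
#' `Qyy = -Qxx` and `Qyx = Qxy` implied, so tracelessness and symmetry hold
#' exactly by representation.
#'
#' @param Qxx,Qxy numeric matrices of identical dimension (first index x,
#'   second index y, periodic).
#' @return object of class `"an_qfield"`.
#' @seealso [decompose_q()] for the (magnitude, director angle) view.
#' @export
nematic_field <- function(Qxx, Qxy) {
  stopifnot(is.matrix(Qxx), is.matrix(Qxy), all(dim(Qxx) == dim(Qxy)),
            all(is.finite(Qxx)), all(is.finite(Qxy)))
  structure(list(Qxx = Qxx, Qxy = Qxy), class = "an_qfield")
}

#' @export
print.an_qfield <- function(x, ...) {
  d <- decompose_q(x)
  cat(sprintf("Nematic field %d x %d: order magnitude q in [%.4f, %.4f], mean %.4f\n",
              nrow(x$Qxx), ncol(x$Qxx), min(d$q), max(d$q), mean(d$q)))
  invisible(x)
}

#' Decompose a Q-tensor field into order magnitude and director angle
#'
#' Inverts `Qxx = q cos(2 theta)`, `Qxy = q sin(2 theta)`. The director
#' angle is defined modulo pi; sites with `q = 0` get `theta = 0` by
#' convention.
#'
#' @param Q an [nematic_field()] object.
#' @return list with matrices `q` (order magnitude, >= 0), `theta` (director
#'   angle in (-pi/2, pi/2]), and the director components `nx`, `ny`.
#' @examples
#' Q <- nematic_field(matrix(1, 4, 4), matrix(0, 4, 4))
#' d <- decompose_q(Q)
#' d$q[1, 1]; d$theta[1, 1]      # 1 and 0: aligned along x
#' @export
decompose_q <- function(Q) {
  q <- sqrt(Q$Qxx^2 + Q$Qxy^2)
  theta <- 0.5 * atan2(Q$Qxy, Q$Qxx)
  list(q = q, theta = theta, nx = cos(theta), ny = sin(theta))
}

#' Polarity field
#'
#' Per-site unit vector equal to plus or minus the local director; the sign
#' is chosen by [assign_polarity()] as the direction closest to the flow.
#'
#' @param px,py numeric matrices; `(px, py)` must be unit vectors.
#' @return object of class `"an_pfield"`.
#' @export
polarity_field <- function(px, py) {
  stopifnot(is.matrix(px), is.matrix(py), all(dim(px) == dim(py)))
  nrm <- px^2 + py^2
  stopifnot(max(abs(nrm - 1)) < 1e-8)
  structure(list(px = px, py = py), class = "an_pfield")
}

#' Aligned or random initial order-parameter field
#'
#' Builds the initial condition used by [run_simulation()]: a uniform
#' director along x at magnitude `init_q` plus uniform random noise of
#' amplitude `noise_amp` on both components (and optionally one seeded
#' Fourier mode on Qxy), or an isotropic random field.
#'
#' @param config an [simulation_config()] object.
#' @return an [nematic_field()].
#' @export
initial_q_field <- function(config) {
  L <- config$params$L
  set.seed(config$params$seed)
  if (config$init == "aligned") {
    Qxx <- matrix(config$init_q, L, L)
    Qxy <- matrix(0, L, L)
  } else {
    th <- matrix(stats::runif(L * L, -pi / 2, pi / 2), L, L)
    Qxx <- config$noise_amp * cos(2 * th)
    Qxy <- config$noise_amp * sin(2 * th)
  }
  if (config$noise_amp > 0 && config$init == "aligned") {
    Qxx <- Qxx + matrix(stats::runif(L * L, -1, 1) * config$noise_amp, L, L)
    Qxy <- Qxy + matrix(stats::runif(L * L, -1, 1) * config$noise_amp, L, L)
  }
  if (!is.null(config$perturb_mode)) {
    nm <- config$perturb_mode
    x <- matrix((seq_len(L) - 1), L, L)
    y <- t(x)
    Qxy <- Qxy + config$perturb_amp * cos(2 * pi * (nm[1] * x + nm[2] * y) / L)
  }
  nematic_field(Qxx, Qxy)
}
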