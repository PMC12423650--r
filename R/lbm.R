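# D2Q9 lattice Boltzmann solver (BGK collision, Guo forcing, periodic
# streaming) for the weakly compressible Navier-Stokes equation driven by
# the divergence of the passive + active stress.

# D2Q9 velocity set and weights (rest, axis, diagonal).
d2q9 <- list(
  cx = c(0, 1, 0, -1, 0, 1, -1, -1, 1),
  cy = c(0, 0, 1, 0, -1, 1, 1, -1, -1),
  w  = c(4 / 9, rep(1 / 9, 4), rep(1 / 36, 4))
)

#' Second-order D2Q9 equilibrium distributions
#'
#' `f_i^eq = w_i rho (1 + 3 c_i.u + 9/2 (c_i.u)^2 - 3/2 u^2)` with
#' `c_s^2 = 1/3`. The moments reproduce `rho`, `rho u` and the ideal-gas
#' momentum flux `rho c_s^2 delta + rho u u` exactly.
#'
#' @param rho density matrix.
#' @param vx,vy velocity matrices (`|v|` must stay well below `c_s`).
#' @return `L x L x 9` array of equilibrium distributions.
#' @export
lb_equilibrium <- function(rho, vx, vy) {
  L1 <- nrow(rho); L2 <- ncol(rho)
  feq <- array(0, c(L1, L2, 9))
  u2 <- vx^2 + vy^2
  for (k in 1:9) {
    cu <- d2q9$cx[k] * vx + d2q9$cy[k] * vy
    feq[, , k] <- d2q9$w[k] * rho * (1 + 3 * cu + 4.5 * cu^2 - 1.5 * u2)
  }
  feq
}

#' Flow state
#'
#' Container for the nine distribution fields plus the derived density and
#' velocity (velocity includes the half-force correction of the forcing
#' scheme) and the body force applied at the most recent step.
#'
#' @param f `L x L x 9` distribution array.
#' @param Fx,Fy body-force matrices (defaults: zero).
#' @return object of class `"an_flow"` with elements `f`, `rho`, `vx`, `vy`,
#'   `Fx`, `Fy`.
#' @export
flow_state <- function(f, Fx = NULL, Fy = NULL) {
  stopifnot(length(dim(f)) == 3, dim(f)[3] == 9)
  if (is.null(Fx)) Fx <- matrix(0, dim(f)[1], dim(f)[2])
  if (is.null(Fy)) Fy <- matrix(0, dim(f)[1], dim(f)[2])
  st <- list(f = f, Fx = Fx, Fy = Fy)
  mom <- lb_moments(f, Fx, Fy)
  st$rho <- mom$rho; st$vx <- mom$vx; st$vy <- mom$vy
  if (any(st$rho <= 0)) stop("non-positive density in flow state")
  class(st) <- "an_flow"
  st
}

#' @export
print.an_flow <- function(x, ...) {
  cat(sprintf("D2Q9 flow state %d x %d: mean rho %.4f, max |v| %.3e\n",
              nrow(x$rho), ncol(x$rho), mean(x$rho),
              max(sqrt(x$vx^2 + x$vy^2))))
  invisible(x)
}

# Hydrodynamic moments with the half-force velocity shift.
lb_moments <- function(f, Fx, Fy) {
  rho <- f[, , 1]
  mx <- matrix(0, nrow(rho), ncol(rho)); my <- mx
  for (k in 2:9) {
    rho <- rho + f[, , k]
    mx <- mx + d2q9$cx[k] * f[, , k]
    my <- my + d2q9$cy[k] * f[, , k]
  }
  list(rho = rho, vx = (mx + 0.5 * Fx) / rho, vy = (my + 0.5 * Fy) / rho)
}

#' Quiescent flow state at uniform density
#'
#' @param L lattice side length.
#' @param rho0 uniform density.
#' @return an [flow_state()] at rest.
#' @export
lb_init <- function(L, rho0 = 40) {
  flow_state(lb_equilibrium(matrix(rho0, L, L), matrix(0, L, L),
                            matrix(0, L, L)))
}

#' Body force from the stress divergence
#'
#' `F_i = d_j sigma_ij` by central differences; zero for uniform stress.
#'
#' @param sigma stress as returned by [assemble_stress()].
#' @return list of matrices `Fx`, `Fy`.
#' @export
force_from_stress <- function(sigma) {
  list(Fx = ddx_central(sigma$sxx) + ddy_central(sigma$sxy),
       Fy = ddx_central(sigma$syx) + ddy_central(sigma$syy))
}

#' One lattice Boltzmann step (BGK + Guo forcing + periodic streaming)
#'
#' Collides with single relaxation time `tau = 3 eta / rho + 1/2`
#' (kinematic viscosity `c_s^2 (tau - 1/2) = eta / rho`), applies the
#' second-order forcing source with the half-step velocity shift, and
#' streams periodically.
#'
#' @param state an [flow_state()].
#' @param Fx,Fy body-force matrices to apply during this step.
#' @param params an [model_params()] (only `rho` and `eta` are used).
#' @return the new [flow_state()] (its `vx`, `vy` include the half-force
#'   correction with the applied force).
#' @export
lbm_step <- function(state, Fx, Fy, params) {
  tau <- lb_tau(params)
  f <- state$f
  mom <- lb_moments(f, Fx, Fy)
  rho <- mom$rho; ux <- mom$vx; uy <- mom$vy
  if (any(!is.finite(rho)) || any(rho <= 0)) {
    stop("lattice Boltzmann blow-up: non-finite or non-positive density")
  }
  feq <- lb_equilibrium(rho, ux, uy)
  pref <- 1 - 1 / (2 * tau)
  u2F <- ux * Fx + uy * Fy
  fpost <- f
  for (k in 1:9) {
    cu <- d2q9$cx[k] * ux + d2q9$cy[k] * uy
    cF <- d2q9$cx[k] * Fx + d2q9$cy[k] * Fy
    src <- pref * d2q9$w[k] * (3 * (cF - u2F) + 9 * cu * cF)
    fpost[, , k] <- f[, , k] - (f[, , k] - feq[, , k]) / tau + src
  }
  fnew <- fpost
  for (k in 2:9) {
    fnew[, , k] <- shift_field(fpost[, , k], -d2q9$cx[k], -d2q9$cy[k])
  }
  flow_state(fnew, Fx, Fy)
}
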