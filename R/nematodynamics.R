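# Beris-Edwards nemato-hydrodynamics: free energy, molecular field,
# co-rotation, polarity rule, stresses, and the explicit order-parameter
# update. All operators act on periodic matrices (x = first index) and use
# the same stencils as the compiled driver: 2nd-order central differences
# everywhere except 1st-order upwind for the self-advection term.

#' Elastic free-energy density
#'
#' `E = (K/2) (d_k Q_ij)^2`, summed over all four tensor components (the
#' implied `Qyy = -Qxx`, `Qyx = Qxy` double the two stored ones), using the
#' solver's central-difference gradient.
#'
#' @param Q an [nematic_field()].
#' @param K Frank elastic constant.
#' @return matrix of non-negative energy densities.
#' @export
elastic_energy_density <- function(Q, K) {
  K * (ddx_central(Q$Qxx)^2 + ddy_central(Q$Qxx)^2 +
       ddx_central(Q$Qxy)^2 + ddy_central(Q$Qxy)^2)
}

#' Molecular field
#'
#' Functional derivative of the free energy
#' `F = int [ (K/2)(d_k Q_ij)^2 + A (1 - Q_ij Q_ji)^2 ]`:
#' `H_ij = K lap(Q_ij) + 4 A (1 - Q_kl Q_lk) Q_ij`, which is symmetric and
#' traceless by representation. The bulk term vanishes at
#' `Q_kl Q_lk = 2 (Qxx^2 + Qxy^2) = 1`, i.e. order magnitude `1/sqrt(2)`.
#'
#' @param Q an [nematic_field()].
#' @param K Frank elastic constant.
#' @param A bulk free-energy coefficient.
#' @return list with matrices `Hxx`, `Hxy`.
#' @export
molecular_field <- function(Q, K, A) {
  trQ2 <- 2 * (Q$Qxx^2 + Q$Qxy^2)
  bulk <- 4 * A * (1 - trQ2)
  list(Hxx = K * laplacian5(Q$Qxx) + bulk * Q$Qxx,
       Hxy = K * laplacian5(Q$Qxy) + bulk * Q$Qxy)
}

# Velocity-gradient ingredients shared by corotation_term() and the driver:
# strain rate E_ij = (d_i v_j + d_j v_i)/2 and vorticity tensor
# W_ij = (d_j v_i - d_i v_j)/2 (so W_xy = -omega/2 with
# omega = d_x v_y - d_y v_x).
velocity_gradients <- function(vx, vy) {
  dxvx <- ddx_central(vx); dyvx <- ddy_central(vx)
  dxvy <- ddx_central(vy); dyvy <- ddy_central(vy)
  list(Exx = dxvx, Eyy = dyvy, Exy = 0.5 * (dxvy + dyvx),
       Wxy = 0.5 * (dyvx - dxvy),
       trQgv = function(Qxx, Qxy) Qxx * (dxvx - dyvy) + Qxy * (dxvy + dyvx))
}

#' Co-rotation (flow-coupling) term of the order-parameter equation
#'
#' Generalized co-rotational advection
#' `S = (lam E + W)(Q + I/2) + (Q + I/2)(lam E - W) - 2 lam (Q + I/2) (Q_kl d_k v_l)`
#' with strain rate `E` and vorticity tensor `W` built from the same
#' central-difference gradient as the solver. The result is symmetric
#' exactly; the trace (of order `lam tr E`, nonzero only through the weak
#' compressibility of the flow solver) is projected out by the (Qxx, Qxy)
#' representation.
#'
#' @param Q an [nematic_field()].
#' @param vx,vy velocity component matrices.
#' @param lam flow-alignment coefficient.
#' @return list with matrices `Sxx`, `Sxy` (traceless symmetric projection).
#' @export
corotation_term <- function(Q, vx, vy, lam) {
  g <- velocity_gradients(vx, vy)
  Qhxx <- Q$Qxx + 0.5
  Qhyy <- 0.5 - Q$Qxx
  Qxy <- Q$Qxy
  # M = lam E + W, N = lam E - W (2x2, W antisymmetric)
  Mxx <- lam * g$Exx; Myy <- lam * g$Eyy
  Mxy <- lam * g$Exy + g$Wxy
  Myx <- lam * g$Exy - g$Wxy
  # S_raw = M Qh + Qh N  with N = M^T
  Sxx <- Mxx * Qhxx + Mxy * Qxy + Qhxx * Mxx + Qxy * Mxy
  Syy <- Myx * Qxy + Myy * Qhyy + Qxy * Myx + Qhyy * Myy
  Sxy <- Mxx * Qxy + Mxy * Qhyy + Qhxx * Myx + Qxy * Myy
  Syx <- Myx * Qhxx + Myy * Qxy + Qxy * Mxx + Qhyy * Mxy
  tr <- g$trQgv(Q$Qxx, Qxy)
  Sxx <- Sxx - 2 * lam * Qhxx * tr
  Syy <- Syy - 2 * lam * Qhyy * tr
  Sxy <- Sxy - 2 * lam * Qxy * tr
  Syx <- Syx - 2 * lam * Qxy * tr
  list(Sxx = 0.5 * (Sxx - Syy), Sxy = 0.5 * (Sxy + Syx))
}

#' Assign polarity by the flow-alignment rule
#'
#' The polarity is the director direction closest to the local flow:
#' `p = +n` if `v . n > 0`, `p = -n` if `v . n < 0`. Ties (zero velocity,
#' or flow numerically perpendicular to the director:
#' `|v . n| < 1e-12 |v|` or `|v| < 1e-12`) keep the sign of the previous
#' polarity projected on the current director, which avoids sign chattering.
#'
#' @param Q an [nematic_field()].
#' @param vx,vy velocity component matrices.
#' @param p_prev previous [polarity_field()]; used only at ties. For the
#'   first step pass `NULL`, which resolves ties to `+n`.
#' @return a [polarity_field()].
#' @export
assign_polarity <- function(Q, vx, vy, p_prev = NULL) {
  d <- decompose_q(Q)
  vn <- vx * d$nx + vy * d$ny
  vmag <- sqrt(vx^2 + vy^2)
  tie <- (vmag < 1e-12) | (abs(vn) < 1e-12 * vmag)
  s <- sign(vn)
  if (is.null(p_prev)) {
    prev_s <- matrix(1, nrow(vx), ncol(vx))
  } else {
    prev_s <- sign(p_prev$px * d$nx + p_prev$py * d$ny)
    prev_s[prev_s == 0] <- 1
  }
  s[tie] <- prev_s[tie]
  polarity_field(s * d$nx, s * d$ny)
}

#' Passive plus active stress
#'
#' Assembles the stress driving the flow solver:
#' \describe{
#'   \item{active}{`-zeta Q_ij` (dipolar activity).}
#'   \item{passive}{`2 lam (Q + I/2) (Q:H) - lam H (Q + I/2) - lam (Q + I/2) H
#'     + (Q H - H Q) - K d_i Q_kl d_j Q_kl`.}
#' }
#' The isotropic pressure `-P delta_ij` is NOT included: the lattice
#' Boltzmann equation of state (`P = rho c_s^2`) already supplies it, and
#' adding both would double-count. The viscous stress lives inside the
#' collision operator for the same reason.
#'
#' @param Q an [nematic_field()].
#' @param H molecular field as returned by [molecular_field()].
#' @param lam flow-alignment coefficient.
#' @param zeta dipolar activity coefficient.
#' @param K Frank elastic constant (for the distortion/Ericksen term).
#' @return list of matrices `sxx`, `sxy`, `syx`, `syy`; the active part is
#'   symmetric traceless, the `QH - HQ` contribution is antisymmetric.
#' @export
assemble_stress <- function(Q, H, lam, zeta, K) {
  Qxx <- Q$Qxx; Qxy <- Q$Qxy
  Hxx <- H$Hxx; Hxy <- H$Hxy
  Qhxx <- Qxx + 0.5
  Qhyy <- 0.5 - Qxx
  QH2 <- 2 * (Qxx * Hxx + Qxy * Hxy)          # Q_lk H_kl
  # (H Qh) components; (Qh H) is its transpose since both factors are
  # symmetric, so diagonals coincide and off-diagonals swap.
  HQh_xx <- Hxx * Qhxx + Hxy * Qxy
  HQh_xy <- Hxx * Qxy + Hxy * Qhyy
  HQh_yx <- Hxy * Qhxx - Hxx * Qxy
  HQh_yy <- Hxy * Qxy - Hxx * Qhyy
  anti <- 2 * (Qxx * Hxy - Hxx * Qxy)         # (QH - HQ)_xy
  dxQxx <- ddx_central(Qxx); dyQxx <- ddy_central(Qxx)
  dxQxy <- ddx_central(Qxy); dyQxy <- ddy_central(Qxy)
  er_xx <- -2 * K * (dxQxx^2 + dxQxy^2)
  er_yy <- -2 * K * (dyQxx^2 + dyQxy^2)
  er_xy <- -2 * K * (dxQxx * dyQxx + dxQxy * dyQxy)
  list(
    sxx = 2 * lam * Qhxx * QH2 - 2 * lam * HQh_xx + er_xx - zeta * Qxx,
    sxy = 2 * lam * Qxy * QH2 - lam * (HQh_xy + HQh_yx) + anti + er_xy -
      zeta * Qxy,
    syx = 2 * lam * Qxy * QH2 - lam * (HQh_xy + HQh_yx) - anti + er_xy -
      zeta * Qxy,
    syy = 2 * lam * Qhyy * QH2 - 2 * lam * HQh_yy + er_yy + zeta * Qxx
  )
}

#' One explicit Beris-Edwards update
#'
#' Advances the order tensor by one explicit Euler step of
#' `dQ/dt + (v + V0 p) . grad Q = Gamma H + S`, with first-order upwind
#' differencing of the advection term (on the combined velocity
#' `v + V0 p`) and central differences elsewhere. The result stays
#' traceless symmetric by representation.
#'
#' @param Q an [nematic_field()].
#' @param vx,vy velocity matrices.
#' @param p a [polarity_field()].
#' @param params an [model_params()].
#' @param dt time step (defaults to `params$dt`).
#' @return the updated [nematic_field()].
#' @export
beris_edwards_step <- function(Q, vx, vy, p, params, dt = params$dt) {
  wx <- vx + params$V0 * p$px
  wy <- vy + params$V0 * p$py
  if (max(abs(wx)) * dt >= 1 || max(abs(wy)) * dt >= 1) {
    stop("advection CFL violated: (max|v| + V0) * dt >= 1 grid spacing")
  }
  H <- molecular_field(Q, params$K, params$A)
  S <- corotation_term(Q, vx, vy, params$lam)
  adv_xx <- wx * upwind_deriv(Q$Qxx, wx, "x") + wy * upwind_deriv(Q$Qxx, wy, "y")
  adv_xy <- wx * upwind_deriv(Q$Qxy, wx, "x") + wy * upwind_deriv(Q$Qxy, wy, "y")
  Qxx <- Q$Qxx + dt * (-adv_xx + params$Gamma * H$Hxx + S$Sxx)
  Qxy <- Q$Qxy + dt * (-adv_xy + params$Gamma * H$Hxy + S$Sxy)
  if (!all(is.finite(Qxx)) || !all(is.finite(Qxy))) {
    stop("order-parameter blow-up: non-finite Q after update")
  }
  nematic_field(Qxx, Qxy)
}
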