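# Linear stability of the x-aligned state (Qxx, Qxy, omega) = (1, 0, 0)
# with polarity (1, 0). Perturbations are single Fourier modes
# exp(i q (n x + m y)) with q = 2 pi / L the smallest wavevector. The
# Jacobian below was derived by hand from the continuum equations
# (incompressible flow, vorticity formulation) and is validated against a
# numerical directional-derivative linearization of the full nonlinear
# right-hand side (stability_jacobian_fd).

#' Mode Jacobian of the linearized equations
#'
#' Complex 3x3 Jacobian governing `d(dQxx, dQxy, domega)/dt` for the Fourier
#' mode `(n, m)` about the aligned base state. Includes the self-advection
#' contribution `-i V0 kx` on both tensor rows and the bulk free-energy
#' (`A`) contributions; with `A = 0` the `(dQxy, domega)` block reduces to
#' the classical active nematic dispersion with self-propulsion.
#' The `dQxx` row decouples from the other two whenever `kx ky = 0`, which
#' is why the longitudinal mode `(1, 0)` is governed by a 2x2 block.
#'
#' @param n,m integer mode indices, not both zero.
#' @param params an [model_params()]; the base wavenumber is `2 pi / L`.
#' @return complex 3x3 matrix on the basis (dQxx, dQxy, domega).
#' @export
stability_jacobian <- function(n, m, params) {
  stopifnot(n != 0 || m != 0)
  q <- 2 * pi / params$L
  kx <- q * n
  ky <- q * m
  k2 <- kx^2 + ky^2
  lam <- params$lam
  K <- params$K
  A <- params$A
  zeta <- params$zeta
  rho <- params$rho
  J <- matrix(0i, 3, 3)
  J[1, 1] <- -1i * params$V0 * kx - params$Gamma * (K * k2 + 20 * A)
  J[1, 3] <- 3 * lam * kx * ky / k2
  J[2, 2] <- -1i * params$V0 * kx - params$Gamma * (K * k2 + 4 * A)
  J[2, 3] <- lam * (kx^2 - ky^2) / (2 * k2) + 1
  # linearized stress components per unit mode amplitude:
  #   sigma_yx = Cyx dQxy, sigma_xy = Cxy dQxy,
  #   sigma_yy - sigma_xx = 2 Cd dQxx
  Cyx <- (lam + 2) * K * k2 - 12 * lam * A - zeta
  Cxy <- (lam - 2) * K * k2 - 12 * lam * A - zeta
  Cd <- 3 * lam * K * k2 + 92 * lam * A + zeta
  J[3, 1] <- -2 * kx * ky * Cd / rho
  J[3, 2] <- -(kx^2 * Cyx - ky^2 * Cxy) / rho
  J[3, 3] <- -(params$eta / rho) * k2
  J
}

#' Closed-form eigenvalues of the longitudinal (1, 0) mode
#'
#' Eigenvalue pair of the coupled `(dQxy, domega)` 2x2 block of
#' [stability_jacobian()] at `(n, m) = (1, 0)`:
#' `Lambda = (a + d)/2 +- sqrt(((a - d)/2)^2 + b c)` with
#' `a = -i q V0 - Gamma (K q^2 + 4 A)`, `d = -(eta/rho) q^2`,
#' `b = q^2 (zeta + 12 lam A - (2 + lam) K q^2) / rho`, `c = (2 + lam)/2`.
#' At `A = 0` this is exactly the classical dispersion
#' `Lambda = (q/2) [ -q (Gamma K + eta/rho) - i V0 +-
#'   sqrt( q^2 (Gamma K - eta/rho)^2 + 2 i q V0 (Gamma K - eta/rho)
#'   - V0^2 + (2 (2+lam)/rho) (zeta - q^2 K (2+lam)) ) ]`.
#'
#' @param params an [model_params()].
#' @return complex vector of length 2, sorted by decreasing real part.
#' @export
lambda_10 <- function(params) {
  J <- stability_jacobian(1, 0, params)
  a <- J[2, 2]; b <- J[3, 2]; cc <- J[2, 3]; d <- J[3, 3]
  disc <- sqrt(((a - d) / 2)^2 + b * cc)
  ev <- c((a + d) / 2 + disc, (a + d) / 2 - disc)
  ev[order(-Re(ev))]
}

# The A = 0 dispersion exactly as the classical printed form (radical
# expression); used in tests to confirm lambda_10() reduces to it.
lambda_10_a0 <- function(params) {
  q <- 2 * pi / params$L
  nu <- params$eta / params$rho
  GK <- params$Gamma * params$K
  lam <- params$lam
  rad <- sqrt(as.complex(
    q^2 * (GK - nu)^2 + 2i * q * params$V0 * (GK - nu) - params$V0^2 +
      (2 * (2 + lam) / params$rho) *
        (params$zeta - q^2 * params$K * (2 + lam))
  ))
  ev <- (q / 2) * c(-q * (GK + nu) - 1i * params$V0 + rad,
                    -q * (GK + nu) - 1i * params$V0 - rad)
  ev[order(-Re(ev))]
}

#' Largest growth rate over a family of modes
#'
#' @param params an [model_params()].
#' @param max_index modes with `max(|n|, |m|) <= max_index` (excluding
#'   (0, 0)) are scanned.
#' @return list with `re_max` (largest real part), `mode` (the `(n, m)`
#'   attaining it) and `stable` (`re_max < 0`).
#' @export
max_growth_rate <- function(params, max_index = 2L) {
  best <- -Inf
  best_nm <- c(NA_integer_, NA_integer_)
  for (n in -max_index:max_index) {
    for (m in -max_index:max_index) {
      if (n == 0 && m == 0) next
      r <- max(Re(eigen(stability_jacobian(n, m, params),
                        only.values = TRUE)$values))
      if (r > best) {
        best <- r
        best_nm <- c(n, m)
      }
    }
  }
  list(re_max = best, mode = best_nm, stable = best < 0)
}

#' Critical self-propulsion speed suppressing the instability
#'
#' Smallest `V0` for which the largest real eigenvalue of the `(1, 0)` mode
#' Jacobian crosses zero, found by bisection on `[0, v_max]` to absolute
#' tolerance `1e-10` (the root of the assembled Jacobian is authoritative;
#' the closed-form `A = 0` expression [critical_v0_closed()] is a
#' cross-check). Returns 0 when the parameters are already stable at
#' `V0 = 0`.
#'
#' @param params an [model_params()] (its `V0` is ignored).
#' @param v_max upper end of the search bracket.
#' @return `V0*`; attribute `"already_stable"` is `TRUE` when 0 is returned
#'   because the system is stable without self-propulsion.
#' @export
critical_v0 <- function(params, v_max = 1) {
  g <- function(v0) {
    p <- params
    p$V0 <- v0
    max(Re(lambda_10(p)))
  }
  if (g(0) <= 0) {
    return(structure(0, already_stable = TRUE))
  }
  if (g(v_max) >= 0) {
    stop("no stabilizing V0 in [0, ", v_max, "]: increase v_max")
  }
  lo <- 0
  hi <- v_max
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  structure((lo + hi) / 2, already_stable = FALSE)
}

#' Closed-form critical self-propulsion speed (A = 0)
#'
#' `V0* = sqrt( (Gamma K + eta/rho)^2 (2 + lam)
#'   (zeta - q^2 K (2 + lam)) / (2 Gamma K eta) -
#'   q^2 (Gamma K + eta/rho)^2 )`, the analytic zero crossing of the
#' `A = 0` dispersion; 0 when the bracket is non-positive (already stable).
#'
#' @param params an [model_params()].
#' @return `V0*` (numeric).
#' @export
critical_v0_closed <- function(params) {
  q <- 2 * pi / params$L
  nu <- params$eta / params$rho
  GK <- params$Gamma * params$K
  lam <- params$lam
  v2 <- (GK + nu)^2 * (2 + lam) *
    (params$zeta - q^2 * params$K * (2 + lam)) /
    (2 * GK * params$eta) - q^2 * (GK + nu)^2
  if (v2 <= 0) 0 else sqrt(v2)
}

#' Characteristic time scales of order and flow
#'
#' `tau_Q = Gamma K / V0^2` (self-propulsion time scale of the order
#' tensor) and `tau_v = eta / zeta` (balance of viscous and active stress).
#' Setting them equal gives `V0 = sqrt(Gamma K zeta / eta)`, the
#' square-root scaling between self-propulsion and activity.
#'
#' @param params an [model_params()] with `V0 > 0` and `zeta > 0`.
#' @return list with `tau_Q`, `tau_v` and `v0_balance`.
#' @export
timescales <- function(params) {
  if (params$V0 <= 0) stop("tau_Q undefined: V0 must be positive")
  if (params$zeta <= 0) stop("tau_v undefined: zeta must be positive")
  list(tau_Q = params$Gamma * params$K / params$V0^2,
       tau_v = params$eta / params$zeta,
       v0_balance = sqrt(params$Gamma * params$K * params$zeta / params$eta))
}

#' Stability phase diagram over (V0, zeta)
#'
#' Classifies every grid cell by the sign of the largest real eigenvalue
#' over all modes with `max(|n|, |m|) <= 2`, and computes the critical
#' curve `V0*(zeta)` from the longitudinal mode.
#'
#' @param v0_grid,zeta_grid numeric grids (non-negative).
#' @param params an [model_params()] providing all other coefficients.
#' @param max_index mode truncation (default 2).
#' @return list with `grid` (data frame: V0, zeta, re_lambda_max, stable)
#'   and `v0_star` (data frame: zeta, v0_star).
#' @export
phase_diagram <- function(v0_grid, zeta_grid, params, max_index = 2L) {
  stopifnot(all(v0_grid >= 0), all(zeta_grid >= 0))
  grid <- expand.grid(V0 = v0_grid, zeta = zeta_grid)
  grid$re_lambda_max <- NA_real_
  for (r in seq_len(nrow(grid))) {
    p <- params
    p$V0 <- grid$V0[r]
    p$zeta <- grid$zeta[r]
    grid$re_lambda_max[r] <- max_growth_rate(p, max_index)$re_max
  }
  grid$stable <- grid$re_lambda_max < 0
  v0s <- vapply(zeta_grid, function(z) {
    p <- params
    p$zeta <- z
    as.numeric(critical_v0(p))
  }, numeric(1))
  list(grid = grid, v0_star = data.frame(zeta = zeta_grid, v0_star = v0s))
}

# ---- numerical linearization oracle ---------------------------------------

# Continuum nonlinear right-hand side in the vorticity formulation,
# evaluated with exact spectral derivatives on an N x N grid spanning a
# periodic box of physical side L. Fields may be complex (analytic
# continuation of the polynomial nonlinearities); polarity is held at
# (1, 0), its variation enters the dynamics only at second order around the
# aligned base state.
rhs_spectral <- function(Qxx, Qxy, omega, params, box) {
  N <- nrow(Qxx)
  k1 <- fft_wavenumbers(N, box)
  KX <- matrix(k1, N, N)
  KY <- t(KX)
  K2 <- KX^2 + KY^2
  fft2 <- function(m) stats::fft(m)
  ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)
  dx <- function(m) ifft2(1i * KX * fft2(m))
  dy <- function(m) ifft2(1i * KY * fft2(m))
  lap <- function(m) ifft2(-K2 * fft2(m))

  # velocity from vorticity (zero-mean incompressible flow)
  oh <- fft2(omega)
  inv <- ifelse(K2 > 0, 1 / K2, 0)
  vx <- ifft2(1i * KY * oh * inv)
  vy <- ifft2(-1i * KX * oh * inv)

  dxvx <- dx(vx); dyvx <- dy(vx); dxvy <- dx(vy); dyvy <- dy(vy)
  Exx <- dxvx; Eyy <- dyvy; Exy <- 0.5 * (dxvy + dyvx)
  Wxy <- 0.5 * (dyvx - dxvy)

  trQ2 <- 2 * (Qxx * Qxx + Qxy * Qxy)
  bulk <- 4 * params$A * (1 - trQ2)
  Hxx <- params$K * lap(Qxx) + bulk * Qxx
  Hxy <- params$K * lap(Qxy) + bulk * Qxy

  lam <- params$lam
  Qhxx <- Qxx + 0.5
  Qhyy <- 0.5 - Qxx
  Mxx <- lam * Exx; Myy <- lam * Eyy
  Mxy <- lam * Exy + Wxy
  Myx <- lam * Exy - Wxy
  Sxx <- 2 * (Mxx * Qhxx + Mxy * Qxy)
  Syy <- 2 * (Myx * Qxy + Myy * Qhyy)
  Sxy <- Mxx * Qxy + Mxy * Qhyy + Qhxx * Myx + Qxy * Myy
  Syx <- Myx * Qhxx + Myy * Qxy + Qxy * Mxx + Qhyy * Mxy
  tr <- Qxx * (dxvx - dyvy) + Qxy * (dxvy + dyvx)
  Sxx <- Sxx - 2 * lam * Qhxx * tr
  Syy <- Syy - 2 * lam * Qhyy * tr
  Sxy <- Sxy - 2 * lam * Qxy * tr
  Syx <- Syx - 2 * lam * Qxy * tr

  wx <- vx + params$V0   # polarity fixed at (1, 0)
  wy <- vy
  dQxx_dt <- -(wx * dx(Qxx) + wy * dy(Qxx)) + params$Gamma * Hxx +
    0.5 * (Sxx - Syy)
  dQxy_dt <- -(wx * dx(Qxy) + wy * dy(Qxy)) + params$Gamma * Hxy +
    0.5 * (Sxy + Syx)

  QH2 <- 2 * (Qxx * Hxx + Qxy * Hxy)
  HQh_xx <- Hxx * Qhxx + Hxy * Qxy
  HQh_xy <- Hxx * Qxy + Hxy * Qhyy
  HQh_yx <- Hxy * Qhxx - Hxx * Qxy
  HQh_yy <- Hxy * Qxy - Hxx * Qhyy
  anti <- 2 * (Qxx * Hxy - Hxx * Qxy)
  dxQxx <- dx(Qxx); dyQxx <- dy(Qxx)
  dxQxy <- dx(Qxy); dyQxy <- dy(Qxy)
  er_xx <- -2 * params$K * (dxQxx^2 + dxQxy^2)
  er_yy <- -2 * params$K * (dyQxx^2 + dyQxy^2)
  er_xy <- -2 * params$K * (dxQxx * dyQxx + dxQxy * dyQxy)
  z <- params$zeta
  sxx <- 2 * lam * Qhxx * QH2 - 2 * lam * HQh_xx + er_xx - z * Qxx
  sxy <- 2 * lam * Qxy * QH2 - lam * (HQh_xy + HQh_yx) + anti + er_xy -
    z * Qxy
  syx <- 2 * lam * Qxy * QH2 - lam * (HQh_xy + HQh_yx) - anti + er_xy -
    z * Qxy
  syy <- 2 * lam * Qhyy * QH2 - 2 * lam * HQh_yy + er_yy + z * Qxx
  Fx <- dx(sxx) + dy(sxy)
  Fy <- dx(syx) + dy(syy)
  domega_dt <- -(vx * dx(omega) + vy * dy(omega)) +
    (params$eta * lap(omega) + dx(Fy) - dy(Fx)) / params$rho

  list(dQxx = dQxx_dt, dQxy = dQxy_dt, domega = domega_dt)
}

#' Numerically linearized mode Jacobian (directional derivatives)
#'
#' Independent check of [stability_jacobian()]: evaluates the full
#' nonlinear right-hand side (vorticity formulation, exact spectral
#' derivatives) at the aligned base state perturbed by `+eps` and `-eps`
#' times each unit Fourier mode, and assembles the Jacobian column-by-column
#' from the symmetric differences projected back onto the mode.
#'
#' @param n,m mode indices, not both zero; `max(|n|, |m|)` must be below
#'   `N/2`.
#' @param params an [model_params()].
#' @param N oracle grid resolution (the grid spans the physical box
#'   `L x L`, so the mode is represented exactly).
#' @param eps perturbation amplitude for the directional derivative.
#' @return complex 3x3 matrix comparable to [stability_jacobian()].
#' @export
stability_jacobian_fd <- function(n, m, params, N = 16L, eps = 1e-6) {
  stopifnot(n != 0 || m != 0, max(abs(c(n, m))) < N / 2)
  L <- params$L
  xg <- matrix((seq_len(N) - 1) * (L / N), N, N)
  yg <- t(xg)
  q <- 2 * pi / L
  mode <- exp(1i * q * (n * xg + m * yg))
  base <- list(Qxx = matrix(1 + 0i, N, N), Qxy = matrix(0i, N, N),
               omega = matrix(0i, N, N))
  project <- function(field) mean(field * Conj(mode))
  J <- matrix(0i, 3, 3)
  for (col in 1:3) {
    plus <- base
    minus <- base
    nm <- c("Qxx", "Qxy", "omega")[col]
    plus[[nm]] <- plus[[nm]] + eps * mode
    minus[[nm]] <- minus[[nm]] - eps * mode
    rp <- rhs_spectral(plus$Qxx, plus$Qxy, plus$omega, params, L)
    rm <- rhs_spectral(minus$Qxx, minus$Qxy, minus$omega, params, L)
    J[1, col] <- project((rp$dQxx - rm$dQxx) / (2 * eps))
    J[2, col] <- project((rp$dQxy - rm$dQxy) / (2 * eps))
    J[3, col] <- project((rp$domega - rm$domega) / (2 * eps))
  }
  J
}
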