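# Deterministic synthetic generators for tests and examples: defect
# textures with known winding, point processes with known hyperuniformity
# class, and divergence-free velocity fields with prescribed spectra or
# anisotropy. All generators are reproducible bit-exactly from their
# arguments and seed.

#' Synthetic defect textures
#'
#' Builds a nematic field from the standard half-integer defect ansatz
#' `theta(x) = sum_k s_k atan2(y - y_k, x - x_k)` with charges
#' `s_k = +-1/2`, order magnitude `q_bulk` tapered to zero over ~2 sites at
#' each core (`q = q_bulk prod_k tanh(r_k / 2)`).
#' `kind = "single"` places one defect of charge `charge` at the center
#' (the texture is not periodic: use it as an open-boundary patch);
#' `kind = "pair"` places a +1/2 and a -1/2 defect `separation` sites apart
#' along x, centered, whose far field is asymptotically uniform.
#'
#' @param kind `"single"` or `"pair"`.
#' @param L lattice side length.
#' @param separation pair separation in sites (`0 < separation < L/2`).
#' @param charge charge of the single defect (+1/2 or -1/2).
#' @param q_bulk bulk order magnitude.
#' @return an [nematic_field()].
#' @export
make_defect_texture <- function(kind = c("pair", "single"), L = 64,
                                separation = 20, charge = 0.5,
                                q_bulk = 1 / sqrt(2)) {
  kind <- match.arg(kind)
  x <- matrix(seq_len(L) - 1, L, L)
  y <- t(x)
  c0 <- (L - 1) / 2
  if (kind == "single") {
    stopifnot(charge %in% c(0.5, -0.5))
    cores <- data.frame(x = c0, y = c0, s = charge)
  } else {
    if (separation <= 0) stop("pair separation must be positive")
    if (separation >= L / 2) stop("pair separation must be below L/2")
    cores <- data.frame(x = c0 + c(-0.5, 0.5) * separation, y = c(c0, c0),
                        s = c(0.5, -0.5))
  }
  theta <- matrix(0, L, L)
  q <- matrix(q_bulk, L, L)
  for (k in seq_len(nrow(cores))) {
    theta <- theta + cores$s[k] * atan2(y - cores$y[k], x - cores$x[k])
    q <- q * tanh(sqrt((x - cores$x[k])^2 + (y - cores$y[k])^2) / 2)
  }
  nematic_field(q * cos(2 * theta), q * sin(2 * theta))
}

# Symmetric alpha-stable deviates (Chambers-Mallows-Stuck); used for
# heavy-tailed lattice displacements whose characteristic function
# exp(-|c k|^alpha) yields a structure factor ~ |k|^alpha at small k.
rstable_sym <- function(n, alpha, scale = 1) {
  stopifnot(alpha > 0, alpha <= 2)
  th <- stats::runif(n, -pi / 2, pi / 2)
  w <- stats::rexp(n)
  if (alpha == 1) return(scale * tan(th))
  scale * (sin(alpha * th) / cos(th)^(1 / alpha)) *
    (cos((1 - alpha) * th) / w)^((1 - alpha) / alpha)
}

#' Synthetic point processes with known density-fluctuation class
#'
#' \describe{
#'   \item{poisson}{`N` i.i.d. uniform points: `S(q) = 1`, `alpha = 0`,
#'     `beta = 1/2`.}
#'   \item{perturbed_lattice}{square lattice plus uniform jitter of
#'     `jitter` lattice spacings per component: hyperuniform
#'     (`S(q) ~ q^2` at small q, `beta < 1/2`).}
#'   \item{thomas_cluster}{Poisson parents with `mean_daughters` Gaussian
#'     (`sd = cluster_sd`) daughters each: clustered, enhanced
#'     fluctuations (`beta > 1/2`) on scales up to the cluster size.}
#'   \item{stable_lattice}{square lattice displaced by i.i.d. symmetric
#'     alpha-stable jumps with index `alpha_target` in (0, 2): realizes a
#'     prescribed hyperuniform exponent `S(q) ~ |q|^alpha_target`.}
#'   \item{cox_powerlaw}{Cox process whose random intensity is a clipped
#'     Gaussian field with a band-limited power-law spectrum
#'     `~ q^alpha_target` (`alpha_target < 0`): realizes anti-hyperuniform
#'     scaling `S(q) ~ 1 + amp (q L / 2 pi)^alpha_target` inside the band.}
#' }
#'
#' @param kind one of the process names above.
#' @param L box side length (points in `[0, L)`).
#' @param N target number of points (lattice kinds round to a square
#'   count).
#' @param seed RNG seed.
#' @param jitter perturbed-lattice jitter in lattice spacings.
#' @param mean_daughters,cluster_sd Thomas process parameters.
#' @param alpha_target prescribed structure-factor exponent for
#'   `stable_lattice` (in (0, 2]) / `cox_powerlaw` (negative).
#' @param amp amplitude of `S - 1` at the box wavevector for
#'   `cox_powerlaw`.
#' @param q_cut spectral band limit of the Cox intensity field.
#' @param stable_scale displacement scale of the stable-lattice jumps.
#' @return two-column matrix of point coordinates.
#' @export
make_point_process <- function(kind = c("poisson", "perturbed_lattice",
                                        "thomas_cluster", "stable_lattice",
                                        "cox_powerlaw"),
                               L = 256, N = 500, seed = 1L,
                               jitter = 0.2, mean_daughters = 10,
                               cluster_sd = 2, alpha_target = NULL,
                               amp = 40, q_cut = 0.2, stable_scale = 1) {
  kind <- match.arg(kind)
  stopifnot(N >= 2)
  set.seed(seed)
  if (kind == "poisson") {
    return(cbind(stats::runif(N, 0, L), stats::runif(N, 0, L)))
  }
  if (kind %in% c("perturbed_lattice", "stable_lattice")) {
    ns <- round(sqrt(N))
    a <- L / ns
    g <- expand.grid(x = (0:(ns - 1) + 0.5) * a, y = (0:(ns - 1) + 0.5) * a)
    n <- nrow(g)
    if (kind == "perturbed_lattice") {
      dxy <- matrix(stats::runif(2 * n, -jitter * a, jitter * a), n, 2)
    } else {
      if (is.null(alpha_target)) alpha_target <- 0.4
      stopifnot(alpha_target > 0, alpha_target <= 2)
      dxy <- cbind(rstable_sym(n, alpha_target, scale = stable_scale),
                   rstable_sym(n, alpha_target, scale = stable_scale))
    }
    return(cbind((g$x + dxy[, 1]) %% L, (g$y + dxy[, 2]) %% L))
  }
  if (kind == "thomas_cluster") {
    n_par <- max(1, round(N / mean_daughters))
    px <- stats::runif(n_par, 0, L)
    py <- stats::runif(n_par, 0, L)
    nd <- stats::rpois(n_par, mean_daughters)
    xs <- rep(px, nd) + stats::rnorm(sum(nd), 0, cluster_sd)
    ys <- rep(py, nd) + stats::rnorm(sum(nd), 0, cluster_sd)
    return(cbind(xs %% L, ys %% L))
  }
  # cox_powerlaw: intensity Lambda ~ lam_bar (1 + f), f Gaussian with
  # band-limited spectrum C |q|^alpha, clipped at zero intensity (the
  # clip is ~2 sigma out for the default amplitude, so distortion is
  # mild); points thinned from a dominating Poisson draw. The calibration
  # makes S(q) ~ 1 + amp (q/q_min)^alpha inside the band.
  if (is.null(alpha_target)) alpha_target <- -0.8
  stopifnot(alpha_target < 0)
  qmin <- 2 * pi / L
  lam_bar <- N / L^2
  Cspec <- amp * qmin^(-alpha_target) / lam_bar
  g <- gaussian_powerlaw_field(L, alpha_target, Cspec, q_cut)
  lam <- pmax(0, 1 + g)
  lam <- lam / mean(lam)
  # conditionally Poisson per unit cell, points uniform within their cell
  counts <- stats::rpois(L * L, as.vector(lam) * (N / L^2))
  cell <- rep.int(seq_len(L * L) - 1L, counts)
  n_tot <- length(cell)
  cbind(cell %% L + stats::runif(n_tot),
        cell %/% L + stats::runif(n_tot))
}

# Real Gaussian field on an L x L lattice with isotropic spectral density
# C |q|^alpha for 0 < |q| <= q_cut, zero beyond (band limit keeps the
# variance finite for alpha > -2).
gaussian_powerlaw_field <- function(L, alpha, C, q_cut) {
  k1 <- fft_wavenumbers(L)
  KX <- matrix(k1, L, L)
  KY <- t(KX)
  K <- sqrt(KX^2 + KY^2)
  P <- ifelse(K > 0 & K <= q_cut, C * K^alpha, 0)
  # Hermitian white noise in Fourier space via fft of real white noise
  # E|fft(wn)|^2 = L^2, so this realizes Var(g) = (1/L^2) sum_k P(k),
  # the lattice version of the continuum spectral-density convention
  wn <- matrix(stats::rnorm(L * L), L, L)
  gh <- stats::fft(wn) * sqrt(P)
  Re(stats::fft(gh, inverse = TRUE)) / (L * L)
}

#' Synthetic divergence-free velocity fields
#'
#' \describe{
#'   \item{taylor_green}{`v = (sin x cos y, -cos x sin y)` on one
#'     2-pi-periodized cell: all energy in the single shell
#'     `|q| = sqrt(2)` (normalized).}
#'   \item{powerlaw}{random-phase field with shell-integrated kinetic
#'     energy spectrum `E(q) ~ q^exponent` over the band
#'     `q_band` (normalized wavenumbers), zero outside.}
#'   \item{anisotropic}{random-phase field with a Gaussian spectral
#'     envelope elongated along the axis at `axis_angle` (radians):
#'     `sigma_along < sigma_across` gives structures elongated along the
#'     axis.}
#'   \item{banded}{coherent flow bands along the axis (a very narrow
#'     `anisotropic` spectral sliver, `sigma_along = 0.3`) mixed with
#'     isotropic small-scale noise of relative amplitude `noise_rms`.
#'     The flow direction locally follows the bands, so the velocity
#'     component parallel to the local flow stays correlated over longer
#'     radial distances than the perpendicular one (`l_par > l_perp`),
#'     emulating the broken rotational symmetry of the
#'     intermediate-self-propulsion flow state.}
#' }
#' All random fields are built on the discrete (central-difference)
#' solenoidal polarization, so the solver's divergence vanishes to
#' rounding.
#'
#' @param kind `"taylor_green"`, `"powerlaw"` or `"anisotropic"`.
#' @param L lattice side length.
#' @param exponent shell-spectrum exponent for `"powerlaw"` (in (-5, 0]).
#' @param q_band normalized wavenumber band for `"powerlaw"`.
#' @param sigma_along,sigma_across envelope widths (normalized wavenumbers)
#'   for `"anisotropic"`.
#' @param axis_angle orientation of the anisotropy/band axis, radians.
#' @param noise_rms relative amplitude of the isotropic noise mixed into
#'   `"banded"` fields.
#' @param rms target root-mean-square speed.
#' @param seed RNG seed.
#' @return list with matrices `vx`, `vy`.
#' @export
make_velocity_field <- function(kind = c("taylor_green", "powerlaw",
                                         "anisotropic", "banded"),
                                L = 128, exponent = -3,
                                q_band = c(1, L / 4),
                                sigma_along = 3, sigma_across = 12,
                                axis_angle = 0, noise_rms = 0.25,
                                rms = 1, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "taylor_green") {
    x <- matrix(2 * pi * (seq_len(L) - 1) / L, L, L)
    y <- t(x)
    return(list(vx = sin(x) * cos(y), vy = -cos(x) * sin(y)))
  }
  if (kind == "banded") {
    b <- make_velocity_field("anisotropic", L = L, sigma_along = 0.3,
                             sigma_across = sigma_across,
                             axis_angle = axis_angle, rms = 1, seed = seed)
    n <- make_velocity_field("powerlaw", L = L, exponent = -3,
                             q_band = c(6, min(50, L / 4)), rms = noise_rms,
                             seed = seed + 500L)
    sc <- rms / sqrt(mean((b$vx + n$vx)^2 + (b$vy + n$vy)^2))
    return(list(vx = sc * (b$vx + n$vx), vy = sc * (b$vy + n$vy)))
  }
  stopifnot(exponent > -5, exponent <= 0)
  set.seed(seed)
  k1 <- fft_wavenumbers(L)           # physical wavenumbers 2 pi j / L
  KX <- matrix(k1, L, L)
  KY <- t(KX)
  qn <- sqrt(KX^2 + KY^2) * L / (2 * pi)  # normalized |q|
  # discrete solenoidal polarization: central-difference wavevector
  SX <- sin(KX)
  SY <- sin(KY)
  S2 <- SX^2 + SY^2
  if (kind == "powerlaw") {
    # shell-integrated E(q) ~ q^e with ~q modes per shell => per-mode
    # amplitude^2 ~ q^(e-1)
    env <- ifelse(qn >= q_band[1] & qn <= q_band[2] & S2 > 0,
                  qn^((exponent - 1) / 2), 0)
  } else {
    ca <- cos(axis_angle); sa <- sin(axis_angle)
    qa <- (KX * ca + KY * sa) * L / (2 * pi)
    qb <- (-KX * sa + KY * ca) * L / (2 * pi)
    env <- ifelse(S2 > 0 & qn > 0,
                  exp(-0.5 * (qa / sigma_along)^2 -
                        0.5 * (qb / sigma_across)^2), 0)
  }
  # Hermitian random phases (theta(k) - theta(-k) is antisymmetric) on a
  # streamfunction; the velocity is its central-difference curl, so the
  # field is real and the solver's discrete divergence vanishes exactly.
  th <- matrix(stats::runif(L * L, -pi, pi), L, L)
  rev2 <- function(m) m[c(1, rev(seq_len(L)[-1])), c(1, rev(seq_len(L)[-1]))]
  phase <- exp(1i * (th - rev2(th)))
  inv <- ifelse(S2 > 0, 1 / sqrt(S2), 0)
  psih <- env * phase * inv
  vxh <- 1i * SY * psih
  vyh <- -1i * SX * psih
  vx <- Re(stats::fft(vxh, inverse = TRUE)) / (L * L)
  vy <- Re(stats::fft(vyh, inverse = TRUE)) / (L * L)
  sc <- rms / sqrt(mean(vx^2 + vy^2))
  list(vx = vx * sc, vy = vy * sc)
}
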