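test_that("vorticity reproduces rigid rotation, shear and a spectral oracle", {
  L <- 32
  x <- matrix(0:(L - 1), L, L)
  y <- t(x)
  expect_equal(vorticity(0.3 * y, matrix(0, L, L))[5, 5], -0.3)
  expect_equal(vorticity(-0.1 * y, 0.1 * x)[8, 8], 0.2)
  v <- make_velocity_field("powerlaw", L = 64, exponent = -3,
                           q_band = c(2, 10), seed = 3)
  om <- vorticity(v$vx, v$vy)
  sd <- activenem:::spectral_deriv
  om_sp <- sd(v$vy, "x") - sd(v$vx, "y")
  expect_lt(max(abs(om - om_sp)), 0.1 * max(abs(om_sp)))
  expect_lt(abs(mean(om)), 1e-14)
})

test_that("spectra satisfy Parseval and localize single-mode fields", {
  L <- 64
  y <- t(matrix(0:(L - 1), L, L))
  k <- 2 * pi * 5 / L
  vx <- 0.3 * sin(k * y)
  es <- energy_spectrum(vx, matrix(0, L, L))
  expect_equal(es$q[which(es$values > 1e-14)], 5)
  expect_lt(abs(sum(es$values) - mean(vx^2) / 2), 1e-10)

  # Taylor-Green: one shell; Parseval for energy and enstrophy
  tg <- make_velocity_field("taylor_green", L = 64)
  et <- energy_spectrum(tg$vx, tg$vy)
  expect_equal(sum(et$values > 1e-12), 1)
  expect_lt(abs(sum(et$values) - mean(tg$vx^2 + tg$vy^2) / 2) /
              sum(et$values), 1e-8)
  en <- enstrophy_spectrum(tg$vx, tg$vy)
  omt <- vorticity(tg$vx, tg$vy)
  expect_lt(abs(sum(en$values) - mean(omt^2) / 2) / sum(en$values), 1e-8)
})

test_that("prescribed power-law spectra are recovered by the exponent fits", {
  pw <- make_velocity_field("powerlaw", L = 256, exponent = -3,
                            q_band = c(2, 64), seed = 4)
  es <- energy_spectrum(pw$vx, pw$vy, fit_range = c(4, 32))
  expect_equal(es$fit$exponent, -3, tolerance = 0.05)

  # Parseval on the same snapshot
  tot <- mean(pw$vx^2 + pw$vy^2) / 2
  expect_lt(abs(sum(es$values) - tot) / tot, 1e-8)
})

test_that("vorticity correlations: noise floor, mean removal, nu = b + 1", {
  # white-noise vorticity is uncorrelated beyond the stencil
  set.seed(9)
  wn <- matrix(rnorm(128^2), 128)
  vc <- vorticity_correlation(wn, fit_range = c(30, 60))
  expect_true(all(abs(vc$C[4:20]) < 3 / 128))

  # uniform field: zero variance after mean removal is rejected
  expect_error(vorticity_correlation(matrix(2, 32, 32)),
               "zero variance")

  # Fourier-pair construction: enstrophy exponent b maps to real-space
  # decay nu = b + 1 (b = +0.5 keeps the finite-box infrared offset
  # negligible over the fit window)
  vs <- lapply(1:6, function(i) make_velocity_field("powerlaw", L = 512,
               exponent = -1.5, q_band = c(1, 250), seed = i))
  en <- enstrophy_spectrum(lapply(vs, `[[`, "vx"), lapply(vs, `[[`, "vy"),
                           fit_range = c(1, 24))
  oms <- lapply(vs, function(v) vorticity(v$vx, v$vy))
  vc2 <- vorticity_correlation(oms, fit_range = c(6, 32))
  expect_equal(vc2$nu, en$fit$exponent + 1, tolerance = 0.1)
})

test_that("elastic energy summary is bounded, averaging-consistent and arithmetic-exact", {
  Qp <- make_defect_texture("pair", L = 64, separation = 20)
  r1 <- elastic_energy_summary(Qp, K = 0.05)
  expect_gt(r1, 0)
  expect_lt(r1, 1)
  # duplicated snapshots: unchanged
  expect_equal(elastic_energy_summary(list(Qp, Qp), K = 0.05), r1)
  # uniform field: degenerate
  expect_error(elastic_energy_summary(nematic_field(matrix(0.5, 16, 16),
                                                    matrix(0, 16, 16)),
                                      K = 0.05), "degenerate")
  # one hot site of value M over background b: rho_e = (b/M) up to the hot
  # site's own unit contribution
  E <- matrix(0.02, 32, 32)
  E[5, 7] <- 2
  expect_equal(mean(E / max(E)), (1023 * 0.01 + 1) / 1024, tolerance = 1e-12)
})

test_that("director correlation length matches a constructed correlation scale", {
  # Gaussian Q components with isotropic spectral density chosen so the
  # tensor correlation decays roughly exponentially with length ell
  mk_exp_q <- function(L, ell, seed) {
    set.seed(seed)
    k1 <- activenem:::fft_wavenumbers(L)
    KX <- matrix(k1, L, L)
    KY <- t(KX)
    P <- (1 + (sqrt(KX^2 + KY^2) * ell)^2)^(-1.5)
    mk <- function() {
      wh <- stats::fft(matrix(rnorm(L * L), L))
      Re(stats::fft(wh * sqrt(P), inverse = TRUE)) / (L * L)
    }
    nematic_field(mk(), mk())
  }
  Qs <- lapply(1:6, function(i) mk_exp_q(256, 10, i))
  dc <- director_correlation(Qs)
  expect_true(dc$crossed)
  expect_equal(dc$l_c, 10, tolerance = 0.1)

  # global director rotation by pi/2 (Q -> -Q) leaves the curve unchanged
  Qflip <- lapply(Qs, function(q) nematic_field(-q$Qxx, -q$Qxy))
  dc2 <- director_correlation(Qflip)
  expect_field_equal(dc2$C, dc$C, 1e-12)

  # uniform director: no crossing, flagged, l_c = L/2
  du <- director_correlation(nematic_field(matrix(0.7, 64, 64),
                                           matrix(0.1, 64, 64)))
  expect_false(du$crossed)
  expect_equal(du$l_c, 32)
})

test_that("flow-frame velocity correlations detect broken rotational symmetry", {
  # statistically isotropic field: parallel and perpendicular lengths agree
  iso <- lapply(1:5, function(i) make_velocity_field("powerlaw", L = 256,
                exponent = -3, q_band = c(2, 40), seed = i))
  ai <- anisotropy_correlations(lapply(iso, `[[`, "vx"),
                                lapply(iso, `[[`, "vy"), seed = 2)
  expect_lt(abs(ai$delta_l), 2)

  # banded flow: the parallel component stays correlated longer
  ban <- lapply(1:5, function(i) make_velocity_field("banded", L = 256,
                sigma_across = 12, noise_rms = 0.25, seed = i))
  ab <- anisotropy_correlations(lapply(ban, `[[`, "vx"),
                                lapply(ban, `[[`, "vy"), seed = 2)
  expect_gt(ab$delta_l, 0.5)

  # exact frame invariance: rotating the velocity COMPONENTS globally by
  # 37 degrees leaves both curves unchanged (the frames co-rotate)
  th <- 37 * pi / 180
  rvx <- lapply(ban, function(v) cos(th) * v$vx - sin(th) * v$vy)
  rvy <- lapply(ban, function(v) sin(th) * v$vx + cos(th) * v$vy)
  ar <- anisotropy_correlations(rvx, rvy, seed = 2)
  expect_field_equal(ar$C_par, ab$C_par, 1e-10)
  expect_field_equal(ar$C_perp, ab$C_perp, 1e-10)

  # statistical equivariance: bands at a 37-degree axis give the same
  # anisotropy sign and comparable magnitude
  ban37 <- lapply(1:5, function(i) make_velocity_field("banded", L = 256,
                  sigma_across = 12, noise_rms = 0.25,
                  axis_angle = th, seed = i + 40))
  a37 <- anisotropy_correlations(lapply(ban37, `[[`, "vx"),
                                 lapply(ban37, `[[`, "vy"), seed = 2)
  expect_gt(a37$delta_l, 0.5)
})
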