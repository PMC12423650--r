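test_that("elastic energy density matches closed forms and a brute-force gradient sum", {
  L <- 32
  K <- 0.05
  # uniform field carries no elastic energy
  E0 <- elastic_energy_density(nematic_field(matrix(0.6, L, L),
                                             matrix(-0.2, L, L)), K)
  expect_field_equal(E0, matrix(0, L, L), 1e-15)

  # resolved plane wave: lattice average K eps^2 keff^2 / 2 with the
  # central-difference wavenumber keff = sin(k)
  x <- matrix(0:(L - 1), L, L)
  k <- 2 * pi * 4 / L
  eps <- 0.01
  E <- elastic_energy_density(nematic_field(eps * cos(k * x),
                                            matrix(0, L, L)), K)
  expect_equal(mean(E), K * eps^2 * sin(k)^2 / 2, tolerance = 1e-12)

  # arbitrary field: brute-force loop over all components and directions
  Q <- rand_qfield(16, seed = 5)
  Eb <- matrix(0, 16, 16)
  for (comp in list(Q$Qxx, Q$Qxy)) {
    dx <- (shift_field(comp, 1, 0) - shift_field(comp, -1, 0)) / 2
    dy <- (shift_field(comp, 0, 1) - shift_field(comp, 0, -1)) / 2
    Eb <- Eb + 2 * (dx^2 + dy^2)    # Qyy/Qyx double the stored components
  }
  expect_field_equal(elastic_energy_density(Q, K), K / 2 * Eb, 1e-14)
  expect_true(all(elastic_energy_density(Q, K) >= 0))
})

test_that("molecular field has the right stationary points and discrete spectral action", {
  L <- 32
  # bulk minimum q = 1/sqrt(2): H vanishes
  H <- molecular_field(nematic_field(matrix(1 / sqrt(2), L, L),
                                     matrix(0, L, L)), 0.05, 0.1)
  expect_field_equal(H$Hxx, matrix(0, L, L), 1e-14)
  expect_field_equal(H$Hxy, matrix(0, L, L), 1e-14)

  # uniform Qxx = 1: Hxx = 4 A (1 - 2) = -0.4 for A = 0.1
  H1 <- molecular_field(nematic_field(matrix(1, L, L), matrix(0, L, L)),
                        0.05, 0.1)
  expect_equal(H1$Hxx[3, 7], -0.4)

  # plane wave with A = 0: H = -K keff^2 Q with the 5-point Laplacian
  # eigenvalue keff^2 = 2 - 2 cos(k)
  x <- matrix(0:(L - 1), L, L)
  k <- 2 * pi * 3 / L
  Q <- nematic_field(1e-3 * cos(k * x), matrix(0, L, L))
  H2 <- molecular_field(Q, 0.05, 0)
  expect_field_equal(H2$Hxx, -0.05 * (2 - 2 * cos(k)) * Q$Qxx, 1e-15)
})

test_that("co-rotation reduces to lam*E under shear and rotates the director rigidly", {
  L <- 32
  Z <- matrix(0, L, L)
  x <- matrix(0:(L - 1), L, L)
  y <- t(x)

  # uniform velocity: S = 0
  S0 <- corotation_term(rand_qfield(L, 2), matrix(0.3, L, L),
                        matrix(-0.1, L, L), lam = 0.2)
  expect_field_equal(S0$Sxx, Z, 1e-14)
  expect_field_equal(S0$Sxy, Z, 1e-14)

  # Q = 0, simple shear v = (gam*y, 0): S = lam E, S_xy = lam*gam/2
  # (interior sites; the periodic wrap-around rows see the seam)
  gam <- 0.3
  S <- corotation_term(nematic_field(Z, Z), gam * y, Z, lam = 0.2)
  expect_equal(S$Sxy[5, 5], 0.2 * gam / 2, tolerance = 1e-14)
  expect_equal(S$Sxx[5, 5], 0, tolerance = 1e-14)

  # rigid rotation v = (-om*y, om*x), Q = diag(q, -q): S_xy = 2*om*q,
  # the commutator [W, Q] turning the director at rate om
  om <- 0.1
  qv <- 0.4
  S2 <- corotation_term(nematic_field(matrix(qv, L, L), Z),
                        -om * y, om * x, lam = 0.2)
  expect_equal(S2$Sxy[8, 8], 2 * om * qv, tolerance = 1e-13)
})

test_that("polarity follows the flow and keeps its sign at ties", {
  n1 <- nematic_field(matrix(1, 2, 2), matrix(0, 2, 2))  # director x
  p <- assign_polarity(n1, matrix(1, 2, 2), matrix(0.1, 2, 2))
  expect_equal(p$px[1, 1], 1)
  p2 <- assign_polarity(n1, matrix(-1, 2, 2), matrix(0, 2, 2))
  expect_equal(p2$px[1, 1], -1)
  # zero velocity: retain previous sign
  prev <- polarity_field(matrix(-1, 2, 2), matrix(0, 2, 2))
  p3 <- assign_polarity(n1, matrix(0, 2, 2), matrix(0, 2, 2), prev)
  expect_equal(p3$px[1, 1], -1)
  # flow exactly perpendicular to the director: also a tie
  p4 <- assign_polarity(n1, matrix(0, 2, 2), matrix(1, 2, 2), prev)
  expect_equal(p4$px[1, 1], -1)
})

test_that("stress assembly matches closed forms and brute-force tensor algebra", {
  L <- 16
  Z <- matrix(0, L, L)
  # uniform Q with H = 0 (A = 0): passive stress vanishes, active = -zeta Q
  Qu <- nematic_field(matrix(0.7, L, L), matrix(-0.1, L, L))
  Hu <- molecular_field(Qu, 0.05, 0)
  s <- assemble_stress(Qu, Hu, lam = 0.2, zeta = 0.05, K = 0.05)
  expect_field_equal(s$sxx, -0.05 * Qu$Qxx, 1e-14)
  expect_field_equal(s$sxy, -0.05 * Qu$Qxy, 1e-14)
  expect_field_equal(s$syy, +0.05 * Qu$Qxx, 1e-14)

  # direct substitution: Q = diag(1, -1), zeta = 0.05 -> active diag(-0.05, 0.05)
  Q1 <- nematic_field(matrix(1, L, L), Z)
  s1 <- assemble_stress(Q1, list(Hxx = Z, Hxy = Z), lam = 0.2,
                        zeta = 0.05, K = 0.05)
  expect_equal(s1$sxx[1, 1], -0.05)
  expect_equal(s1$syy[1, 1], 0.05)

  # antisymmetric part equals QH - HQ by brute-force 2x2 tensor loop
  Q <- rand_qfield(L, seed = 9, amp = 0.4)
  H <- molecular_field(Q, 0.05, 0.1)
  s2 <- assemble_stress(Q, H, lam = 0.2, zeta = 0.05, K = 0.05)
  anti_impl <- (s2$sxy - s2$syx) / 2
  anti_ref <- matrix(0, L, L)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      Qm <- matrix(c(Q$Qxx[i, j], Q$Qxy[i, j],
                     Q$Qxy[i, j], -Q$Qxx[i, j]), 2, 2)
      Hm <- matrix(c(H$Hxx[i, j], H$Hxy[i, j],
                     H$Hxy[i, j], -H$Hxx[i, j]), 2, 2)
      anti_ref[i, j] <- (Qm %*% Hm - Hm %*% Qm)[1, 2]
    }
  }
  expect_field_equal(anti_impl, anti_ref, 1e-13)
})

test_that("Beris-Edwards step: fixed point, relaxation rate, pure advection, conservation", {
  # uniform aligned state at the bulk minimum is a fixed point
  L <- 32
  Z <- matrix(0, L, L)
  p <- model_params(L = L, V0 = 0.3, A = 0.1, zeta = 0.05)
  Q0 <- nematic_field(matrix(1 / sqrt(2), L, L), Z)
  pol <- polarity_field(matrix(1, L, L), Z)
  Q1 <- beris_edwards_step(Q0, Z, Z, pol, p)
  expect_field_equal(Q1$Qxx, Q0$Qxx, 1e-14)
  expect_field_equal(Q1$Qxy, Q0$Qxy, 1e-14)

  # Gamma-only relaxation of a plane wave decays at Gamma K keff^2 per
  # step within 1%
  L <- 64
  k <- 2 * pi * 3 / L
  x <- matrix(0:(L - 1), L, L)
  p2 <- model_params(L = L, Gamma = 0.1, K = 0.05, A = 0, zeta = 0, V0 = 0)
  Q <- nematic_field(matrix(1, L, L), 1e-3 * cos(k * x))
  pol64 <- polarity_field(matrix(1, L, L), matrix(0, L, L))
  a0 <- max(abs(Q$Qxy))
  for (i in 1:200) Q <- beris_edwards_step(Q, matrix(0, L, L),
                                           matrix(0, L, L), pol64, p2)
  rate <- -log(max(abs(Q$Qxy)) / a0) / 200
  expect_equal(rate, 0.1 * 0.05 * (2 - 2 * cos(k)), tolerance = 0.01)

  # pure self-advection translates a broad blob by V0 * t along x
  L <- 128
  p3 <- model_params(L = L, Gamma = 1e-12, K = 0.05, A = 0, zeta = 0,
                     V0 = 0.1)
  x <- matrix(0:(L - 1), L, L)
  y <- t(x)
  blob <- function(cx) 0.2 * exp(-((x - cx)^2 + (y - 64)^2) / (2 * 16^2))
  Q <- nematic_field(matrix(1, L, L), blob(40))
  polL <- polarity_field(matrix(1, L, L), matrix(0, L, L))
  ZL <- matrix(0, L, L)
  for (i in 1:100) Q <- beris_edwards_step(Q, ZL, ZL, polL, p3)
  err <- sqrt(sum((Q$Qxy - blob(50))^2) / sum(blob(50)^2))
  expect_lt(err, 0.02)

  # advective term conserves the lattice sums exactly for uniform carrier
  p4 <- model_params(L = 64, Gamma = 1e-300, K = 0.05, A = 0, zeta = 0,
                     V0 = 0.08)
  set.seed(4)
  Qr <- nematic_field(matrix(1, 64, 64) + 0.1 * matrix(rnorm(64^2), 64),
                      0.1 * matrix(rnorm(64^2), 64))
  s0 <- c(sum(Qr$Qxx), sum(Qr$Qxy))
  for (i in 1:50) Qr <- beris_edwards_step(Qr, matrix(0, 64, 64),
                                           matrix(0, 64, 64), pol64, p4)
  expect_lt(abs(sum(Qr$Qxx) - s0[1]), 1e-9)
  expect_lt(abs(sum(Qr$Qxy) - s0[2]), 1e-9)

  # CFL guard
  expect_error(beris_edwards_step(Q0, matrix(1.2, 32, 32), Z, pol,
                                  model_params(L = 32)),
               "CFL")
})

test_that("operators are equivariant under 90-degree lattice rotation", {
  Q <- rand_qfield(32, seed = 11)
  Qrot <- rot90_qfield(Q)
  # molecular field transforms like Q (components negate at rotated sites)
  H <- molecular_field(Q, 0.05, 0.1)
  Hrot <- molecular_field(Qrot, 0.05, 0.1)
  expect_field_equal(Hrot$Hxx, -rot90_scalar(H$Hxx), 1e-13)
  expect_field_equal(Hrot$Hxy, -rot90_scalar(H$Hxy), 1e-13)
  # elastic energy is a scalar
  E <- elastic_energy_density(Q, 0.05)
  expect_field_equal(elastic_energy_density(Qrot, 0.05), rot90_scalar(E),
                     1e-14)
})
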