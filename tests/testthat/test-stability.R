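test_that("assembled Jacobian matches numerical linearization of the nonlinear equations", {
  p <- model_params(L = 256, zeta = 0.01, V0 = 0.05)   # A = 0.1 default
  for (nm in list(c(1, 0), c(0, 1), c(1, 1), c(2, -1))) {
    Ja <- stability_jacobian(nm[1], nm[2], p)
    Jn <- stability_jacobian_fd(nm[1], nm[2], p)
    expect_lt(max(Mod(Ja - Jn)), 1e-8)
  }
  # also with A = 0 and different transport coefficients
  p2 <- model_params(L = 128, zeta = 0.03, V0 = 0.2, A = 0, eta = 10,
                     lam = 0.5, Gamma = 0.3)
  expect_lt(max(Mod(stability_jacobian(1, 0, p2) -
                      stability_jacobian_fd(1, 0, p2))), 1e-8)
})

test_that("longitudinal mode decouples and lambda_10 equals the 2x2 block eigenvalues", {
  p <- model_params(L = 256, zeta = 0.01, V0 = 0.07)
  J <- stability_jacobian(1, 0, p)
  expect_equal(Mod(J[1, 3]), 0)     # dQxx decouples at (1, 0)
  expect_equal(Mod(J[3, 1]), 0)
  expect_equal(Mod(J[1, 2]) + Mod(J[2, 1]), 0)
  ev_block <- eigen(J[2:3, 2:3], only.values = TRUE)$values
  ev <- lambda_10(p)
  expect_lt(max(Mod(sort_complex(ev) - sort_complex(ev_block))), 1e-10)
})

test_that("A = 0 dispersion reproduces the printed closed form exactly", {
  for (v0 in c(0, 0.03, 0.2)) {
    p <- model_params(L = 256, zeta = 0.008, V0 = v0, A = 0)
    expect_lt(max(Mod(lambda_10(p) - activenem:::lambda_10_a0(p))), 1e-14)
  }
  # V0 = 0: eigenvalues are real or a conjugate pair; positive growth for
  # activity above the elastic threshold
  p0 <- model_params(L = 256, zeta = 0.01, V0 = 0, A = 0)
  expect_gt(max(Re(lambda_10(p0))), 0)
  # activity exactly at the elastic threshold zeta = q^2 K (2 + lam):
  # the active term in the radical vanishes and the state is stable
  q <- 2 * pi / 256
  pth <- model_params(L = 256, zeta = q^2 * 0.05 * 2.2, V0 = 0, A = 0)
  expect_lt(max(Re(lambda_10(pth))), 0)
})

test_that("passive limit is non-growing for all scanned modes", {
  p <- model_params(L = 128, zeta = 0, V0 = 0, A = 0)
  for (n in -2:2) for (m in -2:2) {
    if (n == 0 && m == 0) next
    expect_lte(max(Re(eigen(stability_jacobian(n, m, p),
                            only.values = TRUE)$values)), 1e-14)
  }
})

test_that("critical V0: root against closed form, monotonicity, sqrt(zeta) scaling", {
  p <- model_params(L = 256, zeta = 0.01, A = 0)
  v_root <- critical_v0(p)
  expect_equal(as.numeric(v_root), critical_v0_closed(p), tolerance = 1e-7)

  # already stable: returns 0 with the flag
  ps <- model_params(L = 256, zeta = 1e-7, A = 0)
  v0s <- critical_v0(ps)
  expect_equal(as.numeric(v0s), 0)
  expect_true(attr(v0s, "already_stable"))

  # strictly increasing in zeta
  zs <- c(0.002, 0.005, 0.01, 0.02, 0.05)
  vs <- vapply(zs, function(z) {
    as.numeric(critical_v0(model_params(L = 256, zeta = z, A = 0)))
  }, numeric(1))
  expect_true(all(diff(vs) > 0))

  # sqrt scaling for zeta far above the elastic threshold: log-log slope 1/2
  zbig <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  vbig <- vapply(zbig, function(z) {
    as.numeric(critical_v0(model_params(L = 256, zeta = z, A = 0), v_max = 3))
  }, numeric(1))
  slope <- coef(lm(log(vbig) ~ log(zbig)))[2]
  expect_equal(unname(slope), 0.5, tolerance = 0.01)
})

test_that("time scales evaluate literally and balance at V0 = sqrt(Gamma K zeta / eta)", {
  p <- model_params(V0 = 0.06, zeta = 0.05)
  ts <- timescales(p)
  expect_equal(ts$tau_Q, 0.1 * 0.05 / 0.06^2)   # ~1.389
  expect_equal(ts$tau_v, 20 / 0.05)             # 400
  pb <- model_params(V0 = ts$v0_balance, zeta = 0.05)
  tb <- timescales(pb)
  expect_equal(tb$tau_Q, tb$tau_v, tolerance = 1e-12)
  expect_error(timescales(model_params(V0 = 0, zeta = 0.05)))
  expect_error(timescales(model_params(V0 = 0.1, zeta = 0)))
})

test_that("eigenvalues are continuous in V0 and cross zero exactly once", {
  p <- model_params(L = 256, zeta = 0.01, A = 0)
  v0s <- seq(0, 0.4, length.out = 400)
  res <- vapply(v0s, function(v) {
    p$V0 <- v
    max(Re(lambda_10(p)))
  }, numeric(1))
  expect_lt(max(abs(diff(res))), 5e-4)            # no branch jumps
  expect_equal(sum(diff(sign(res)) != 0), 1)      # single crossing
})

test_that("phase diagram classifies cells and the first unstable mode is longitudinal", {
  p <- model_params(L = 1024, A = 0)
  # activity below the elastic threshold q^2 K (2 + lam) ~ 4e-6 at this
  # lattice size: stable for every V0
  z_tiny <- 2e-6
  pd <- phase_diagram(v0_grid = c(0, 0.02, 0.08),
                      zeta_grid = c(z_tiny, 0.002, 0.01), params = p)
  expect_equal(nrow(pd$grid), 9)
  expect_true(all(pd$grid$stable[pd$grid$zeta == z_tiny]))
  expect_equal(pd$v0_star$v0_star[1], 0)
  # boundary cells bracket the critical curve
  for (z in c(0.002, 0.01)) {
    vstar <- pd$v0_star$v0_star[pd$v0_star$zeta == z]
    sub <- pd$grid[pd$grid$zeta == z, ]
    expect_true(all(sub$stable[sub$V0 > vstar]))
    expect_true(all(!sub$stable[sub$V0 < vstar]))
  }
  # the first mode to rise as activity grows is the longitudinal (1, 0):
  # its activity threshold (the smallest zeta with positive growth at
  # V0 = 0) lies below every other scanned mode's, so just above it the
  # unstable set is exactly {(+-1, 0)}
  zc <- uniroot(function(z) {
    max(Re(lambda_10(model_params(L = 1024, zeta = z, V0 = 0, A = 0))))
  }, c(1e-8, 1e-3), tol = 1e-12)$root
  mg <- max_growth_rate(model_params(L = 1024, zeta = 1.5 * zc, V0 = 0,
                                     A = 0))
  expect_false(mg$stable)
  expect_equal(abs(mg$mode[1]), 1)
  expect_equal(mg$mode[2], 0)
})
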