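# Shared helpers: random smooth fields, 90-degree lattice rotation with the
# correct tensor/vector transformation rules, and small closed-form
# utilities used across test files.

# Internal helpers exercised directly by the tests.
shift_field <- activenem:::shift_field
lb_moments <- activenem:::lb_moments
coupled_step <- activenem:::coupled_step
initial_state <- activenem:::initial_state

# Random smooth periodic scalar field (band-limited Fourier synthesis).
rand_smooth_field <- function(L, seed, kmax = 4, amp = 1) {
  set.seed(seed)
  f <- matrix(0, L, L)
  x <- matrix(0:(L - 1), L, L)
  y <- t(x)
  for (i in 1:6) {
    n <- sample(-kmax:kmax, 1)
    m <- sample(-kmax:kmax, 1)
    f <- f + stats::rnorm(1, 0, amp) *
      cos(2 * pi * (n * x + m * y) / L + stats::runif(1, 0, 2 * pi))
  }
  f
}

rand_qfield <- function(L, seed, amp = 0.3) {
  nematic_field(rand_smooth_field(L, seed, amp = amp),
                rand_smooth_field(L, seed + 1000, amp = amp))
}

# Lattice rotation by +90 degrees: the rotated field at (x, y) is the
# original at (y, -x).
rot90_scalar <- function(m) t(m[, rev(seq_len(ncol(m))), drop = FALSE])

# Under a +90 degree rotation the director angle shifts by pi/2, so
# (Qxx, Qxy) -> (-Qxx, -Qxy) evaluated at the rotated coordinates.
rot90_qfield <- function(Q) {
  nematic_field(-rot90_scalar(Q$Qxx), -rot90_scalar(Q$Qxy))
}

# Vector field: (vx, vy) -> (-vy, vx) at rotated coordinates.
rot90_vector <- function(vx, vy) {
  list(vx = -rot90_scalar(vy), vy = rot90_scalar(vx))
}

expect_field_equal <- function(a, b, tol = 1e-12) {
  expect_lt(max(abs(a - b)), tol)
}

sort_complex <- function(z) z[order(Re(z), Im(z))]
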