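#' Model parameters for the self-propulsive active nematic
#'
#' Bundles the coefficients of the coupled Beris-Edwards / Navier-Stokes
#' model in lattice units. The defaults are the reference parameter set used
#' throughout the package: `rho = 40`, `eta = 20`, `lam = 0.2`,
#' `Gamma = 0.1`, `K = 0.05`, `A = 0.1`, `zeta = 0.05`, `L = 1024`.
#'
#' @param rho fluid mass density (lattice units). Positive.
#' @param eta dynamic viscosity; the kinematic viscosity seen by the flow
#'   solver is `eta / rho`.
#' @param lam flow-alignment coefficient coupling the order tensor to the
#'   strain rate.
#' @param Gamma rotational mobility: relaxation rate of the order tensor
#'   towards the molecular field.
#' @param K Frank elastic constant (single-constant approximation).
#' @param A bulk free-energy coefficient; `A > 0` selects the ordered state
#'   with `Q_ij Q_ji = 1`, i.e. order magnitude `q = 1/sqrt(2)`.
#' @param zeta dipolar activity coefficient; `zeta > 0` is the extensile
#'   convention used here.
#' @param V0 self-propulsion speed: coefficient of the polar self-advection
#'   `V0 p . grad Q`, with `p` the director sign closest to the local flow.
#' @param L lattice side length in sites (`L >= 8`).
#' @param dt time step of the explicit order-parameter update; the lattice
#'   Boltzmann step is always 1, so `dt` should normally be left at 1.
#' @param seed integer seed for every random initialization derived from
#'   these parameters.
#' @return object of class `"an_params"` (a validated named list).
#' @examples
#' p <- model_params(L = 128, zeta = 0.05, V0 = 0.02)
#' p$eta / p$rho      # kinematic viscosity, 0.5 for the defaults
#' @export
model_params <- function(rho = 40, eta = 20, lam = 0.2, Gamma = 0.1,
                         K = 0.05, A = 0.1, zeta = 0.05, V0 = 0,
                         L = 1024L, dt = 1, seed = 1L) {
  p <- list(rho = rho, eta = eta, lam = lam, Gamma = Gamma, K = K, A = A,
            zeta = zeta, V0 = V0, L = as.integer(L), dt = dt,
            seed = as.integer(seed))
  stopifnot(
    p$rho > 0, p$eta > 0, p$Gamma > 0, p$K > 0, p$A >= 0,
    p$L >= 8L, p$dt > 0, is.finite(p$zeta), is.finite(p$V0)
  )
  class(p) <- "an_params"
  p
}

#' @export
print.an_params <- function(x, ...) {
  cat("Active nematic model parameters (lattice units)\n")
  cat(sprintf("  rho = %g, eta = %g (nu = %g), lam = %g, Gamma = %g\n",
              x$rho, x$eta, x$eta / x$rho, x$lam, x$Gamma))
  cat(sprintf("  K = %g, A = %g, zeta = %g, V0 = %g\n",
              x$K, x$A, x$zeta, x$V0))
  cat(sprintf("  L = %d, dt = %g, seed = %d  (tau_LB = %g)\n",
              x$L, x$dt, x$seed, lb_tau(x)))
  invisible(x)
}

# BGK relaxation time reproducing kinematic viscosity eta/rho with
# c_s^2 = 1/3: tau = 3 eta / rho + 1/2 (2.0 for the defaults).
lb_tau <- function(params) 3 * params$eta / params$rho + 0.5

#' Simulation run configuration
#'
#' Run-control on top of [model_params()]: number of steps, snapshot cadence
#' and the initial condition. Two initial conditions are supported:
#' `"aligned"` (uniform director along x at order magnitude `init_q`, plus
#' uniform random noise of amplitude `noise_amp` on both tensor components,
#' optionally with a single seeded Fourier mode on Qxy for stability probes)
#' and `"random"` (isotropic random tensor of magnitude `noise_amp`).
#'
#' @param params an [model_params()] object.
#' @param n_steps total number of coupled steps to run.
#' @param snapshot_interval interval (steps) between stored snapshots;
#'   must not exceed `n_steps`.
#' @param warmup_steps steps run before the first stored snapshot (the
#'   snapshot clock starts after warmup). Recorded in the trajectory.
#' @param init `"aligned"` or `"random"`.
#' @param init_q order magnitude of the aligned initial state. The default
#'   `NULL` picks the bulk free-energy minimum `1/sqrt(2)` when `A > 0` and
#'   `1` when `A = 0` (any uniform magnitude is then stationary, and 1 is
#'   the base state of the linear theory).
#' @param noise_amp amplitude of the uniform random perturbation added to
#'   both tensor components at initialization.
#' @param perturb_mode optional integer pair `c(n, m)`: seed a single
#'   Fourier mode `cos(2*pi*(n*x + m*y)/L)` on Qxy for stability probes.
#' @param perturb_amp amplitude of the seeded mode.
#' @param mean_vx uniform background flow along x at initialization. A pure
#'   Galilean boost (leaves growth/decay rates unchanged); a small positive
#'   value pins the polarity to `+n` everywhere, realizing the sign
#'   convention of the linear theory, which assumes flow with a positive
#'   x-component.
#' @param q_substeps integer >= 1: sub-cycle the order-parameter update this
#'   many times per lattice Boltzmann step (stability knob; 1 by default).
#' @return object of class `"an_config"`.
#' @export
simulation_config <- function(params, n_steps, snapshot_interval = n_steps,
                              warmup_steps = 0L,
                              init = c("aligned", "random"),
                              init_q = NULL, noise_amp = 0.01,
                              perturb_mode = NULL, perturb_amp = 1e-4,
                              mean_vx = 0, q_substeps = 1L) {
  stopifnot(inherits(params, "an_params"), n_steps >= 1,
            snapshot_interval >= 1, snapshot_interval <= n_steps,
            warmup_steps >= 0, noise_amp >= 0, q_substeps >= 1)
  init <- match.arg(init)
  if (is.null(init_q)) init_q <- if (params$A > 0) 1 / sqrt(2) else 1
  if (!is.null(perturb_mode)) {
    stopifnot(length(perturb_mode) == 2, any(perturb_mode != 0))
  }
  cfg <- list(params = params, n_steps = as.integer(n_steps),
              snapshot_interval = as.integer(snapshot_interval),
              warmup_steps = as.integer(warmup_steps), init = init,
              init_q = init_q, noise_amp = noise_amp,
              perturb_mode = perturb_mode, perturb_amp = perturb_amp,
              mean_vx = mean_vx, q_substeps = as.integer(q_substeps))
  class(cfg) <- "an_config"
  cfg
}

#' @export
print.an_config <- function(x, ...) {
  cat(sprintf("Active nematic run: %d steps (warmup %d), snapshots every %d\n",
              x$n_steps, x$warmup_steps, x$snapshot_interval))
  cat(sprintf("  init = %s (q0 = %.4f, noise %g)", x$init, x$init_q,
              x$noise_amp))
  if (!is.null(x$perturb_mode)) {
    cat(sprintf(", seeded mode (%d,%d) amp %g", x$perturb_mode[1],
                x$perturb_mode[2], x$perturb_amp))
  }
  cat("\n")
  print(x$params)
  invisible(x)
}
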