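# Flow and order statistics: vorticity, isotropically binned kinetic energy
# and enstrophy spectra with power-law fits, real-space vorticity
# correlations (exponent nu, with the Fourier relation nu = b + 1 to the
# small-q enstrophy exponent b), elastic free-energy density, the director
# correlation length, and parallel/perpendicular velocity correlations in
# the frame of the local flow direction.

#' Vorticity of a velocity field
#'
#' `omega = d_x v_y - d_y v_x` by the solver's central differences; the
#' lattice mean vanishes identically on a periodic domain.
#'
#' @param vx,vy velocity matrices.
#' @return vorticity matrix.
#' @export
vorticity <- function(vx, vy) ddx_central(vy) - ddy_central(vx)

# Radial (shell) average of a 2D map indexed by periodic offsets: returns
# the mean of map values over offsets with round(|r|) == r for integer r.
radial_profile <- function(C2d, r_max = floor(nrow(C2d) / 2)) {
  L1 <- nrow(C2d); L2 <- ncol(C2d)
  dx <- pmin(0:(L1 - 1), L1 - (0:(L1 - 1)))
  dy <- pmin(0:(L2 - 1), L2 - (0:(L2 - 1)))
  rr <- round(sqrt(outer(dx^2, dy^2, `+`)))
  keep <- rr <= r_max
  prof <- tapply(C2d[keep], rr[keep], mean)
  data.frame(r = as.integer(names(prof)), value = as.numeric(prof))
}

# Isotropic shell spectrum of one or two scalar fields: sum of
# |fft|^2 / (2 L^4) over integer shells of the normalized wavenumber
# |k| L / (2 pi). Shell 0 is the mean-flow term; the shells sum to half the
# lattice-mean square of the field(s) (Parseval).
scalar_spectrum <- function(fields) {
  L <- nrow(fields[[1]])
  P <- Reduce(`+`, lapply(fields, function(f) Mod(stats::fft(f))^2))
  P <- P / (2 * L^4)
  idx <- c(0:(L %/% 2), if (L > 1) -((L - L %/% 2 - 1):1))
  shell <- round(sqrt(outer(idx^2, idx^2, `+`)))
  vals <- tapply(P, shell, sum)
  data.frame(q = as.integer(names(vals)), value = as.numeric(vals))
}

spectrum_result <- function(df, total, fit_range, kind) {
  sel <- df$q > fit_range[1] & df$q <= fit_range[2] & df$value > 0
  fit <- NULL
  if (sum(sel) >= 3) {
    lmfit <- stats::lm(log(df$value[sel]) ~ log(df$q[sel]))
    fit <- list(exponent = unname(stats::coef(lmfit)[2]),
                se = sqrt(stats::vcov(lmfit)[2, 2]),
                q_range = fit_range, n_bins = sum(sel))
  }
  structure(list(q = df$q, values = df$value, total = total,
                 fit = fit, kind = kind),
            class = "an_spectrum")
}

#' @export
print.an_spectrum <- function(x, ...) {
  cat(sprintf("%s spectrum: %d shells, total %.4e", x$kind,
              length(x$q), x$total))
  if (!is.null(x$fit)) {
    cat(sprintf("; exponent %.3f +- %.3f over q in (%g, %g]",
                x$fit$exponent, x$fit$se, x$fit$q_range[1], x$fit$q_range[2]))
  }
  cat("\n")
  invisible(x)
}

#' Kinetic energy spectrum
#'
#' Isotropic shell binning of `|v(q)|^2`, wavenumber normalized by the
#' smallest wavevector `2 pi / L` (so shell 1 is the box mode). The shell
#' values sum to the mean kinetic energy density per unit mass
#' `<|v|^2>/2` (Parseval). A power law `E(q) ~ q^beta` is fitted over
#' normalized `q` in `fit_range` (default `(1, L/8]`, the small-scale
#' branch).
#'
#' @param vx,vy velocity matrices, or lists of matrices (snapshot
#'   averaging of the spectrum before fitting).
#' @param fit_range normalized wavenumber window for the exponent fit.
#' @return object of class `"an_spectrum"` with `q`, `values`, `total` and
#'   `fit` (`exponent`, `se`, `q_range`).
#' @export
energy_spectrum <- function(vx, vy, fit_range = NULL) {
  if (!is.list(vx)) { vx <- list(vx); vy <- list(vy) }
  L <- nrow(vx[[1]])
  if (is.null(fit_range)) fit_range <- c(1, L / 8)
  dfs <- mapply(function(a, b) scalar_spectrum(list(a, b)),
                vx, vy, SIMPLIFY = FALSE)
  df <- dfs[[1]]
  if (length(dfs) > 1) {
    df$value <- rowMeans(sapply(dfs, `[[`, "value"))
  }
  total <- mean(vapply(seq_along(vx),
                       function(i) mean(vx[[i]]^2 + vy[[i]]^2) / 2,
                       numeric(1)))
  spectrum_result(df, total, fit_range, "kinetic energy")
}

#' Enstrophy spectrum
#'
#' Shell spectrum of `|omega(q)|^2` with `omega` from [vorticity()]; the
#' shells sum to half the mean squared vorticity. The small-q exponent `b`
#' (fitted over `fit_range`, default normalized `q` in `(1, 8]`) is related
#' to the real-space vorticity correlation decay by `nu = b + 1`.
#'
#' @inheritParams energy_spectrum
#' @return an `"an_spectrum"`.
#' @export
enstrophy_spectrum <- function(vx, vy, fit_range = c(1, 8)) {
  if (!is.list(vx)) { vx <- list(vx); vy <- list(vy) }
  om <- mapply(function(a, b) vorticity(a, b), vx, vy, SIMPLIFY = FALSE)
  dfs <- lapply(om, function(o) scalar_spectrum(list(o)))
  df <- dfs[[1]]
  if (length(dfs) > 1) df$value <- rowMeans(sapply(dfs, `[[`, "value"))
  total <- mean(vapply(om, function(o) mean(o^2) / 2, numeric(1)))
  spectrum_result(df, total, fit_range, "enstrophy")
}

# FFT autocorrelation of a (mean-removed, optionally) field, radially
# averaged: <f(x) f(x + r)> as a function of integer r.
fft_autocorr_radial <- function(field, remove_mean = TRUE,
                                r_max = floor(nrow(field) / 2)) {
  if (remove_mean) field <- field - mean(field)
  Fh <- stats::fft(field)
  C <- Re(stats::fft(Mod(Fh)^2, inverse = TRUE)) / length(field)^2
  radial_profile(C, r_max)
}

#' Real-space vorticity correlation and decay exponent
#'
#' Two-point correlation `<omega(x) omega(x + r)>` (spatial mean removed,
#' which the periodic domain makes zero anyway; a zero-variance field is
#' rejected), radially averaged via FFT and normalized to `C(0) = 1`,
#' averaged over snapshots. The large-distance decay exponent `nu`
#' (`C(r) ~ r^-nu`) is fitted on the positive part of the curve over
#' `r` in `fit_range` (default `[L/8, L/3]`).
#'
#' @param omega vorticity matrix or list of matrices (snapshots).
#' @param fit_range distance window for the `nu` fit.
#' @return object of class `"an_corr"`: list with `r`, `C`, `nu`, `nu_se`,
#'   `fit_range`.
#' @export
vorticity_correlation <- function(omega, fit_range = NULL) {
  if (!is.list(omega)) omega <- list(omega)
  L <- nrow(omega[[1]])
  if (is.null(fit_range)) fit_range <- c(L / 8, L / 3)
  profs <- lapply(omega, fft_autocorr_radial)
  C <- rowMeans(sapply(profs, `[[`, "value"))
  if (C[1] <= 0) stop("degenerate input: vorticity field has zero variance")
  r <- profs[[1]]$r
  Cn <- C / C[1]
  sel <- r >= fit_range[1] & r <= fit_range[2] & Cn > 0
  nu <- NA_real_; se <- NA_real_
  if (sum(sel) >= 3) {
    fit <- stats::lm(log(Cn[sel]) ~ log(r[sel]))
    nu <- -unname(stats::coef(fit)[2])
    se <- sqrt(stats::vcov(fit)[2, 2])
  }
  structure(list(r = r, C = Cn, nu = nu, nu_se = se, fit_range = fit_range),
            class = "an_corr")
}

#' Elastic free-energy density summary
#'
#' Per snapshot, the elastic energy field is normalized by its spatial
#' maximum; the summary `rho_e` is the lattice-and-snapshot average of
#' `E / max(E)`, a dimensionless measure of how sharply distortion energy
#' is localized (small when energy is concentrated at defect cores).
#'
#' @param Q an [nematic_field()] or list of them.
#' @param K Frank elastic constant.
#' @return `rho_e` (numeric scalar in (0, 1]).
#' @export
elastic_energy_summary <- function(Q, K) {
  if (inherits(Q, "an_qfield")) Q <- list(Q)
  vals <- vapply(Q, function(qf) {
    E <- elastic_energy_density(qf, K)
    mx <- max(E)
    if (mx <= 0) stop("degenerate input: uniform field has zero elastic energy")
    mean(E / mx)
  }, numeric(1))
  mean(vals)
}

#' Director autocorrelation and correlation length
#'
#' Nematic-invariant correlation
#' `C(r) = <Q(x) : Q(x + r)> / <Q : Q>` (equal to the order-weighted
#' `<cos 2 dtheta>`), radially averaged via FFT and averaged over
#' snapshots. The correlation length `l_c` is the first crossing of
#' `1/e`, linearly interpolated; if the curve never crosses, `l_c = L/2`
#' and `crossed = FALSE`.
#'
#' @param Q an [nematic_field()] or list of them.
#' @return object of class `"an_corr"`: list with `r`, `C`, `l_c`,
#'   `crossed`.
#' @export
director_correlation <- function(Q) {
  if (inherits(Q, "an_qfield")) Q <- list(Q)
  L <- nrow(Q[[1]]$Qxx)
  profs <- lapply(Q, function(qf) {
    pxx <- fft_autocorr_radial(qf$Qxx, remove_mean = FALSE)
    pxy <- fft_autocorr_radial(qf$Qxy, remove_mean = FALSE)
    pxx$value + pxy$value        # ~ Q:Q / 2; normalization cancels
  })
  C <- rowMeans(do.call(cbind, profs))
  r <- 0:(length(C) - 1)
  Cn <- C / C[1]
  cross <- first_crossing(r, Cn, exp(-1))
  structure(list(r = r, C = Cn,
                 l_c = if (is.na(cross)) L / 2 else cross,
                 crossed = !is.na(cross)),
            class = "an_corr")
}

#' @export
print.an_corr <- function(x, ...) {
  if (!is.null(x$l_c)) {
    cat(sprintf("Correlation curve (%d radii): l_c = %.2f%s\n", length(x$r),
                x$l_c, if (isFALSE(x$crossed)) " (no 1/e crossing)" else ""))
  } else {
    cat(sprintf("Correlation curve (%d radii): nu = %.3f +- %.3f\n",
                length(x$r), x$nu, x$nu_se))
  }
  invisible(x)
}

# First r at which curve falls below level, linearly interpolated; NA if it
# never does.
first_crossing <- function(r, C, level) {
  below <- which(C < level)
  below <- below[below > 1]
  if (length(below) == 0) return(NA_real_)
  i <- below[1]
  r[i - 1] + (C[i - 1] - level) / (C[i - 1] - C[i]) * (r[i] - r[i - 1])
}

#' Velocity correlations parallel and perpendicular to the local flow
#'
#' For sampled reference sites, the velocity field is decomposed in the
#' frame of the flow direction at the reference site
#' (`v_par = e . v`, `v_perp = e_perp . v` with `e = v(x0)/|v(x0)|`), and
#' the autocorrelations of both component fields are radially averaged and
#' then averaged over reference sites and snapshots (each site's curves are
#' normalized at r = 0 first). Correlation lengths `l_par`, `l_perp` are
#' `1/e` crossings; a positive difference `l_par - l_perp` signals broken
#' rotational symmetry of the flow.
#'
#' Implementation note: rotating components commutes with radial averaging,
#' so the per-site curves are linear combinations (via the frame angle) of
#' the three FFT cross-correlation profiles of (vx, vy), computed once per
#' snapshot.
#'
#' @param vx,vy velocity matrices or lists of matrices (snapshots).
#' @param n_ref reference sites sampled per snapshot.
#' @param seed seed for the reference-site sampling.
#' @return list with `r`, `C_par`, `C_perp`, `l_par`, `l_perp`, `delta_l`.
#' @export
anisotropy_correlations <- function(vx, vy, n_ref = 256L, seed = 1L) {
  if (!is.list(vx)) { vx <- list(vx); vy <- list(vy) }
  L <- nrow(vx[[1]])
  set.seed(seed)
  acc_par <- NULL
  acc_perp <- NULL
  n_acc <- 0L
  for (s in seq_along(vx)) {
    a <- vx[[s]]; b <- vy[[s]]
    Fa <- stats::fft(a); Fb <- stats::fft(b)
    n2 <- length(a)^2
    Axx <- radial_profile(Re(stats::fft(Mod(Fa)^2, inverse = TRUE)) / n2)
    Ayy <- radial_profile(Re(stats::fft(Mod(Fb)^2, inverse = TRUE)) / n2)
    Axy <- radial_profile(Re(stats::fft(Conj(Fa) * Fb +
                                          Conj(Fb) * Fa, inverse = TRUE)) / n2)
    ii <- sample.int(L, n_ref, replace = TRUE)
    jj <- sample.int(L, n_ref, replace = TRUE)
    for (k in seq_len(n_ref)) {
      v0x <- a[ii[k], jj[k]]; v0y <- b[ii[k], jj[k]]
      vm <- sqrt(v0x^2 + v0y^2)
      if (vm < 1e-14) next
      cpsi <- v0x / vm; spsi <- v0y / vm
      cp <- cpsi^2 * Axx$value + spsi^2 * Ayy$value +
        cpsi * spsi * Axy$value
      cq <- spsi^2 * Axx$value + cpsi^2 * Ayy$value -
        cpsi * spsi * Axy$value
      if (cp[1] <= 0 || cq[1] <= 0) next
      if (is.null(acc_par)) {
        acc_par <- cp / cp[1]
        acc_perp <- cq / cq[1]
      } else {
        acc_par <- acc_par + cp / cp[1]
        acc_perp <- acc_perp + cq / cq[1]
      }
      n_acc <- n_acc + 1L
    }
  }
  if (n_acc == 0) stop("no usable reference sites (velocity everywhere ~0)")
  C_par <- acc_par / n_acc
  C_perp <- acc_perp / n_acc
  r <- Axx$r
  l_par <- first_crossing(r, C_par, exp(-1))
  l_perp <- first_crossing(r, C_perp, exp(-1))
  if (is.na(l_par)) l_par <- L / 2
  if (is.na(l_perp)) l_perp <- L / 2
  list(r = r, C_par = C_par, C_perp = C_perp,
       l_par = l_par, l_perp = l_perp, delta_l = l_par - l_perp)
}

#' Write a correlation or spectrum curve to CSV
#'
#' @param obj an `"an_corr"`, `"an_spectrum"`, `"an_sq"` or `"an_nvar"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(obj, path) {
  df <- if (inherits(obj, "an_spectrum")) {
    data.frame(q = obj$q, value = obj$values)
  } else if (inherits(obj, "an_sq")) {
    data.frame(q = obj$q_bins, S = obj$S_values, n_modes = obj$n_modes)
  } else if (inherits(obj, "an_nvar")) {
    data.frame(R = obj$radii, mean_n = obj$mean_n, var_n = obj$var_n)
  } else {
    data.frame(r = obj$r, C = obj$C)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
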