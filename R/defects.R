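# Topological defect detection and hyperuniformity statistics: winding
# numbers on plaquettes, structure factor of point patterns, small-q scaling
# exponent alpha, and number variance / giant-number-fluctuation exponent
# beta with the map beta = 0.5 (1 - alpha/d), d = 2.

# Fold a nematic angle difference into (-pi/2, pi/2].
fold_nematic <- function(d) d - pi * round(d / pi)

#' Detect half-integer defects from the director field
#'
#' Accumulates the nematic winding of the director angle around every unit
#' plaquette (angle differences folded into (-pi/2, pi/2], periodic wrap
#' included). A winding of +-pi marks a +-1/2 defect at the plaquette
#' center. No sub-pixel refinement is applied: positions are plaquette
#' centers (site coordinates run 0..L-1, centers at +1/2).
#'
#' @param Q an [nematic_field()].
#' @return object of class `"an_defects"`: data frame with columns `x`, `y`,
#'   `charge`; attribute `L` carries the lattice size.
#' @export
detect_defects <- function(Q) {
  th <- decompose_q(Q)$theta
  # corners of plaquette (i, j): a = (i,j), b = (i+1,j), c = (i+1,j+1),
  # d = (i,j+1); winding = sum of folded differences around the loop
  b <- shift_field(th, 1L, 0L)
  cc <- shift_field(th, 1L, 1L)
  d <- shift_field(th, 0L, 1L)
  w <- fold_nematic(b - th) + fold_nematic(cc - b) +
    fold_nematic(d - cc) + fold_nematic(th - d)
  idx <- which(abs(w) > pi / 2, arr.ind = TRUE)
  res <- data.frame(
    x = idx[, 1] - 1 + 0.5,
    y = idx[, 2] - 1 + 0.5,
    charge = round(w[idx] / pi) / 2
  )
  res <- res[res$charge != 0, , drop = FALSE]
  rownames(res) <- NULL
  structure(res, L = nrow(th), class = c("an_defects", "data.frame"))
}

#' @export
print.an_defects <- function(x, ...) {
  cat(sprintf("%d defects (%d x +1/2, %d x -1/2), net charge %g\n",
              nrow(x), sum(x$charge > 0), sum(x$charge < 0), sum(x$charge)))
  if (nrow(x) > 0) print.data.frame(utils::head(x, 6))
  invisible(x)
}

#' Write a defect list to CSV
#' @param defects an `"an_defects"` object (or a list of them, written with
#'   a snapshot index column).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_defects_csv <- function(defects, path) {
  if (inherits(defects, "an_defects")) defects <- list(defects)
  rows <- do.call(rbind, lapply(seq_along(defects), function(i) {
    d <- as.data.frame(defects[[i]])
    if (nrow(d) > 0) cbind(t = i, d) else NULL
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Structure factor of a point pattern
#'
#' `S(q) = |sum_j exp(-i q . r_j)|^2 / N` on the allowed wavevectors
#' `q = (2 pi / L)(n, m)`, `q != 0`, `|q| <= q_upper`, averaged over
#' orientations by binning on `|q|` (bin width `2 pi / L`) and over
#' snapshots when `points` is a list of point sets. The `1/N` normalization
#' makes the Poisson expectation 1.
#'
#' @param points two-column matrix (x, y) of point positions in `[0, L)`,
#'   or a list of such matrices (time average).
#' @param L box side length.
#' @param q_upper retain only `|q| <= q_upper` (default 1/4).
#' @return object of class `"an_sq"`: list with `q_bins` (bin centers),
#'   `S_values`, `n_modes` (Fourier modes per bin, summed over snapshots)
#'   and `q_upper`.
#' @export
structure_factor <- function(points, L, q_upper = 0.25) {
  if (!is.list(points)) points <- list(points)
  points <- lapply(points, function(p) {
    p <- as.matrix(p)
    stopifnot(ncol(p) == 2)
    p
  })
  if (any(vapply(points, nrow, 1L) < 1)) stop("empty point set")
  if (length(points) == 1 && nrow(points[[1]]) < 2) {
    warning("structure factor of a single point is identically 1")
  }
  dq <- 2 * pi / L
  nmax <- floor(q_upper / dq)
  if (nmax < 1) stop("q_upper below the smallest allowed wavevector 2*pi/L")
  nm <- expand.grid(n = -nmax:nmax, m = 0:nmax)
  nm <- nm[!(nm$m == 0 & nm$n <= 0), , drop = FALSE]  # half-plane: S(-q)=S(q)
  qx <- dq * nm$n
  qy <- dq * nm$m
  qnorm <- sqrt(qx^2 + qy^2)
  keep <- qnorm <= q_upper
  qx <- qx[keep]; qy <- qy[keep]; qnorm <- qnorm[keep]

  Sacc <- numeric(length(qx))
  for (p in points) {
    # chunk the mode axis to bound the N x modes phase matrix memory
    chunks <- split(seq_along(qx), ceiling(seq_along(qx) / 256))
    for (ch in chunks) {
      ph <- exp(-1i * (outer(p[, 1], qx[ch]) + outer(p[, 2], qy[ch])))
      Sacc[ch] <- Sacc[ch] + (Mod(colSums(ph))^2) / nrow(p)
    }
  }
  Smode <- Sacc / length(points)

  bin <- round(qnorm / dq)
  q_bins <- sort(unique(bin)) * dq
  S_values <- as.numeric(tapply(Smode, bin, mean))
  n_modes <- as.integer(tapply(Smode, bin, length)) * length(points)
  structure(list(q_bins = q_bins, S_values = S_values, n_modes = n_modes,
                 q_upper = q_upper),
            class = "an_sq")
}

#' @export
print.an_sq <- function(x, ...) {
  cat(sprintf("Structure factor: %d |q| bins up to %.3f; S in [%.3g, %.3g]\n",
              length(x$q_bins), x$q_upper, min(x$S_values), max(x$S_values)))
  invisible(x)
}

#' Small-q scaling exponent of the structure factor
#'
#' Fits `S(q) ~ q^alpha` by least squares on log S versus log q over the
#' lowest decade of retained wavevectors (or an explicit `q_range`).
#'
#' @param est an `"an_sq"` from [structure_factor()].
#' @param q_range optional `c(min, max)`; default is the lowest decade
#'   `[q_min, 10 q_min]`.
#' @return list with `alpha`, `se`, `ci` (95%), `n_bins` and the fitted
#'   range.
#' @export
fit_alpha <- function(est, q_range = NULL) {
  if (is.null(q_range)) q_range <- c(min(est$q_bins), 10 * min(est$q_bins))
  sel <- est$q_bins >= q_range[1] & est$q_bins <= q_range[2] &
    est$S_values > 0
  if (sum(sel) < 5) stop("fewer than 5 bins in the fit range")
  fit <- stats::lm(log(est$S_values[sel]) ~ log(est$q_bins[sel]))
  alpha <- unname(stats::coef(fit)[2])
  se <- sqrt(stats::vcov(fit)[2, 2])
  list(alpha = alpha, se = se, ci = alpha + c(-1.96, 1.96) * se,
       n_bins = sum(sel), q_range = q_range)
}

#' Number variance over randomly placed circular windows
#'
#' Estimates the moments of `N(R)`, the count of points inside a circular
#' window of radius `R` placed uniformly at random (periodic minimum-image
#' distances), for `n_radii` radii log-spaced in `[L/100, L/10]`. The
#' giant-number-fluctuation exponent `beta` is the log-log slope of the
#' standard deviation `sigma_N(R)` against the mean `<N(R)>`
#' (`sigma_N ~ <N>^beta`; 1/2 for uniform systems, `0.5 (1 - alpha/2)`
#' through the structure-factor exponent).
#'
#' @param points two-column matrix or list of matrices (snapshots; each
#'   snapshot gets its own windows and the moments pool all windows).
#' @param L box side length.
#' @param n_windows random windows per snapshot (default 1e4).
#' @param n_radii number of radii (default 25).
#' @param radii optional explicit radii (sorted increasing).
#' @param seed RNG seed for window placement.
#' @return object of class `"an_nvar"`: list with `radii`, `mean_n`,
#'   `var_n`, `beta`, `beta_se`, `beta_ci`.
#' @export
number_variance <- function(points, L, n_windows = 10000L, n_radii = 25L,
                            radii = NULL, seed = 1L) {
  if (!is.list(points)) points <- list(points)
  if (is.null(radii)) {
    radii <- exp(seq(log(L / 100), log(L / 10), length.out = n_radii))
  }
  radii <- sort(radii)
  set.seed(seed)
  nsum <- numeric(length(radii))
  n2sum <- numeric(length(radii))
  total <- 0L
  for (p in points) {
    p <- as.matrix(p)
    cx <- stats::runif(n_windows, 0, L)
    cy <- stats::runif(n_windows, 0, L)
    counts <- cpp_count_in_windows(p[, 1], p[, 2], cx, cy, L, radii)
    nsum <- nsum + colSums(counts)
    n2sum <- n2sum + colSums(counts^2)
    total <- total + n_windows
  }
  mean_n <- nsum / total
  var_n <- n2sum / total - mean_n^2
  ok <- mean_n > 0 & var_n > 0
  fit <- stats::lm(log(sqrt(var_n[ok])) ~ log(mean_n[ok]))
  beta <- unname(stats::coef(fit)[2])
  se <- sqrt(stats::vcov(fit)[2, 2])
  structure(list(radii = radii, mean_n = mean_n, var_n = var_n,
                 beta = beta, beta_se = se,
                 beta_ci = beta + c(-1.96, 1.96) * se),
            class = "an_nvar")
}

#' @export
print.an_nvar <- function(x, ...) {
  cat(sprintf(
    "Number variance over %d radii in [%.2f, %.2f]: beta = %.3f +- %.3f\n",
    length(x$radii), min(x$radii), max(x$radii), x$beta, x$beta_se))
  invisible(x)
}

#' Exponent map between structure factor and number fluctuations
#'
#' `beta = 0.5 (1 - alpha / d)` with spatial dimension `d = 2`:
#' anti-hyperuniform patterns (`alpha < 0`) show giant number fluctuations
#' (`beta > 1/2`), hyperuniform ones (`alpha > 0`) suppressed fluctuations.
#'
#' @param alpha small-q structure-factor exponent.
#' @param d spatial dimension (default 2).
#' @return the corresponding `beta`.
#' @export
beta_from_alpha <- function(alpha, d = 2) 0.5 * (1 - alpha / d)
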