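#' Configuration of the three-point Dixon fitter
#'
#' @param echo_indices Three distinct 1-based indices into the protocol's
#'   echo train; the default `c(2, 4, 6)` selects the second, fourth and
#'   sixth echoes of the 10-echo GRE train (TE 4.76, 9.53, 14.29 ms).
#' @param psi_grid_points Number of grid points for the initial
#'   field-frequency search over one aliasing period (>= 64; the default
#'   384 resolves the closely spaced true and swapped minima).
#' @param refine_tol_hz Width (Hz) at which the golden-section refinement
#'   of the field frequency stops.
#' @return A list of class `hf_dixon_config`.
#' @export
dixon_config <- function(echo_indices = c(2L, 4L, 6L),
                         psi_grid_points = 384L, refine_tol_hz = 1e-6) {
  echo_indices <- as.integer(echo_indices)
  if (length(echo_indices) != 3L || anyDuplicated(echo_indices) ||
      any(echo_indices < 1L)) {
    stop("echo_indices must be three distinct positive indices",
         call. = FALSE)
  }
  if (psi_grid_points < 64L) {
    stop("psi_grid_points must be at least 64", call. = FALSE)
  }
  structure(list(echo_indices = echo_indices,
                 psi_grid_points = as.integer(psi_grid_points),
                 refine_tol_hz = refine_tol_hz),
            class = "hf_dixon_config")
}

# Orthonormal basis of span{1, e^{-j2pi df t}} in C^3 (Gram-Schmidt).
.dixon_basis <- function(times, fat_shift_hz) {
  a1 <- rep(1 + 0i, 3)
  a2 <- exp(-2i * pi * fat_shift_hz * times)
  q1 <- a1 / sqrt(3)
  p <- a2 - q1 * sum(Conj(q1) * a2)
  q2 <- p / sqrt(sum(Mod(p)^2))
  cbind(q1, q2)
}

# Captured energy |Q^H z|^2 for every voxel (rows of Y) at one shared
# field frequency psi.
.dixon_energy <- function(Y, psi, times, Q) {
  ph <- exp(2i * pi * psi * times)
  Z <- Y * matrix(ph, nrow(Y), length(times), byrow = TRUE)
  P <- Z %*% Conj(Q)
  rowSums(Mod(P)^2)
}

# Refine one field-frequency candidate per voxel: golden-section on the
# captured energy inside [psi0 - step, psi0 + step], then Gauss-Newton
# polish of psi on the full residual (amplitudes resolved exactly at
# each step; the projected-energy surface is too flat near its maximum
# for bracketing alone to reach machine precision).
.dixon_refine <- function(Y, psi0, step, times, Q, E, s, config) {
  gr <- (sqrt(5) - 1) / 2
  lo <- psi0 - step
  hi <- psi0 + step
  x1 <- hi - gr * (hi - lo)
  x2 <- lo + gr * (hi - lo)
  f1 <- .dixon_energy_vec(Y, x1, times, Q)
  f2 <- .dixon_energy_vec(Y, x2, times, Q)
  while (max(hi - lo) > max(config$refine_tol_hz, 1e-9)) {
    take2 <- f2 >= f1
    lo[take2] <- x1[take2]
    x1[take2] <- x2[take2]
    f1[take2] <- f2[take2]
    x2[take2] <- lo[take2] + gr * (hi[take2] - lo[take2])
    f2[take2] <- .dixon_energy_vec(Y[take2, , drop = FALSE], x2[take2],
                                   times, Q)
    t1 <- !take2
    hi[t1] <- x2[t1]
    x2[t1] <- x1[t1]
    f2[t1] <- f1[t1]
    x1[t1] <- hi[t1] - gr * (hi[t1] - lo[t1])
    f1[t1] <- .dixon_energy_vec(Y[t1, , drop = FALSE], x1[t1], times, Q)
  }
  psi <- (lo + hi) / 2

  amp <- .dixon_amp_rows(Y, psi, times, E, s)
  det_g <- 9 - Mod(s)^2
  for (it in 1:40) {
    r <- Y - amp$fit
    J <- sweep(amp$fit, 2L, -2i * pi * times, `*`)
    # reduced (variable-projection) Jacobian: remove the component of J
    # lying in the span of the amplitude basis, otherwise the step is
    # damped by orders of magnitude along the shallow swap valley
    ph <- exp(-2i * pi * outer(psi, times))
    U1 <- ph
    U2 <- sweep(ph, 2L, E, `*`)
    p1 <- rowSums(Conj(U1) * J)
    p2 <- rowSums(Conj(U2) * J)
    g1 <- (3 * p1 - s * p2) / det_g
    g2 <- (3 * p2 - Conj(s) * p1) / det_g
    Jp <- J - g1 * U1 - g2 * U2
    denom <- rowSums(Mod(Jp)^2)
    dpsi <- rowSums(Re(Conj(Jp) * r)) / pmax(denom, .Machine$double.xmin)
    if (all(abs(dpsi) < 1e-12)) break
    psi_new <- psi + dpsi
    amp_new <- .dixon_amp_rows(Y, psi_new, times, E, s)
    worse <- amp_new$rss > amp$rss
    if (any(worse)) {              # keep the bracketed solution there
      psi_new[worse] <- psi[worse]
      amp_new$W[worse] <- amp$W[worse]
      amp_new$F[worse] <- amp$F[worse]
      amp_new$fit[worse, ] <- amp$fit[worse, , drop = FALSE]
      amp_new$rss[worse] <- amp$rss[worse]
    }
    psi <- psi_new; amp <- amp_new
  }
  list(psi = psi, W = amp$W, F = amp$F, rss = amp$rss)
}

# Core variable-projection solve: grid over psi in (-|df|/2, |df|/2],
# refinement of the top separated grid candidates (the water-fat swap
# creates a second, nearly-as-deep basin a few Hz away), lowest-residual
# winner with ties toward smaller |psi|. Y: n x 3 complex matrix.
.dixon_fit_rows <- function(Y, times, fat_shift_hz, config,
                            n_candidates = 4L) {
  n <- nrow(Y)
  Q <- .dixon_basis(times, fat_shift_hz)
  E <- exp(-2i * pi * fat_shift_hz * times)
  s <- sum(E)                      # <1, E>
  half <- abs(fat_shift_hz) / 2
  k <- config$psi_grid_points
  grid <- seq(-half, half, length.out = k + 1L)[-1L]
  step <- grid[2] - grid[1]

  energy <- matrix(0, n, k)
  for (j in seq_len(k)) {
    energy[, j] <- .dixon_energy(Y, grid[j], times, Q)
  }

  psi <- numeric(n); W <- complex(n); F <- complex(n)
  rss <- rep(Inf, n)
  e <- energy
  for (cand in seq_len(n_candidates)) {
    idx <- max.col(e, ties.method = "first")
    # suppress the immediate neighbourhood (the swapped basin can sit
    # only a few Hz away and must stay available as its own candidate)
    for (d in -3:3) {
      j <- pmin(pmax(idx + d, 1L), k)
      e[cbind(seq_len(n), j)] <- -Inf
    }
    ref <- .dixon_refine(Y, grid[idx], step, times, Q, E, s, config)
    better <- ref$rss < rss - 1e-14 |
      (abs(ref$rss - rss) <= 1e-14 & abs(ref$psi) < abs(psi))
    psi[better] <- ref$psi[better]
    W[better] <- ref$W[better]
    F[better] <- ref$F[better]
    rss[better] <- ref$rss[better]
  }
  resid <- sqrt(pmax(rss, 0))

  degenerate <- rowSums(Mod(Y)^2) == 0
  psi[degenerate] <- 0
  W[degenerate] <- 0i
  F[degenerate] <- 0i
  resid[degenerate] <- 0
  list(rho_w = Mod(W), rho_f = Mod(F), psi = psi,
       residual = resid, degenerate = degenerate)
}

# closed-form amplitude solve + fitted model at per-voxel psi
.dixon_amp_rows <- function(Y, psi, times, E, s) {
  Z <- Y * exp(2i * pi * outer(psi, times))
  b1 <- rowSums(Z)
  b2 <- as.vector(Z %*% Conj(E))
  det <- 9 - Mod(s)^2
  W <- (3 * b1 - s * b2) / det
  F <- (3 * b2 - Conj(s) * b1) / det
  fit <- (outer(W, rep(1 + 0i, 3)) + outer(F, E)) *
    exp(-2i * pi * outer(psi, times))
  list(W = W, F = F, fit = fit, rss = rowSums(Mod(Y - fit)^2))
}

# per-voxel psi variant (psi same length as nrow(Y)); empty input safe
.dixon_energy_vec <- function(Y, psi, times, Q) {
  if (length(psi) == 0L) return(numeric(0))
  Z <- Y * exp(2i * pi * outer(psi, times))
  P <- Z %*% Conj(Q)
  rowSums(Mod(P)^2)
}

#' Three-point Dixon fit of a single voxel
#'
#' Minimises \eqn{\sum_i |y_i - (\rho_w + \rho_f e^{-j 2\pi \Delta f t_i})
#' e^{-j 2\pi \psi t_i}|^2} over complex water/fat amplitudes and the
#' field frequency \eqn{\psi}, with R2* fixed at zero. \eqn{\psi} is
#' searched over one aliasing period \eqn{(-|\Delta f|/2, |\Delta f|/2]}
#' by a grid followed by golden-section refinement (ties toward smaller
#' \eqn{|\psi|}); amplitudes are then the exact linear least-squares
#' solution and their magnitudes are reported.
#'
#' @param signal Complex vector of length 3.
#' @param times Echo times in seconds, strictly increasing, length 3.
#' @param fat_shift_hz Fat chemical shift in Hz.
#' @param config An `hf_dixon_config`.
#' @return List with `rho_w`, `rho_f`, `psi_hz`, `residual`, `degenerate`
#'   (all-zero input flag) and `pdff`.
#' @export
dixon_fit_voxel <- function(signal, times, fat_shift_hz = 217,
                            config = dixon_config()) {
  signal <- as.complex(signal)
  times <- as.numeric(times)
  if (length(signal) != 3L || length(times) != 3L) {
    stop("three-point Dixon needs exactly 3 echoes", call. = FALSE)
  }
  if (any(!is.finite(Re(signal))) || any(!is.finite(Im(signal)))) {
    stop("signal must be finite", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("echo times must be strictly increasing", call. = FALSE)
  }
  f <- .dixon_fit_rows(matrix(signal, 1L, 3L), times, fat_shift_hz, config)
  list(rho_w = f$rho_w, rho_f = f$rho_f, psi_hz = f$psi,
       residual = f$residual, degenerate = f$degenerate,
       pdff = pdff_from_components(f$rho_w, f$rho_f))
}

#' Three-point Dixon PDFF map
#'
#' Applies [dixon_fit_voxel()] to every voxel inside the mask (taken from
#' the embedded ground truth if present, otherwise the whole frame) using
#' the three configured echoes of the acquisition, and derives
#' \eqn{PDFF = |\rho_f| / (|\rho_w| + |\rho_f|)} per voxel.
#'
#' @param image An `hf_multiecho` acquisition.
#' @param config An `hf_dixon_config`; echo indices are 1-based into the
#'   protocol's echo train.
#' @return An object of class `hf_pdff_map` with fields `pdff`, `psi_hz`,
#'   `residual`, `mask`, `method = "dixon"` (no R2* map: the three-point
#'   method neglects decay).
#' @export
dixon_pdff_map <- function(image, config = dixon_config()) {
  stopifnot(inherits(image, "hf_multiecho"))
  idx <- config$echo_indices
  n_echo <- dim(image$data)[3]
  if (max(idx) > n_echo) {
    stop(sprintf("echo index %d out of range (%d echoes)", max(idx), n_echo),
         call. = FALSE)
  }
  times <- image$protocol$echo_times[idx]
  dims <- dim(image$data)[1:2]
  mask <- if (!is.null(image$truth)) image$truth$mask else
    matrix(TRUE, dims[1], dims[2])

  flat <- matrix(image$data, prod(dims), n_echo)
  Y <- flat[as.vector(mask), idx, drop = FALSE]
  f <- .dixon_fit_rows(Y, times, image$protocol$fat_shift_hz, config)

  pdff <- matrix(0, dims[1], dims[2])
  psi <- matrix(0, dims[1], dims[2])
  resid <- matrix(0, dims[1], dims[2])
  pdff[mask] <- pdff_from_components(f$rho_w, f$rho_f)
  psi[mask] <- f$psi
  resid[mask] <- f$residual
  structure(list(pdff = pdff, r2star = NULL, psi_hz = psi,
                 residual = resid, mask = mask, method = "dixon"),
            class = "hf_pdff_map")
}
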