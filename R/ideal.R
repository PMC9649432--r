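#' Fat fraction from water and fat amplitude magnitudes
#'
#' \eqn{PDFF = |\rho_f| / (|\rho_w| + |\rho_f|)}, defined as 0 when both
#' amplitudes are 0. Vectorised.
#'
#' @param rho_w,rho_f Non-negative amplitude magnitudes.
#' @return Fat fraction(s) in \eqn{[0, 1]}.
#' @export
pdff_from_components <- function(rho_w, rho_f) {
  rho_w <- abs(rho_w); rho_f <- abs(rho_f)
  tot <- rho_w + rho_f
  out <- numeric(length(tot))
  nz <- tot > 0
  out[nz] <- rho_f[nz] / tot[nz]
  out
}

# Given (phi, r2), solve the linear LS problem y ~ D A c exactly
# (D = decay diagonal, A = [1, E]) and return amplitudes, model, rss.
.ideal_amplitudes <- function(y, t, E, phi, r2) {
  d <- exp(-(2i * pi * phi + r2) * t)
  b1 <- d; b2 <- E * d
  a11 <- sum(Mod(b1)^2)
  a12 <- sum(Conj(b1) * b2)
  a22 <- sum(Mod(b2)^2)
  r1 <- sum(Conj(b1) * y)
  r2c <- sum(Conj(b2) * y)
  det <- a11 * a22 - Mod(a12)^2
  if (det <= .Machine$double.eps * a11 * a22) {
    # basis collapse (extreme decay): water-only solve
    W <- r1 / a11; F <- 0i
  } else {
    W <- (a22 * r1 - a12 * r2c) / det
    F <- (a11 * r2c - Conj(a12) * r1) / det
  }
  m <- (W * b1 + F * b2)
  list(W = W, F = F, model = m, rss = sum(Mod(y - m)^2))
}

#' Fit the full IDEAL signal model to one voxel
#'
#' Estimates \eqn{(\rho_w, \rho_f, \varphi, R_2^*)} from an n-echo complex
#' signal by variable projection: at the current \eqn{(\varphi, R_2^*)}
#' the two complex amplitudes are the exact linear least-squares solution
#' against the basis \eqn{\{1, e^{-j 2\pi \Delta f t_i}\}} modulated by
#' the decay, then a damped Gauss--Newton step updates
#' \eqn{(\varphi, R_2^*)} on the full residual with \eqn{R_2^*} clamped at
#' 0. Several field-frequency starts are run and the lowest-residual
#' solution returned; iteration stops when the relative parameter step
#' falls below `tol`.
#'
#' @param signal Complex vector, at least 4 echoes.
#' @param protocol An `hf_protocol` (supplies echo times and fat shift).
#' @param starts Initial field-frequency guesses in Hz; default
#'   \eqn{\{-\Delta f/2, 0, +\Delta f/2\}}.
#' @param r2star_start Initial R2* in 1/s (default 30).
#' @param tol Relative step tolerance (default 1e-8).
#' @param max_iter Maximum Gauss--Newton iterations per start (default 100).
#' @return List of class `hf_fit_result`: `rho_w`, `rho_f` (magnitudes),
#'   `field_map_hz`, `r2star`, `residual`, `iterations`, `converged`,
#'   `degenerate`, `pdff`.
#' @export
ideal_fit_voxel <- function(signal, protocol, starts = NULL,
                            r2star_start = 30, tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(protocol, "hf_protocol"))
  y <- as.complex(signal)
  t <- protocol$echo_times
  if (length(y) < 4L) {
    stop("IDEAL fitting needs at least 4 echoes (4 unknowns)", call. = FALSE)
  }
  if (length(y) != length(t)) stop("signal/echo count mismatch", call. = FALSE)
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  df <- protocol$fat_shift_hz
  if (is.null(starts)) starts <- c(-abs(df) / 2, 0, abs(df) / 2)
  E <- exp(-2i * pi * df * t)

  if (sum(Mod(y)^2) == 0) {
    return(structure(list(rho_w = 0, rho_f = 0, field_map_hz = 0,
                          r2star = 0, residual = 0, iterations = 0L,
                          converged = TRUE, degenerate = TRUE, pdff = 0),
                     class = "hf_fit_result"))
  }

  best <- NULL
  scale_phi <- abs(df)
  for (phi0 in starts) {
    phi <- phi0; r2 <- max(0, r2star_start)
    amp <- .ideal_amplitudes(y, t, E, phi, r2)
    converged <- FALSE
    iter <- 0L
    while (iter < max_iter) {
      iter <- iter + 1L
      m <- amp$model
      r <- y - m
      j1 <- -2i * pi * t * m        # d m / d phi
      j2 <- -t * m                  # d m / d r2*
      g11 <- sum(Mod(j1)^2)
      g12 <- sum(Re(Conj(j1) * j2))
      g22 <- sum(Mod(j2)^2)
      h1 <- sum(Re(Conj(j1) * r))
      h2 <- sum(Re(Conj(j2) * r))
      det <- g11 * g22 - g12^2
      if (!is.finite(det) || det <= 0) break
      d_phi <- (g22 * h1 - g12 * h2) / det
      d_r2 <- (g11 * h2 - g12 * h1) / det
      # damped update: halve the step while it fails to reduce the rss
      ok <- FALSE
      for (h in 0:14) {
        f <- 2^(-h)
        phi_new <- phi + f * d_phi
        r2_new <- max(0, r2 + f * d_r2)
        amp_new <- .ideal_amplitudes(y, t, E, phi_new, r2_new)
        if (amp_new$rss <= amp$rss + 1e-15) { ok <- TRUE; break }
      }
      if (!ok) break
      step <- sqrt(((phi_new - phi) / scale_phi)^2 + ((r2_new - r2) / 100)^2)
      phi <- phi_new; r2 <- r2_new; amp <- amp_new
      if (step < tol) { converged <- TRUE; break }
    }
    cand <- list(rho_w = Mod(amp$W), rho_f = Mod(amp$F), field_map_hz = phi,
                 r2star = r2, residual = sqrt(amp$rss), iterations = iter,
                 converged = converged)
    if (is.null(best) || cand$residual < best$residual) best <- cand
  }
  best$degenerate <- FALSE
  best$pdff <- pdff_from_components(best$rho_w, best$rho_f)
  structure(best, class = "hf_fit_result")
}

#' IDEAL PDFF and R2* maps
#'
#' Runs [ideal_fit_voxel()] at every voxel inside the mask (embedded
#' ground truth if present, whole frame otherwise) and assembles PDFF,
#' R2* and field maps together with a convergence mask.
#'
#' @param image An `hf_multiecho` acquisition with >= 4 echoes.
#' @param tol,max_iter Passed to [ideal_fit_voxel()].
#' @return An `hf_pdff_map` with fields `pdff`, `r2star`, `field_hz`,
#'   `residual`, `convergence_mask`, `mask`, `method = "ideal"`.
#' @export
ideal_pdff_map <- function(image, tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(image, "hf_multiecho"))
  dims <- dim(image$data)[1:2]
  n_echo <- dim(image$data)[3]
  if (n_echo < 4L) stop("IDEAL fitting needs at least 4 echoes", call. = FALSE)
  mask <- if (!is.null(image$truth)) image$truth$mask else
    matrix(TRUE, dims[1], dims[2])
  flat <- matrix(image$data, prod(dims), n_echo)
  vox <- which(as.vector(mask))

  pdff <- matrix(0, dims[1], dims[2])
  r2map <- matrix(0, dims[1], dims[2])
  fmap <- matrix(0, dims[1], dims[2])
  resid <- matrix(0, dims[1], dims[2])
  conv <- matrix(FALSE, dims[1], dims[2])
  for (v in vox) {
    f <- ideal_fit_voxel(flat[v, ], image$protocol, tol = tol,
                         max_iter = max_iter)
    pdff[v] <- f$pdff
    r2map[v] <- f$r2star
    fmap[v] <- f$field_map_hz
    resid[v] <- f$residual
    conv[v] <- f$converged && !f$degenerate
  }
  structure(list(pdff = pdff, r2star = r2map, field_hz = fmap,
                 residual = resid, convergence_mask = conv, mask = mask,
                 method = "ideal"),
            class = "hf_pdff_map")
}
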