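#' Ground-truth parameter maps for a simulated liver slice
#'
#' Constructs/validates the voxelwise ground truth of a 2-D slice: water
#' amplitude `rho_w`, fat amplitude `rho_f` (arbitrary units), field
#' inhomogeneity `field_map` (Hz), relaxation rate `r2star` (1/s) and a
#' logical liver `mask`. All five images must share one shape and
#' `r2star` must be non-negative.
#'
#' @param rho_w,rho_f Non-negative numeric matrices (water/fat amplitude).
#' @param field_map Numeric matrix, off-resonance in Hz.
#' @param r2star Non-negative numeric matrix, 1/s.
#' @param mask Logical matrix marking the liver region.
#' @return An object of class `hf_parameter_maps`.
#' @export
parameter_maps <- function(rho_w, rho_f, field_map, r2star, mask) {
  dims <- dim(rho_w)
  for (m in list(rho_f, field_map, r2star, mask)) {
    if (!identical(dim(m), dims)) {
      stop("all parameter maps must share one shape", call. = FALSE)
    }
  }
  if (any(rho_w < 0) || any(rho_f < 0)) {
    stop("water/fat amplitudes must be non-negative", call. = FALSE)
  }
  if (any(r2star < 0)) stop("r2star must be non-negative", call. = FALSE)
  if (!is.logical(mask)) stop("mask must be logical", call. = FALSE)
  structure(
    list(rho_w = rho_w, rho_f = rho_f, field_map = field_map,
         r2star = r2star, mask = mask),
    class = "hf_parameter_maps"
  )
}

#' True proton density fat fraction of a parameter map
#'
#' @param maps An `hf_parameter_maps` object.
#' @return Matrix of \eqn{\rho_f / (\rho_w + \rho_f)}, 0 where the total
#'   amplitude is 0.
#' @export
true_pdff <- function(maps) {
  tot <- maps$rho_w + maps$rho_f
  out <- maps$rho_f
  nz <- tot > 0
  out[nz] <- maps$rho_f[nz] / tot[nz]
  out[!nz] <- 0
  out
}

#' Simulate ground-truth parameter maps
#'
#' Builds a phantom slice: a filled-ellipse "liver" mask centred in the
#' frame, voxelwise PDFF drawn i.i.d. from `pdff_dist` inside the mask
#' (total amplitude fixed at 1 a.u., so `rho_f = PDFF`,
#' `rho_w = 1 - PDFF`), R2* drawn uniformly from `r2star_range`, and a
#' field map given by a low-order polynomial in coordinates normalised
#' to \eqn{[-1, 1]} along each axis.
#'
#' @param shape Integer vector of length 2, at least 32 x 32.
#' @param pdff_dist Distribution of the true fat fraction: either
#'   `list(kind = "point", value = v)`, `list(kind = "uniform", min =,
#'   max =)`, or a function `f(n)` returning `n` draws in \eqn{[0, 1]}.
#' @param r2star_range Length-2 interval in 1/s within \eqn{[0, 500]};
#'   a single value (or a zero-width interval) gives a constant map.
#' @param field_poly Polynomial coefficients in Hz over normalised
#'   coordinates \eqn{(x, y)}, ordered as constant, x, y, x^2, xy, y^2;
#'   shorter vectors are zero-padded.
#' @param seed Integer seed; every stochastic generator in this package
#'   takes an explicit seed and leaves the caller's RNG state untouched.
#' @return An `hf_parameter_maps` object.
#' @export
simulate_parameter_maps <- function(shape = c(64L, 64L),
                                    pdff_dist = list(kind = "uniform",
                                                     min = 0, max = 0.4),
                                    r2star_range = c(20, 60),
                                    field_poly = c(0, 15, -10),
                                    seed) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 32L)) {
    stop("shape must be two extents of at least 32 voxels", call. = FALSE)
  }
  r2star_range <- range(as.numeric(r2star_range))
  if (r2star_range[1] < 0 || r2star_range[2] > 500) {
    stop("r2star_range must lie within [0, 500] 1/s", call. = FALSE)
  }
  draw_pdff <- .pdff_sampler(pdff_dist)

  nr <- shape[1]; nc <- shape[2]
  # normalised coordinates and elliptical mask (semi-axes 80% of frame)
  x <- matrix(rep(seq(-1, 1, length.out = nc), each = nr), nr, nc)
  y <- matrix(rep(seq(-1, 1, length.out = nr), times = nc), nr, nc)
  mask <- (x / 0.8)^2 + (y / 0.8)^2 <= 1
  if (!any(mask)) stop("empty phantom mask", call. = FALSE)

  cf <- c(as.numeric(field_poly), rep(0, 6))[1:6]
  field_map <- cf[1] + cf[2] * x + cf[3] * y + cf[4] * x^2 +
    cf[5] * x * y + cf[6] * y^2

  n_in <- sum(mask)
  withr::with_seed(seed, {
    pdff <- draw_pdff(n_in)
    r2 <- stats::runif(n_in, r2star_range[1], r2star_range[2])
  })
  if (any(pdff < 0 | pdff > 1)) {
    stop("pdff_dist must produce values in [0, 1]", call. = FALSE)
  }

  zero <- matrix(0, nr, nc)
  rho_w <- zero; rho_f <- zero; r2star <- zero
  rho_f[mask] <- pdff
  rho_w[mask] <- 1 - pdff
  r2star[mask] <- r2
  parameter_maps(rho_w, rho_f, field_map, r2star, mask)
}

.pdff_sampler <- function(pdff_dist) {
  if (is.function(pdff_dist)) return(pdff_dist)
  if (!is.list(pdff_dist) || is.null(pdff_dist$kind)) {
    stop("pdff_dist must be a spec list or a sampling function",
         call. = FALSE)
  }
  switch(pdff_dist$kind,
    point = function(n) rep(pdff_dist$value, n),
    uniform = function(n) stats::runif(n, pdff_dist$min, pdff_dist$max),
    stop("unknown pdff_dist kind: ", pdff_dist$kind, call. = FALSE)
  )
}

#' Evaluate the noise-free water-fat signal model
#'
#' The single-peak signal model
#' \deqn{y_i = (\rho_w + \rho_f e^{-j 2\pi \Delta f t_i})
#'   e^{-j 2\pi \varphi t_i} e^{-R_2^* t_i}}
#' evaluated at each echo time. Inputs are vectors over voxels (recycled
#' scalars allowed); the result is a complex matrix voxels x echoes.
#'
#' @param rho_w,rho_f,field_hz,r2star Voxelwise parameters.
#' @param echo_times Echo times in seconds.
#' @param fat_shift_hz Fat chemical shift in Hz.
#' @return Complex matrix `length(rho_w)` x `length(echo_times)`.
#' @export
wf_signal_model <- function(rho_w, rho_f, field_hz, r2star, echo_times,
                            fat_shift_hz) {
  t <- as.numeric(echo_times)
  efat <- exp(-2i * pi * fat_shift_hz * t)                # 1 x n_echo
  amp <- outer(rho_f, efat) + rho_w                       # recycles rho_w
  dec <- exp(outer(-(2i * pi * field_hz + r2star), t))
  amp * dec
}

#' Simulate a multi-echo acquisition from ground truth
#'
#' Evaluates the signal model at every voxel and echo of the protocol and
#' adds i.i.d. circular complex Gaussian noise with standard deviation
#' `protocol$noise_sd` per real/imaginary channel. The ground truth is
#' embedded in the result for testing.
#'
#' @param maps An `hf_parameter_maps` object.
#' @param protocol An `hf_protocol`.
#' @param seed Integer seed for the noise draw.
#' @return An object of class `hf_multiecho` with fields `data` (complex
#'   array height x width x n_echo), `protocol` and `truth`.
#' @export
simulate_multiecho <- function(maps, protocol, seed) {
  stopifnot(inherits(maps, "hf_parameter_maps"),
            inherits(protocol, "hf_protocol"))
  dims <- dim(maps$rho_w)
  n_echo <- length(protocol$echo_times)
  sig <- wf_signal_model(as.vector(maps$rho_w), as.vector(maps$rho_f),
                         as.vector(maps$field_map), as.vector(maps$r2star),
                         protocol$echo_times, protocol$fat_shift_hz)
  if (protocol$noise_sd > 0) {
    n <- length(sig)
    withr::with_seed(seed, {
      noise <- complex(real = stats::rnorm(n, sd = protocol$noise_sd),
                       imaginary = stats::rnorm(n, sd = protocol$noise_sd))
    })
    sig <- sig + noise
  }
  structure(
    list(data = array(sig, c(dims, n_echo)), protocol = protocol,
         truth = maps),
    class = "hf_multiecho"
  )
}

#' Inject a water-fat-swap-inducing field offset into a region
#'
#' Shifts the field map by half the fat chemical shift inside a
#' rectangular region. Offsetting the off-resonance by \eqn{\Delta f / 2}
#' moves it outside the one-period search window of the fitters and
#' aliases water and fat there -- the failure mode the lowest-s.d. ROI
#' rule is designed to avoid. All other maps are unchanged.
#'
#' @param maps An `hf_parameter_maps` object.
#' @param region Integer vector `c(row_min, row_max, col_min, col_max)`
#'   (inclusive), or `NULL` for no change. Must intersect the mask.
#' @param fat_shift_hz Fat chemical shift in Hz (default 217).
#' @return The modified `hf_parameter_maps`, with the region recorded in
#'   attribute `"swap_region"`.
#' @export
inject_swap_region <- function(maps, region, fat_shift_hz = 217) {
  stopifnot(inherits(maps, "hf_parameter_maps"))
  if (is.null(region)) return(maps)
  region <- as.integer(region)
  if (length(region) != 4L) {
    stop("region must be c(row_min, row_max, col_min, col_max)",
         call. = FALSE)
  }
  dims <- dim(maps$field_map)
  if (region[1] > region[2] || region[3] > region[4]) return(maps)
  if (region[1] < 1L || region[3] < 1L || region[2] > dims[1] ||
      region[4] > dims[2]) {
    stop("region lies outside the image", call. = FALSE)
  }
  rows <- region[1]:region[2]; cols <- region[3]:region[4]
  if (!any(maps$mask[rows, cols])) {
    stop("region does not intersect the mask", call. = FALSE)
  }
  maps$field_map[rows, cols] <- maps$field_map[rows, cols] + fat_shift_hz / 2
  attr(maps, "swap_region") <- region
  maps
}
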