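#' Place eight 25-voxel ROIs inside a mask
#'
#' Deterministic placement of `n_rois` rectangular regions of interest
#' (default eight 5x5 = 25-voxel ROIs) inside the liver mask: the mask
#' bounding box is partitioned into a grid of `n_rois` cells (4 columns x
#' 2 rows along the wider axis), and each cell's centre is snapped to the
#' nearest position whose ROI lies fully inside the mask and does not
#' overlap a previously placed ROI. No randomness is involved, so fits
#' are reproducible without a seed.
#'
#' @param mask Logical matrix.
#' @param n_rois Number of ROIs (default 8).
#' @param roi_shape ROI extent in voxels, default `c(5, 5)`.
#' @return A list of `n_rois` rectangles `c(row_min, row_max, col_min,
#'   col_max)`, pairwise disjoint, each fully inside the mask.
#' @export
place_rois <- function(mask, n_rois = 8L, roi_shape = c(5L, 5L)) {
  stopifnot(is.logical(mask), is.matrix(mask))
  rh <- as.integer(roi_shape[1]); rw <- as.integer(roi_shape[2])
  nr <- nrow(mask); nc <- ncol(mask)

  # all top-left corners whose ROI is fully inside the mask
  ok <- matrix(FALSE, nr, nc)
  if (nr >= rh && nc >= rw) {
    cs <- rbind(0, apply(mask, 2, cumsum))          # column cumsums
    block <- function(r, c) {
      sum(cs[r + rh, c:(c + rw - 1)] - cs[r, c:(c + rw - 1)])
    }
    for (r in seq_len(nr - rh + 1L)) {
      for (c in seq_len(nc - rw + 1L)) {
        ok[r, c] <- block(r, c) == rh * rw
      }
    }
  }
  cand <- which(ok, arr.ind = TRUE)
  if (nrow(cand) < n_rois) {
    stop(sprintf(
      "mask (area %d voxels) admits only %d fully-interior %dx%d ROI positions, need %d",
      sum(mask), nrow(cand), rh, rw, n_rois), call. = FALSE)
  }

  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  wide <- diff(cols) >= diff(rows)
  n_c <- if (wide) 4L else 2L
  n_r <- n_rois / n_c
  # cell centres of the bounding-box grid, as ROI top-left targets
  centres_r <- rows[1] + (seq_len(n_r) - 0.5) / n_r * (diff(rows) + 1) -
    rh / 2
  centres_c <- cols[1] + (seq_len(n_c) - 0.5) / n_c * (diff(cols) + 1) -
    rw / 2
  targets <- expand.grid(r = centres_r, c = centres_c)

  taken <- matrix(FALSE, nr, nc)      # voxels covered by placed ROIs
  rois <- vector("list", n_rois)
  for (i in seq_len(n_rois)) {
    d2 <- (cand[, 1] - targets$r[i])^2 + (cand[, 2] - targets$c[i])^2
    placed <- FALSE
    for (j in order(d2)) {
      r0 <- unname(cand[j, 1]); c0 <- unname(cand[j, 2])
      if (!any(taken[r0:(r0 + rh - 1L), c0:(c0 + rw - 1L)])) {
        rois[[i]] <- c(r0, r0 + rh - 1L, c0, c0 + rw - 1L)
        taken[r0:(r0 + rh - 1L), c0:(c0 + rw - 1L)] <- TRUE
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf(
        "could not place %d disjoint %dx%d ROIs in mask of %d voxels",
        n_rois, rh, rw, sum(mask)), call. = FALSE)
    }
  }
  rois
}

#' Select the reported ROI by the lowest-s.d. rule
#'
#' Computes mean and sample standard deviation (n-1 denominator) of the
#' PDFF map over each candidate ROI and reports the mean of the ROI with
#' the smallest s.d., in percent. Low within-ROI spread indicates a
#' region free of water-fat swaps, which inflate local variability; ties
#' go to the lowest ROI index. ROIs containing non-finite voxels are
#' excluded with a warning. When the map carries an R2* image, the
#' selected ROI's mean R2* is converted to an iron concentration.
#'
#' @param pdff_map An `hf_pdff_map` (or a bare numeric matrix).
#' @param rois List of rectangles from [place_rois()].
#' @param cal An [iron_calibration()] used when R2* is available.
#' @return An object of class `hf_pdff_report`: `rois` (data frame with
#'   index, bounds, mean, sd), `selected_index`, `reported_pdff`
#'   (percent), `iron_mg_per_g` (`NA` for Dixon maps, which carry no R2*).
#' @export
select_roi <- function(pdff_map, rois, cal = iron_calibration()) {
  pdff <- if (inherits(pdff_map, "hf_pdff_map")) pdff_map$pdff else pdff_map
  r2 <- if (inherits(pdff_map, "hf_pdff_map")) pdff_map$r2star else NULL
  stats_df <- data.frame(index = seq_along(rois), row_min = NA_integer_,
                         row_max = NA_integer_, col_min = NA_integer_,
                         col_max = NA_integer_, mean = NA_real_,
                         sd = NA_real_)
  for (i in seq_along(rois)) {
    rc <- rois[[i]]
    vals <- pdff[rc[1]:rc[2], rc[3]:rc[4]]
    stats_df[i, 2:5] <- rc
    if (any(!is.finite(vals))) {
      warning(sprintf("ROI %d contains non-finite PDFF voxels; excluded", i))
      next
    }
    stats_df$mean[i] <- mean(vals)
    stats_df$sd[i] <- stats::sd(vals)
  }
  usable <- which(is.finite(stats_df$sd))
  if (!length(usable)) stop("all ROIs excluded", call. = FALSE)
  sel <- usable[order(stats_df$sd[usable], stats_df$index[usable])][1]

  iron <- NA_real_
  if (!is.null(r2)) {
    rc <- rois[[sel]]
    iron <- iron_concentration(mean(r2[rc[1]:rc[2], rc[3]:rc[4]]), cal)
  }
  structure(
    list(rois = stats_df, selected_index = sel,
         reported_pdff = 100 * stats_df$mean[sel], iron_mg_per_g = iron),
    class = "hf_pdff_report"
  )
}

#' @export
print.hf_pdff_report <- function(x, ...) {
  cat(sprintf("<hf_pdff_report: PDFF %.2f%% from ROI %d (s.d. %.4f)%s>\n",
              x$reported_pdff, x$selected_index,
              x$rois$sd[x$selected_index],
              if (is.finite(x$iron_mg_per_g))
                sprintf(", iron %.3f mg/g", x$iron_mg_per_g) else ""))
  invisible(x)
}

#' R2*-to-iron calibration constants
#'
#' The linear calibration iron = 0.202 + 0.0254 R2* (mg iron per g dry
#' tissue, R2* in 1/s). Override only deliberately.
#'
#' @param intercept,slope Calibration constants.
#' @return A list of class `hf_iron_calibration`.
#' @export
iron_calibration <- function(intercept = 0.202, slope = 0.0254) {
  structure(list(intercept = intercept, slope = slope),
            class = "hf_iron_calibration")
}

#' Hepatic iron concentration from R2*
#'
#' @param r2star R2* in 1/s, non-negative (vectorised).
#' @param cal An [iron_calibration()].
#' @return Iron concentration in mg/g.
#' @export
iron_concentration <- function(r2star, cal = iron_calibration()) {
  if (any(!is.finite(r2star)) || any(r2star < 0)) {
    stop("r2star must be finite and non-negative", call. = FALSE)
  }
  cal$intercept + cal$slope * r2star
}

#' Linear calibration between PDFF scores of two acquisitions
#'
#' Ordinary least-squares fit of the IDEAL-derived PDFF on the GRE
#' (Dixon) PDFF over paired scores, with the coefficient of
#' determination, quantifying the correspondence between the two
#' acquisitions.
#'
#' @param paired_pdff Data frame with columns `gre_pdff` and `ideal_pdff`
#'   (percent).
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
cross_protocol_calibration <- function(paired_pdff) {
  stopifnot(is.data.frame(paired_pdff),
            all(c("gre_pdff", "ideal_pdff") %in% names(paired_pdff)))
  if (nrow(paired_pdff) < 3L) {
    stop("need at least 3 paired scores", call. = FALSE)
  }
  if (stats::var(paired_pdff$gre_pdff) == 0) {
    stop("constant predictor: GRE PDFF has no variance", call. = FALSE)
  }
  fit <- stats::lm(ideal_pdff ~ gre_pdff, data = paired_pdff)
  # R^2 computed directly: summary.lm warns on exact fits
  y <- paired_pdff$ideal_pdff
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       n = nrow(paired_pdff))
}
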