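#' Cross-sectional areas perpendicular to the fitted spiral
#'
#' At stations every `step_um` of arc length along the fitted centerline, the
#' mask is resampled (trilinear interpolation at half-voxel resolution) on
#' the plane normal to the local tangent, thresholded at 0.5, and reduced to
#' the connected in-plane component containing the centerline point — this
#' keeps adjacent turns of the spiral, which also intersect the plane, out of
#' the station's area. Stations whose plane misses the foreground entirely
#' are dropped with a warning, not an error.
#'
#' @param mask a [voxel_mask()].
#' @param fit a [spiral_fit()] derived from (or consistent with) `mask`.
#' @param step_um station spacing in arc length, µm.
#' @param half_width_um half-extent of the sampling plane; default is sized
#'   from the mask's mean cross-section so the largest section fits.
#' @param basal_end which end of the centerline is the basal (round window)
#'   end: `"auto"` picks the end with the larger mean area over its first
#'   five stations, `"start"`/`"end"` override.
#' @return an [area_profile()] (distances in mm from the basal end, areas in
#'   mm², source `"mask"`).
#' @export
cross_section_areas <- function(mask, fit, step_um = 100,
                                half_width_um = NULL,
                                basal_end = c("auto", "start", "end")) {
  basal_end <- match.arg(basal_end)
  vox <- mask$voxel_size_um
  cl <- centerline(fit, step_um)

  # the fitted curve can overshoot the physical tube ends by a fraction of a
  # percent of arc length; keep only stations whose center point is solidly
  # inside the foreground so no plane straddles an end cap
  ctr_val <- .trilinear_mask(as.vector(mask$voxels), dim(mask$voxels),
                             cl$points / vox)
  solid <- which(ctr_val > 0.999)
  if (!length(solid))
    pk_stop("degenerate_geometry", "centerline misses the mask foreground")
  span <- seq(min(solid), max(solid))
  cl <- list(points = cl$points[span, , drop = FALSE],
             theta = cl$theta[span],
             s_um = cl$s_um[span] - cl$s_um[span[1]],
             tangents = cl$tangents[span, , drop = FALSE])
  ns <- nrow(cl$points)

  if (is.null(half_width_um)) {
    # mean area = volume / length; allow sections up to ~5x the mean radius
    mean_area_um2 <- mask_volume(mask) * 1e9 / max(cl$s_um)
    half_width_um <- 2.2 * sqrt(mean_area_um2 / pi) + 6 * vox
  }
  cell <- vox / 2
  g <- seq(-half_width_um, half_width_um, by = cell)
  ng <- length(g)
  ctr_idx <- which.min(abs(g))
  gu <- rep(g, ng); gv <- rep(g, each = ng)

  areas <- numeric(ns)
  for (k in seq_len(ns)) {
    tg <- cl$tangents[k, ]
    n1 <- fit$axis - sum(fit$axis * tg) * tg
    if (sqrt(sum(n1^2)) < 1e-6) n1 <- axis_frame(tg)$e1
    n1 <- unit(n1)
    n2 <- cross3(tg, n1)
    pts <- cbind(cl$points[k, 1] + gu * n1[1] + gv * n2[1],
                 cl$points[k, 2] + gu * n1[2] + gv * n2[2],
                 cl$points[k, 3] + gu * n1[3] + gv * n2[3]) / vox
    val <- .trilinear_mask(as.vector(mask$voxels), dim(mask$voxels), pts)
    m <- matrix(val >= 0.5, ng, ng)
    if (!m[ctr_idx, ctr_idx]) {
      # tolerate interpolation right at the boundary: look one cell around
      nb <- m[pmax(1, ctr_idx - 1):pmin(ng, ctr_idx + 1),
              pmax(1, ctr_idx - 1):pmin(ng, ctr_idx + 1)]
      if (!any(nb)) { areas[k] <- 0; next }
      w <- which(nb, arr.ind = TRUE)[1, ]
      ci <- pmax(1, ctr_idx - 1) + w[1] - 1
      cj <- pmax(1, ctr_idx - 1) + w[2] - 1
    } else {
      ci <- ctr_idx; cj <- ctr_idx
    }
    lab <- .label_components_2d(m)
    areas[k] <- sum(lab == lab[ci, cj]) * (cell / 1000)^2
  }

  keep <- areas > 0
  if (any(!keep))
    warning(sprintf("%d empty station(s) dropped", sum(!keep)))
  s_mm <- cl$s_um[keep] / 1000
  a <- areas[keep]

  # end-cap guard: a terminal station whose plane grazes the rounded tube
  # end is eroded at the rim; drop end stations clearly below their interior
  # neighbour (the taper itself changes area by well under 5% per station)
  while (length(a) > 2 && a[1] < 0.95 * a[2]) {
    a <- a[-1]; s_mm <- s_mm[-1]
  }
  while (length(a) > 2 && a[length(a)] < 0.95 * a[length(a) - 1]) {
    a <- a[-length(a)]; s_mm <- s_mm[-length(s_mm)]
  }

  flip <- switch(basal_end,
                 start = FALSE,
                 end = TRUE,
                 auto = mean(head(a, 5)) < mean(tail(a, 5)))
  if (flip) {
    a <- rev(a)
    s_mm <- max(s_mm) - rev(s_mm)
  }
  area_profile(s_mm - s_mm[1], a, source = "mask")
}
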