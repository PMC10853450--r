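# 3D logarithmic spiral model:
#   p(theta) = center + a e^{b theta} (cos(theta) e1 + sin(theta) e2)
#              + pitch * theta * axis
# with (e1, e2, axis) a right-handed orthonormal frame. The fitted object is
# normalised so that theta runs from 0 (start of the curve) and b >= 0, i.e.
# theta = 0 sits at the small-radius end of the spiral.

wrap_pi <- function(x) ((x + pi) %% (2 * pi)) - pi

unit <- function(v) v / sqrt(sum(v^2))

# right-handed frame (e1, e2, axis) for a given unit axis
axis_frame <- function(axis) {
  h <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit(h - sum(h * axis) * axis)
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

#' Construct a 3D logarithmic spiral description
#'
#' @param center 3-vector, µm.
#' @param axis unit 3-vector: the spiral (modiolar) axis.
#' @param radius_scale_a planar radius at theta = 0, µm (> 0).
#' @param growth_rate_b dimensionless logarithmic growth rate per radian.
#' @param pitch axial advance per radian, µm/rad.
#' @param theta_range numeric length-2, increasing.
#' @param rms_residual root-mean-square fit residual, µm (0 for analytic
#'   spirals).
#' @param ref_dir in-plane reference direction defining theta = 0; any vector
#'   not parallel to the axis (default: an arbitrary perpendicular).
#' @return an object of class `spiral_fit`.
#' @export
spiral_fit <- function(center, axis, radius_scale_a, growth_rate_b, pitch,
                       theta_range, rms_residual = 0, ref_dir = NULL) {
  axis <- unit(axis)
  if (radius_scale_a <= 0) pk_stop("invalid_params", "radius_scale_a must be > 0")
  if (diff(theta_range) <= 0) pk_stop("invalid_params", "theta_range must increase")
  if (rms_residual < 0) pk_stop("invalid_params", "rms_residual must be >= 0")
  if (is.null(ref_dir)) {
    ref_dir <- axis_frame(axis)$e1
  } else {
    ref_dir <- unit(ref_dir - sum(ref_dir * axis) * axis)
  }
  structure(list(center = as.numeric(center), axis = axis, ref_dir = ref_dir,
                 radius_scale_a = unname(radius_scale_a),
                 growth_rate_b = unname(growth_rate_b),
                 pitch = unname(pitch), theta_range = as.numeric(theta_range),
                 rms_residual = unname(rms_residual)),
            class = "spiral_fit")
}

#' @export
print.spiral_fit <- function(x, ...) {
  cat(sprintf(paste0("<spiral_fit> a=%.1f um, b=%.4f, pitch=%.1f um/rad, ",
                     "theta %.2f-%.2f rad (%.2f turns), rms=%.2f um\n"),
              x$radius_scale_a, x$growth_rate_b, x$pitch,
              x$theta_range[1], x$theta_range[2],
              diff(x$theta_range) / (2 * pi), x$rms_residual))
  invisible(x)
}

# curve evaluation and derivatives (n x 3 matrices, µm)
spiral_points <- function(fit, theta) {
  e2 <- cross3(fit$axis, fit$ref_dir)
  r <- fit$radius_scale_a * exp(fit$growth_rate_b * theta)
  outer(r * cos(theta), fit$ref_dir) + outer(r * sin(theta), e2) +
    outer(fit$pitch * theta, fit$axis) +
    matrix(fit$center, length(theta), 3, byrow = TRUE)
}

spiral_deriv <- function(fit, theta) {
  e2 <- cross3(fit$axis, fit$ref_dir)
  b <- fit$growth_rate_b
  r <- fit$radius_scale_a * exp(b * theta)
  outer(r * (b * cos(theta) - sin(theta)), fit$ref_dir) +
    outer(r * (b * sin(theta) + cos(theta)), e2) +
    outer(rep(fit$pitch, length(theta)), fit$axis)
}

spiral_deriv2 <- function(fit, theta) {
  e2 <- cross3(fit$axis, fit$ref_dir)
  b <- fit$growth_rate_b
  r <- fit$radius_scale_a * exp(b * theta)
  outer(r * ((b^2 - 1) * cos(theta) - 2 * b * sin(theta)), fit$ref_dir) +
    outer(r * ((b^2 - 1) * sin(theta) + 2 * b * cos(theta)), e2)
}

spiral_speed <- function(fit, theta) {
  sqrt(fit$radius_scale_a^2 * exp(2 * fit$growth_rate_b * theta) *
         (1 + fit$growth_rate_b^2) + fit$pitch^2)
}

# cumulative arc length lookup table over the fitted theta range
spiral_arclength_table <- function(fit, n = 20001) {
  th <- seq(fit$theta_range[1], fit$theta_range[2], length.out = n)
  sp <- spiral_speed(fit, th)
  s <- c(0, cumsum((sp[-1] + sp[-n]) / 2 * diff(th)))
  list(theta = th, s = s)
}

#' Total arc length of a fitted spiral
#' @param fit a [spiral_fit()].
#' @return arc length in mm.
#' @export
spiral_arc_length <- function(fit) {
  tab <- spiral_arclength_table(fit)
  tab$s[length(tab$s)] / 1000
}

#' Centerline points at equal arc-length spacing
#'
#' Samples the spiral at equal arc-length steps (not equal angle steps: on a
#' log spiral those would concentrate stations at the small-radius end).
#' The first point sits at `theta_range[1]`, by convention the basal end for
#' profiles derived from masks.
#'
#' @param fit a [spiral_fit()].
#' @param step_um arc-length spacing between consecutive points, µm.
#' @return a list with `points` (n x 3 matrix, µm), `theta`, `s_um`
#'   (arc-length coordinates), and `tangents` (unit n x 3).
#' @export
centerline <- function(fit, step_um = 100) {
  tab <- spiral_arclength_table(fit)
  S <- tab$s[length(tab$s)]
  s_out <- seq(0, S, by = step_um)
  th <- approx(tab$s, tab$theta, xout = s_out)$y
  d <- spiral_deriv(fit, th)
  list(points = spiral_points(fit, th), theta = th, s_um = s_out,
       tangents = d / sqrt(rowSums(d^2)))
}

# ---- fitting ---------------------------------------------------------------

# per-slab centroids along a direction; used for the collinearity guard
slab_centroids <- function(coords, dir, nslab = 40) {
  p <- as.vector(coords %*% dir)
  br <- seq(min(p), max(p), length.out = nslab + 1)
  idx <- findInterval(p, br, rightmost.closed = TRUE)
  keep <- tabulate(idx, nslab) > 0
  cen <- vapply(which(keep), function(k) colMeans(coords[idx == k, , drop = FALSE]),
                numeric(3))
  t(cen)
}

# max perpendicular deviation of points from their principal line
line_deviation <- function(pts) {
  pc <- sweep(pts, 2, colMeans(pts))
  d1 <- prcomp(pc, center = FALSE)$rotation[, 1]
  perp <- pc - outer(as.vector(pc %*% d1), d1)
  max(sqrt(rowSums(perp^2)))
}

# cluster the voxels of one angular wedge into tube cross-section blobs
wedge_blobs <- function(coords, r, z, cutoff, max_pts = 400) {
  n <- nrow(coords)
  take <- if (n > max_pts) seq(1, n, length.out = max_pts) else seq_len(n)
  take <- unique(round(take))
  rz <- cbind(r[take], z[take])
  cl <- if (length(take) > 1) {
    stats::cutree(stats::hclust(stats::dist(rz), method = "single"), h = cutoff)
  } else 1L
  out <- lapply(unique(cl), function(g) {
    colMeans(coords[take[cl == g], , drop = FALSE])
  })
  do.call(rbind, out)
}

# greedy nearest-neighbour chaining of blob centroids along the tube
chain_blobs <- function(blobs) {
  n <- nrow(blobs)
  dmat <- as.matrix(stats::dist(blobs))
  ctr <- colMeans(blobs)
  start <- which.max(sqrt(rowSums(sweep(blobs, 2, ctr)^2)))
  order_out <- integer(n)
  used <- logical(n)
  order_out[1] <- start; used[start] <- TRUE
  for (k in 2:n) {
    d <- dmat[order_out[k - 1], ]
    d[used] <- Inf
    order_out[k] <- which.min(d)
    used[order_out[k]] <- TRUE
  }
  order_out
}

#' Fit a 3D logarithmic spiral to a segmented volume
#'
#' Fits the conical helico-spiral r(theta) = a e^{b theta}, z(theta) =
#' pitch * theta to the centroid path of the foreground. The centroid path
#' is extracted by wedging the volume into angular bins about a candidate
#' axis, clustering each wedge into tube cross-section blobs, and chaining
#' the blob centroids along the tube; all three principal axes of the voxel
#' cloud are tried as candidates and the lowest-residual nonlinear fit wins.
#'
#' @param mask a [voxel_mask()].
#' @param nbins number of angular wedges used to sample the centroid path.
#' @param max_points voxel subsample cap for the fit.
#' @return a [spiral_fit()] with `rms_residual` the root-mean-square distance
#'   of the centroid path to the fitted curve (µm).
#' @section Errors: `empty_mask` if no foreground; `degenerate_geometry` if
#'   the centroid path is collinear (a straight tube has no winding axis) or
#'   spans less than one full turn.
#' @export
fit_spiral <- function(mask, nbins = 72, max_points = 250000) {
  if (!inherits(mask, "voxel_mask")) pk_stop("invalid_params", "need a voxel_mask")
  vox <- mask$voxel_size_um
  idx <- which(mask$voxels, arr.ind = TRUE)
  if (nrow(idx) == 0) pk_stop("empty_mask", "mask has no foreground voxels")
  coords <- (idx - 1) * vox
  if (nrow(coords) > max_points) {
    take <- unique(round(seq(1, nrow(coords), length.out = max_points)))
    coords <- coords[take, , drop = FALSE]
  }

  # collinearity guard: straight tubes have no identifiable spiral axis
  pca <- prcomp(coords)
  if (line_deviation(slab_centroids(coords, pca$rotation[, 1])) < 2 * vox)
    pk_stop("degenerate_geometry",
            "centroid path is collinear; no spiral axis identifiable")

  center0 <- colMeans(coords)
  best <- NULL
  for (cand in 3:1) {  # smallest-variance principal direction first
    ax <- pca$rotation[, cand]
    f <- try(fit_spiral_one_axis(coords, center0, ax, nbins, vox),
             silent = TRUE)
    if (inherits(f, "try-error")) next
    if (is.null(best) || f$rms_residual < best$rms_residual) best <- f
    if (best$rms_residual < vox) break  # sub-voxel residual: axis found
  }
  if (is.null(best))
    pk_stop("degenerate_geometry",
            "foreground does not wind a full turn about any axis")
  best
}

# axis estimate from an ordered centerline path: consecutive segment cross
# products of a winding curve all point near the spiral axis
path_axis <- function(path) {
  seg <- diff(path)
  n <- seg[-nrow(seg), , drop = FALSE]
  m <- seg[-1, , drop = FALSE]
  cr <- cbind(n[, 2] * m[, 3] - n[, 3] * m[, 2],
              n[, 3] * m[, 1] - n[, 1] * m[, 3],
              n[, 1] * m[, 2] - n[, 2] * m[, 1])
  len <- sqrt(rowSums(cr^2))
  cr <- cr[len > 0, , drop = FALSE] / len[len > 0]
  ref <- cr[1, ]
  sgn <- sign(cr %*% ref)
  sgn[sgn == 0] <- 1
  unit(colMeans(cr * as.vector(sgn)))
}

# fit with a fixed candidate axis; errors if the wedge path does not wind.
# The candidate axis only steers wedge extraction and unwrapping, so it is
# refined once from the chained path itself when clearly off.
fit_spiral_one_axis <- function(coords, center0, ax, nbins, vox,
                                flipped = FALSE, depth = 0) {
  fr <- axis_frame(ax)
  pc <- sweep(coords, 2, center0)
  u <- as.vector(pc %*% fr$e1); v <- as.vector(pc %*% fr$e2)
  z <- as.vector(pc %*% ax)
  r <- sqrt(u^2 + v^2); phi <- atan2(v, u)

  bin <- pmin(nbins, pmax(1L, 1L + floor((phi + pi) / (2 * pi) * nbins)))
  blobs <- do.call(rbind, lapply(seq_len(nbins), function(bq) {
    sel <- bin == bq
    if (!any(sel)) return(NULL)
    wedge_blobs(coords[sel, , drop = FALSE], r[sel], z[sel], cutoff = 3 * vox)
  }))
  if (is.null(blobs) || nrow(blobs) < 8)
    stop("too few centroid blobs")

  ord <- chain_blobs(blobs)
  blobs <- blobs[ord, , drop = FALSE]

  if (depth < 2) {
    ax_est <- path_axis(blobs)
    if (acos(pmin(1, abs(sum(ax_est * ax)))) > 0.05)
      return(fit_spiral_one_axis(coords, center0, ax_est, nbins, vox,
                                 flipped = FALSE, depth = depth + 1))
  }

  bpc <- sweep(blobs, 2, center0)
  bphi <- atan2(as.vector(bpc %*% fr$e2), as.vector(bpc %*% fr$e1))
  # unwrap, anchored at the first blob's azimuth so that the model angle
  # theta (mod 2 pi) coincides with the measured azimuth of every blob
  theta <- bphi[1] + cumsum(c(0, wrap_pi(diff(bphi))))
  if (abs(theta[length(theta)] - theta[1]) < 2 * pi * 0.95)
    stop("foreground spans less than one full turn")
  if (theta[length(theta)] < theta[1]) {
    # chain winds clockwise about this axis; refit about the flipped axis so
    # theta increases along the chain
    if (flipped) stop("winding direction inconsistent")
    return(fit_spiral_one_axis(coords, center0, -ax, nbins, vox,
                               flipped = TRUE, depth = depth))
  }

  br <- sqrt(rowSums((bpc - outer(as.vector(bpc %*% ax), ax))^2))
  bz <- as.vector(bpc %*% ax)
  lin_r <- stats::lm.fit(cbind(1, theta), log(pmax(br, 1e-6)))$coefficients
  lin_z <- stats::lm.fit(cbind(1, theta), bz)$coefficients
  # theta above was unwrapped in the +e2 sense; if the radius shrinks with
  # the chain direction the linear fit simply returns b < 0, handled by the
  # final normalisation.

  t1 <- fr$e1; t2 <- fr$e2
  build_fit <- function(p) {
    w <- unit(ax + p[4] * t1 + p[5] * t2)
    spiral_fit(center = p[1:3] + center0 + lin_z[1] * ax, axis = w,
               radius_scale_a = exp(p[6]), growth_rate_b = p[7],
               pitch = p[8],
               theta_range = range(theta), ref_dir = fr$e1)
  }
  # residuals with per-point theta refined by a few clamped Newton steps
  point_rss <- function(p) {
    f <- build_fit(p)
    th <- theta
    for (it in 1:4) {
      pt <- spiral_points(f, th)
      d1 <- spiral_deriv(f, th)
      d2 <- spiral_deriv2(f, th)
      dv <- pt - blobs
      g <- rowSums(dv * d1)
      h <- rowSums(d1 * d1) + rowSums(dv * d2)
      step <- ifelse(h > 0, -g / h, 0)
      th <- th + pmax(-0.5, pmin(0.5, step))
    }
    dv <- spiral_points(f, th) - blobs
    list(rss = sum(dv^2), theta = th)
  }
  p0 <- c(0, 0, 0, 0, 0, lin_r[1], lin_r[2], lin_z[2])
  opt <- optim(p0, function(p) point_rss(p)$rss, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10,
                              parscale = c(50, 50, 50, 0.05, 0.05,
                                           0.2, 0.02, 20)))
  pr <- point_rss(opt$par)
  f <- build_fit(opt$par)
  f$rms_residual <- sqrt(pr$rss / nrow(blobs))
  f$theta_range <- range(pr$theta)
  normalize_spiral_fit(f)
}

# anchor theta = 0 at the curve start and enforce b >= 0 (theta = 0 at the
# small-radius end); see the frame algebra in the methods vignette
normalize_spiral_fit <- function(f) {
  th0 <- f$theta_range[1]
  if (th0 != 0) {
    e2 <- cross3(f$axis, f$ref_dir)
    f$center <- f$center + f$pitch * th0 * f$axis
    f$ref_dir <- unit(cos(th0) * f$ref_dir + sin(th0) * e2)
    f$radius_scale_a <- f$radius_scale_a * exp(f$growth_rate_b * th0)
    f$theta_range <- f$theta_range - th0
  }
  if (f$growth_rate_b < 0) {
    Th <- f$theta_range[2]
    e2 <- cross3(f$axis, f$ref_dir)
    f$center <- f$center + f$pitch * Th * f$axis
    f$ref_dir <- unit(cos(Th) * f$ref_dir + sin(Th) * e2)
    f$axis <- -f$axis
    f$radius_scale_a <- f$radius_scale_a * exp(f$growth_rate_b * Th)
    f$growth_rate_b <- -f$growth_rate_b
    # pitch along the flipped axis keeps its value: z decreases along old
    # axis as theta' grows, i.e. increases along the new axis
  }
  f
}
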