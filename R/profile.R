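#' Cross-sectional area profile of a perilymph duct
#'
#' An `area_profile` is the 1D geometry the transport simulator consumes:
#' cross-sectional area as a function of distance from the basal (round
#' window) end of the scala tympani.
#'
#' @param distance_mm strictly increasing distances from the basal end, in mm,
#'   starting at 0.
#' @param area_mm2 positive cross-sectional areas, in mm², one per distance.
#' @param source provenance of the profile: `"mask"` (measured from a voxel
#'   mask), `"manual_csv"` (supplied by the user), or `"synthetic"`.
#' @return an object of class `area_profile`: a data frame with columns
#'   `distance_mm`, `area_mm2`, and `equivalent_diameter_mm`.
#' @examples
#' prof <- area_profile(seq(0, 30, by = 0.1), rep(1, 301), source = "synthetic")
#' volume_from_profile(prof)  # 30 uL
#' @export
area_profile <- function(distance_mm, area_mm2,
                         source = c("mask", "manual_csv", "synthetic")) {
  source <- match.arg(source)
  if (length(distance_mm) != length(area_mm2))
    pk_stop("invalid_profile", "distance and area must have the same length")
  if (any(!is.finite(distance_mm)) || any(!is.finite(area_mm2)))
    pk_stop("invalid_profile", "profile values must be finite")
  if (any(diff(distance_mm) <= 0))
    pk_stop("invalid_profile", "distances must be strictly increasing")
  if (any(area_mm2 <= 0))
    pk_stop("invalid_profile", "all areas must be positive")
  out <- data.frame(distance_mm = as.numeric(distance_mm),
                    area_mm2 = as.numeric(area_mm2),
                    equivalent_diameter_mm = equivalent_diameter(area_mm2))
  structure(out, class = c("area_profile", "data.frame"), source = source)
}

#' @export
print.area_profile <- function(x, ...) {
  cat(sprintf("<area_profile> %d stations, %.2f-%.2f mm, source: %s\n",
              nrow(x), min(x$distance_mm), max(x$distance_mm),
              attr(x, "source")))
  cat(sprintf("  area %.3f-%.3f mm2, volume %.2f uL\n",
              min(x$area_mm2), max(x$area_mm2), volume_from_profile(x)))
  invisible(x)
}

#' Equivalent tube diameter of a cross-section
#'
#' Diameter of the circle with the same area as the cross-section:
#' d = 2·sqrt(A/pi). The inverse relation pi·(d/2)² = A holds exactly.
#'
#' @param area_mm2 cross-sectional area(s) in mm², non-negative.
#' @return diameter(s) in mm.
#' @export
equivalent_diameter <- function(area_mm2) {
  if (any(area_mm2 < 0)) pk_stop("invalid_area", "area must be non-negative")
  2 * sqrt(area_mm2 / pi)
}

#' Polyline length of manually placed landmarks
#'
#' Sums consecutive Euclidean distances between landmark points placed along
#' the spiral trajectory (e.g. every ~500 µm along the organ of Corti). A
#' polyline slightly underestimates the true curve length.
#'
#' @param points_um an n x 3 matrix of landmark coordinates in µm, in order
#'   along the path (n >= 2).
#' @return total polyline length in mm.
#' @export
arc_length_from_landmarks <- function(points_um) {
  points_um <- as.matrix(points_um)
  if (nrow(points_um) < 2)
    pk_stop("invalid_landmarks", "need at least 2 landmark points")
  seg <- sqrt(rowSums(diff(points_um)^2))
  sum(seg) / 1000
}

#' Duct volume by trapezoidal integration of an area profile
#'
#' @param profile an [area_profile()].
#' @return volume in µL (1 mm³ = 1 µL).
#' @export
volume_from_profile <- function(profile) {
  x <- profile$distance_mm
  a <- profile$area_mm2
  if (length(x) < 2)
    pk_stop("invalid_profile", "cannot integrate a single-station profile")
  sum(diff(x) * (head(a, -1) + tail(a, -1)) / 2)
}

# linear resampling of a profile onto cell centers x (mm); rule = 2 clamps ends
resample_areas <- function(profile, x) {
  approx(profile$distance_mm, profile$area_mm2, xout = x, rule = 2)$y
}

#' Read / write an area profile as CSV
#'
#' CSV format: header `distance_mm,area_mm2,equivalent_diameter_mm` (the
#' diameter column is recomputed on read and optional in the input).
#'
#' @param path file path.
#' @param source provenance label recorded on the returned profile.
#' @return `read_area_profile` returns an [area_profile()];
#'   `write_area_profile` returns `path` invisibly.
#' @export
read_area_profile <- function(path, source = "manual_csv") {
  d <- read.csv(path)
  if (!all(c("distance_mm", "area_mm2") %in% names(d)))
    pk_stop("invalid_profile",
            "CSV must have columns distance_mm and area_mm2")
  area_profile(d$distance_mm, d$area_mm2, source = source)
}

#' @rdname read_area_profile
#' @param profile an [area_profile()].
#' @export
write_area_profile <- function(profile, path) {
  write.csv(as.data.frame(profile)[, c("distance_mm", "area_mm2",
                                       "equivalent_diameter_mm")],
            path, row.names = FALSE)
  invisible(path)
}
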