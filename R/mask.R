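#' Binary voxel mask of a segmented fluid space
#'
#' @param voxels a 3D logical (or 0/1) array; `TRUE` marks segmented fluid.
#' @param voxel_size_um isotropic voxel edge length, µm.
#' @param check_connectivity warn if the foreground is not a single
#'   6-connected component.
#' @return an object of class `voxel_mask`.
#' @export
voxel_mask <- function(voxels, voxel_size_um, check_connectivity = TRUE) {
  if (length(dim(voxels)) != 3)
    pk_stop("invalid_mask", "voxels must be a 3D array")
  if (!is.logical(voxels)) voxels <- array(voxels > 0.5, dim(voxels))
  if (!any(voxels)) pk_stop("empty_mask", "mask has no foreground voxels")
  if (voxel_size_um <= 0)
    pk_stop("invalid_mask", "voxel_size_um must be positive")
  if (check_connectivity) {
    ncomp <- .count_components_3d(as.vector(voxels), dim(voxels))
    if (ncomp > 1)
      warning(sprintf("mask foreground has %d connected components", ncomp))
  }
  structure(list(voxels = voxels, voxel_size_um = voxel_size_um),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> %s voxels @ %.1f um, %d foreground (%.2f uL)\n",
              paste(dim(x$voxels), collapse = "x"), x$voxel_size_um,
              sum(x$voxels), mask_volume(x)))
  invisible(x)
}

#' Foreground volume of a mask by voxel counting
#' @param mask a [voxel_mask()].
#' @return volume in µL.
#' @export
mask_volume <- function(mask) {
  sum(mask$voxels) * (mask$voxel_size_um / 1000)^3
}

#' Read / write voxel masks
#'
#' Multi-page TIFF stacks (one page per z slice) and NRRD volumes are
#' supported. TIFF carries no voxel size, so it must be given; NRRD headers
#' are parsed for `spacings` or `space directions` (isotropic only), with
#' `voxel_size_um` as a fallback or override.
#'
#' @param path file path (`.tif`/`.tiff` or `.nrrd`).
#' @param voxel_size_um isotropic voxel size in µm.
#' @return a [voxel_mask()].
#' @export
read_mask <- function(path, voxel_size_um = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (is.null(voxel_size_um))
      pk_stop("invalid_mask", "voxel_size_um is required for TIFF masks")
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
    arr <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
    voxel_mask(arr > 0.5, voxel_size_um)
  } else if (ext == "nrrd") {
    nr <- read_nrrd(path)
    vs <- if (!is.null(voxel_size_um)) voxel_size_um else nr$voxel_size_um
    if (is.null(vs))
      pk_stop("invalid_mask", "NRRD header has no spacing; pass voxel_size_um")
    voxel_mask(nr$data > 0.5, vs)
  } else {
    pk_stop("invalid_mask", paste("unsupported mask format:", ext))
  }
}

#' @rdname read_mask
#' @param mask a [voxel_mask()].
#' @param format `"tiff"` or `"nrrd"` (default from the file extension).
#' @export
write_mask <- function(mask, path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  if (format %in% c("tif", "tiff")) {
    slices <- lapply(seq_len(dim(mask$voxels)[3]), function(k)
      (mask$voxels[, , k]) * 1)
    tiff::writeTIFF(slices, path, bits.per.sample = 8)
  } else if (format == "nrrd") {
    write_nrrd(mask$voxels * 1L, path, mask$voxel_size_um)
  } else {
    pk_stop("invalid_mask", paste("unsupported mask format:", format))
  }
  invisible(path)
}

# --- minimal NRRD support (uint8, raw or gzip encoding, attached header) ----

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD", magic)) pk_stop("invalid_mask", "not an NRRD file")
  fields <- list()
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0 || ln == "") break
    if (grepl("^#", ln)) next
    kv <- strsplit(ln, ":[ =]?", perl = TRUE)[[1]]
    fields[[tolower(trimws(kv[1]))]] <- trimws(paste(kv[-1], collapse = ":"))
  }
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  type <- fields$type
  if (!type %in% c("uint8", "uchar", "unsigned char"))
    pk_stop("invalid_mask", paste("unsupported NRRD type:", type))
  enc <- fields$encoding
  n <- prod(sizes)
  raw_data <- readBin(con, "raw", n = file.info(path)$size)
  if (enc %in% c("gzip", "gz")) raw_data <- memDecompress(raw_data, type = "gzip")
  if (length(raw_data) < n) pk_stop("invalid_mask", "truncated NRRD data")
  data <- array(as.integer(raw_data[seq_len(n)]), sizes)
  vs <- NULL
  if (!is.null(fields$spacings)) {
    sp <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
    if (max(sp) - min(sp) > 1e-9 * max(sp))
      pk_stop("invalid_mask", "anisotropic NRRD voxels are not supported")
    vs <- sp[1]
  } else if (!is.null(fields[["space directions"]])) {
    m <- regmatches(fields[["space directions"]],
                    gregexpr("[-0-9.eE+]+", fields[["space directions"]]))[[1]]
    m <- as.numeric(m)
    vs <- max(abs(m))
  }
  list(data = data, voxel_size_um = vs)
}

write_nrrd <- function(arr, path, voxel_size_um, encoding = "gzip") {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "# generated by cochleaPK",
           "type: uint8",
           sprintf("dimension: %d", length(dim(arr))),
           sprintf("sizes: %s", paste(dim(arr), collapse = " ")),
           sprintf("spacings: %s",
                   paste(rep(voxel_size_um, length(dim(arr))), collapse = " ")),
           sprintf("encoding: %s", encoding),
           "endian: little", "")
  writeLines(hdr, con, sep = "\n")
  payload <- as.raw(as.integer(arr))
  if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
  writeBin(payload, con)
  invisible(path)
}
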