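# Axis-aligned 3D scalar volumes: container and NIfTI / raw+JSON I/O.
# Convention: voxel (i, j, k) (1-based) has its center at
# origin + (c(i, j, k) - 0.5) * voxel_size; `origin` is the grid corner.

#' Construct a 3D scalar volume grid
#'
#' @param values 3D numeric array.
#' @param voxel_size Isotropic voxel edge length in cm (> 0).
#' @param origin Grid corner in world cm coordinates (3-vector).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(values, voxel_size, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L)
    stop_parameter("values must be a 3D array")
  if (!is_scalar(voxel_size) || voxel_size <= 0)
    stop_parameter("voxel_size must be a positive scalar")
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop_parameter("origin must be a finite 3-vector")
  structure(list(values = values, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_grid> %d x %d x %d voxels @ %.4g cm (%.3g MB)\n",
              d[1L], d[2L], d[3L], x$voxel_size,
              utils::object.size(x$values) / 2^20))
  cat(sprintf("  origin (%.3g, %.3g, %.3g) cm; value range [%.4g, %.4g]\n",
              x$origin[1L], x$origin[2L], x$origin[3L],
              min(x$values), max(x$values)))
  invisible(x)
}

# Voxel-center coordinates along one axis.
axis_coords <- function(vol, ax) {
  vol$origin[ax] + (seq_len(dim(vol$values)[ax]) - 0.5) * vol$voxel_size
}

congruent_grids <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$voxel_size, b$voxel_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Write a volume to disk
#'
#' Two formats, chosen by extension: NIfTI (`.nii` / `.nii.gz`; voxel size
#' and origin go in the header) or raw little-endian float32 (`.raw`) with a
#' JSON sidecar (same path with `.json`) recording shape (column-major
#' order), voxel size, origin and dtype.
#'
#' @param volume A [volume_grid()].
#' @param path Output path ending in `.nii`, `.nii.gz` or `.raw`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (!inherits(volume, "volume_grid"))
    stop_parameter("volume must be a volume_grid")
  if (grepl("\\.nii(\\.gz)?$", path)) {
    im <- RNifti::asNifti(volume$values)
    vs <- volume$voxel_size
    im <- RNifti::`pixdim<-`(im, rep(vs, 3L))
    # voxel-center world position of voxel (1,1,1) as the NIfTI origin
    aff <- structure(rbind(cbind(diag(vs, 3L),
                                 volume$origin + vs / 2),
                           c(0, 0, 0, 1)), code = 2L)
    im <- RNifti::`sform<-`(im, aff)
    RNifti::writeNifti(im, path)
  } else if (grepl("\\.raw$", path)) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.vector(volume$values), con, size = 4L, endian = "little")
    sidecar <- sub("\\.raw$", ".json", path)
    jsonlite::write_json(list(shape = dim(volume$values),
                              voxel_size_cm = volume$voxel_size,
                              origin_cm = volume$origin,
                              dtype = "float32", order = "F",
                              endian = "little"),
                         sidecar, auto_unbox = TRUE, digits = NA)
  } else stop_format("unsupported volume extension in '%s' (use .nii[.gz] or .raw)",
                     path)
  invisible(path)
}

#' Read a volume from disk
#'
#' Counterpart of [write_volume()]; dispatches on extension.
#'
#' @param path Path to a `.nii`, `.nii.gz` or `.raw` volume (the latter
#'   requires its JSON sidecar next to it).
#' @return A [volume_grid()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop_format("volume file does not exist: %s", path)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    im <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(im)
    if (max(pd) - min(pd) > 1e-6 * max(pd))
      warning("anisotropic NIfTI pixdim; using the first component")
    aff <- RNifti::xform(im)
    center1 <- aff[1:3, 4L]
    volume_grid(array(as.numeric(im), dim = dim(im)),
                voxel_size = pd[1L],
                origin = as.numeric(center1) - pd[1L] / 2)
  } else if (grepl("\\.raw$", path)) {
    sidecar <- sub("\\.raw$", ".json", path)
    if (!file.exists(sidecar))
      stop_format("missing JSON sidecar for raw volume: %s", sidecar)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    shape <- as.integer(meta$shape)
    if (length(shape) != 3L)
      stop_format("sidecar %s: shape must have 3 entries", sidecar)
    n <- prod(shape)
    vals <- readBin(path, "numeric", n = n + 1L, size = 4L, endian = "little")
    if (length(vals) != n)
      stop_format("raw volume %s has %d values, sidecar shape implies %d",
                  path, length(vals), n)
    volume_grid(array(vals, dim = shape),
                voxel_size = meta$voxel_size_cm,
                origin = as.numeric(meta$origin_cm))
  } else stop_format("unsupported volume extension in '%s'", path)
}
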