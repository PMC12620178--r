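#' @include AllClasses.R
NULL

.sidecarPath <- function(path) {
  sub("\\.nii(\\.gz)?$", "", path) |> paste0(".json")
}
.maskPath <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  ext <- regmatches(path, regexpr("\\.nii(\\.gz)?$", path))
  if (length(ext) == 0) ext <- ".nii.gz"
  paste0(base, "_mask", ext)
}

#' Write a ScalarVolume as NIfTI-1 with a JSON sidecar
#'
#' The voxel size is encoded in the NIfTI header; the unit tag (which
#' NIfTI-1 cannot carry for these quantities) goes into a JSON sidecar next
#' to the volume. An attached mask is written as a companion
#' `<name>_mask.nii[.gz]` volume. Data are stored as 64-bit float so the
#' round trip through [readVolume()] is bit-exact.
#'
#' @param vol a [ScalarVolume-class].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "ScalarVolume"))
  validObject(vol)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  arr <- vol@data
  attr(arr, "pixdim") <- vol@voxelSize
  img <- RNifti::asNifti(arr, datatype = "double")
  RNifti::writeNifti(img, path, datatype = "double")
  jsonlite::write_json(
    list(unit = vol@unit, voxel_size_mm = vol@voxelSize,
         has_mask = !is.null(vol@mask)),
    .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  if (!is.null(vol@mask)) {
    marr <- array(as.numeric(vol@mask), dim(vol@mask))
    attr(marr, "pixdim") <- vol@voxelSize
    RNifti::writeNifti(RNifti::asNifti(marr, datatype = "uint8"),
                       .maskPath(path), datatype = "uint8")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume into a ScalarVolume
#'
#' Voxel size comes from the header, the unit from the JSON sidecar written
#' by [writeVolume()] (or the `unit` argument when there is none), and a
#' companion `<name>_mask` volume is picked up as the mask. Non-3D images
#' are rejected, as are non-finite voxels outside the mask.
#'
#' @param path path to a `.nii`/`.nii.gz` file.
#' @param unit unit tag used when no sidecar is present.
#' @return A [ScalarVolume-class].
#' @export
readVolume <- function(path, unit = "dimensionless") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected 3D volume, got ",
                                   length(dim(img)), "D")
  arr <- array(as.vector(img), dim(img))
  vs <- RNifti::pixdim(img)[1:3]
  mask <- NULL
  sc <- .sidecarPath(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$unit)) unit <- meta$unit
    if (isTRUE(meta$has_mask) && file.exists(.maskPath(path)))
      mask <- array(as.array(RNifti::readNifti(.maskPath(path))) != 0,
                    dim(arr))
  }
  if (is.null(mask) && any(!is.finite(arr)))
    stop("volume contains non-finite voxels and no mask")
  ScalarVolume(arr, voxelSize = vs, unit = unit, mask = mask)
}

#' Write an MPE report as a delimited text table
#'
#' One row per (ROI, map, condition); values round-trip through
#' [readReport()] at full double precision.
#'
#' @param report an [MPEReport-class].
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path) {
  stopifnot(is(report, "MPEReport"))
  if (nrow(report@data) == 0L) stop("empty report")
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.csv(report@data, path, row.names = FALSE)
  invisible(path)
}

#' Read back an MPE report written by [writeReport()]
#'
#' @param path path to the CSV file.
#' @param nReplicates replicate count to record on the object.
#' @return An [MPEReport-class].
#' @export
readReport <- function(path, nReplicates = NA_integer_) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (is.na(nReplicates) && "n" %in% names(df))
    nReplicates <- suppressWarnings(max(df$n, na.rm = TRUE))
  new("MPEReport", data = df, nReplicates = as.integer(nReplicates))
}

#' Write the configuration echo of a run
#'
#' Every run writes its full configuration (including all seeds) next to
#' its outputs so deterministic stages reproduce bit-identically and seeded
#' stages reproduce distribution-identically.
#'
#' @param config a configuration list (see [defaultRunConfig()]).
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
writeConfigEcho <- function(config, path) {
  if (is.null(config$seed)) stop("config must record an explicit seed")
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
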