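# Volume I/O: NIfTI-1 via RNifti, Analyze 7.5 via oro.nifti, and a raw
# binary-plus-JSON-sidecar format convenient for tests. All readers convert
# into the canonical in-memory order: 0-based lattice, x fastest-varying.

infer_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) return("nifti")
  if (grepl("\\.(hdr|img)(\\.gz)?$", lp)) return("analyze")
  if (grepl("\\.(bin|json)$", lp)) return("raw")
  stop("cannot infer volume format from path: ", path)
}

#' Read a 3D volume
#'
#' Supported formats: `"nifti"` (`.nii`, `.nii.gz`), `"analyze"`
#' (`.hdr`/`.img`, Analyze 7.5) and `"raw"` (flat little-endian binary with a
#' JSON sidecar describing dims/spacing, used for tests). Values are
#' quantized into `{0..q_levels-1}` by the contract of [quantize_grays()];
#' spacing is taken from the header when present, else (1, 1, 1).
#'
#' @param path file path.
#' @param format one of `"auto"`, `"nifti"`, `"analyze"`, `"raw"`.
#' @param q_levels number of gray levels Q.
#' @return A [volume()].
#' @export
read_volume <- function(path, format = "auto", q_levels = 256L) {
  if (!file.exists(path) && !file.exists(paste0(path, ".gz")))
    stop("file not found: ", path)
  format <- match.arg(format, c("auto", "nifti", "analyze", "raw"))
  if (format == "auto") format <- infer_format(path)
  if (format == "nifti") {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop("unreadable NIfTI file '", path,
                                             "': ", conditionMessage(e)))
    arr <- as.array(img)
    sp <- RNifti::pixdim(img)
    if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) dim(arr) <- dim(arr)[1:3]
    if (length(dim(arr)) != 3L)
      stop("non-3D content in '", path, "': ", length(dim(arr)), " dims")
    sp <- if (length(sp) >= 3 && all(is.finite(sp[1:3])) && all(sp[1:3] > 0))
      sp[1:3] else c(1, 1, 1)
    return(volume(arr, sp, q_levels))
  }
  if (format == "analyze") {
    hdr <- sub("\\.img(\\.gz)?$", ".hdr", path)
    img <- tryCatch(oro.nifti::readANALYZE(hdr),
                    error = function(e) stop("unreadable Analyze file '", path,
                                             "': ", conditionMessage(e)))
    arr <- img@.Data
    if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) dim(arr) <- dim(arr)[1:3]
    if (length(dim(arr)) != 3L)
      stop("non-3D content in '", path, "'")
    sp <- img@pixdim[2:4]
    sp <- if (all(is.finite(sp)) && all(sp > 0)) sp else c(1, 1, 1)
    return(volume(arr, sp, q_levels))
  }
  # raw: <stem>.bin + <stem>.json
  stem <- sub("\\.(bin|json)$", "", path)
  side <- paste0(stem, ".json")
  binf <- paste0(stem, ".bin")
  if (!file.exists(side) || !file.exists(binf))
    stop("raw format needs both ", binf, " and ", side)
  meta <- jsonlite::fromJSON(side)
  if (length(meta$dims) != 3L) stop("non-3D content in '", path, "'")
  n <- prod(meta$dims)
  con <- file(binf, "rb"); on.exit(close(con))
  vals <- readBin(con, what = "integer", n = n, size = 4L, endian = "little")
  if (length(vals) != n) stop("raw volume '", binf, "' truncated")
  arr <- array(vals, meta$dims)
  sp <- if (!is.null(meta$spacing)) meta$spacing else c(1, 1, 1)
  ql <- if (!is.null(meta$q_levels)) meta$q_levels else q_levels
  volume(arr, sp, ql)
}

#' Write a 3D volume (or region map)
#'
#' Round-trips grid values, dims and spacing through [read_volume()].
#'
#' @param v a [volume()] or [region_map()].
#' @param path output path (extension selects the format when `format` is
#'   `"auto"`).
#' @param format one of `"auto"`, `"nifti"`, `"analyze"`, `"raw"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, format = "auto") {
  if (inherits(v, "dwi_region_map")) v <- as_map_volume(v)
  if (!inherits(v, "dwi_volume")) stop("v must be a dwi_volume or dwi_region_map")
  format <- match.arg(format, c("auto", "nifti", "analyze", "raw"))
  if (format == "auto") format <- infer_format(path)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write '", path, "': directory does not exist")
  if (format == "nifti") {
    img <- RNifti::asNifti(array(as.integer(v$data), v$dims))
    RNifti::pixdim(img) <- v$spacing
    tryCatch(RNifti::writeNifti(img, path, datatype = "int16"),
             error = function(e) stop("failed writing '", path, "': ",
                                      conditionMessage(e)))
  } else if (format == "analyze") {
    stem <- sub("\\.(hdr|img)(\\.gz)?$", "", path)
    img <- oro.nifti::anlz(v$data, datatype = 4L)
    img@pixdim[2:4] <- v$spacing
    tryCatch(oro.nifti::writeANALYZE(img, stem),
             error = function(e) stop("failed writing '", path, "': ",
                                      conditionMessage(e)))
  } else {
    stem <- sub("\\.(bin|json)$", "", path)
    con <- file(paste0(stem, ".bin"), "wb")
    writeBin(as.integer(v$data), con, size = 4L, endian = "little")
    close(con)
    jsonlite::write_json(list(dims = v$dims, spacing = v$spacing,
                              q_levels = v$q_levels),
                         paste0(stem, ".json"), auto_unbox = FALSE, digits = NA)
  }
  invisible(path)
}

#' Read a binary region map
#'
#' Reads with [read_volume()] and validates that the labels are exactly
#' \{0, 1\}.
#' @inheritParams read_volume
#' @return A [region_map()].
#' @export
read_region_map <- function(path, format = "auto") {
  v <- read_volume(path, format)
  if (!all(v$data %in% c(0L, 1L)))
    stop("region map '", path, "' contains labels outside {0,1}")
  region_map(v$data, v$spacing)
}

#' Load a multi-b-value series from a manifest
#'
#' The manifest (YAML or JSON file, or an equivalent list) has entries
#' `subject_id` and `volumes`, the latter a list of `{b, path}` records.
#' Relative paths are resolved against the manifest's directory. Volumes are
#' sorted by ascending b-value; duplicate b-values or mismatched dims raise
#' consistency errors.
#'
#' @param manifest path to a YAML/JSON manifest, or a list.
#' @return A [dwi_series()].
#' @export
load_series <- function(manifest) {
  base <- "."
  if (is.character(manifest)) {
    base <- dirname(manifest)
    manifest <- if (grepl("\\.ya?ml$", tolower(manifest)))
      yaml::read_yaml(manifest) else jsonlite::fromJSON(manifest,
                                                        simplifyVector = FALSE)
  }
  vols <- manifest$volumes
  if (is.data.frame(vols)) vols <- split(vols, seq_len(nrow(vols)))
  if (is.null(vols) || length(vols) == 0L)
    stop("manifest lists no volumes")
  b <- vapply(vols, function(e) as.numeric(e$b), 0)
  paths <- vapply(vols, function(e) as.character(e$path), "")
  if (anyDuplicated(b))
    stop("duplicate b-value entries in manifest: ",
         paste(b[duplicated(b)], collapse = ", "))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", paths), paths, file.path(base, paths))
  volumes <- lapply(abs, read_volume)
  dwi_series(b, volumes,
             subject_id = if (!is.null(manifest$subject_id))
               manifest$subject_id else "subject")
}
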