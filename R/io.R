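#' Read a NIfTI-1 volume
#'
#' Integer-typed data yields a `label_volume` (label names default to
#' `"background", "region1", ...`); anything else an `activity_volume`.
#' Voxel spacing is taken from the header and must be positive.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param label_names optional label names when reading a label volume.
#' @return `activity_volume` or `label_volume`.
#' @export
read_volume <- function(path, label_names = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("invalid voxel spacing in NIfTI header of ", path)
  arr <- as.array(img)
  arr <- as_array3d(array(as.vector(arr), dim(arr)))  # strip niftiImage attrs
  if (is.integer(arr) || isTRUE(all(arr == round(arr)) && max(arr) < 1000 &&
                                grepl("label", basename(path), ignore.case = TRUE))) {
    storage.mode(arr) <- "integer"
    if (is.null(label_names))
      label_names <- c("background",
                       if (max(arr) > 0) paste0("region", seq_len(max(arr))))
    label_volume(arr, spacing, label_names)
  } else {
    activity_volume(arr, spacing)
  }
}

#' Write a volume as NIfTI-1
#'
#' @param vol `activity_volume` or `label_volume`.
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  arr <- if (inherits(vol, "label_volume")) vol$labels else vol$values
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Minimal interfile volume reader
#'
#' Parses the `!INTERFILE` ASCII header (`.hv`/`.h33`) for the data file
#' name, matrix sizes, scaling factors and number format, and reads the raw
#' voxel data. Supports float/short little- or big-endian 3D volumes --
#' enough for interoperability with tomographic reconstruction toolkits; the
#' native format of this package is NIfTI-1.
#'
#' @param header_path path to the interfile header.
#' @return an `activity_volume`.
#' @export
read_interfile <- function(header_path) {
  if (!file.exists(header_path)) stop("no such file: ", header_path)
  lines <- readLines(header_path, warn = FALSE)
  kv <- function(key) {
    hit <- grep(paste0("^\\s*!?", key, "\\s*(\\[\\d\\])?\\s*:?="), lines,
                ignore.case = TRUE, value = TRUE)
    trimws(sub("^[^=]*=", "", hit))
  }
  kvn <- function(key, idx) {
    hit <- grep(sprintf("^\\s*!?%s\\s*\\[%d\\]\\s*:?=", key, idx), lines,
                ignore.case = TRUE, value = TRUE)
    as.numeric(trimws(sub("^[^=]*=", "", hit[1])))
  }
  data_file <- kv("name of data file")[1]
  if (is.na(data_file) || !nzchar(data_file)) stop("interfile header has no data file")
  data_path <- file.path(dirname(header_path), data_file)
  n <- vapply(1:3, function(i) kvn("matrix size", i), numeric(1))
  sc <- vapply(1:3, function(i) kvn("scaling factor \\(mm/pixel\\)", i), numeric(1))
  if (any(is.na(sc))) sc <- rep(1, 3)
  fmt <- tolower(kv("number format")[1])
  bytes <- as.integer(kv("number of bytes per pixel")[1])
  if (is.na(bytes)) bytes <- if (grepl("float", fmt)) 4L else 2L
  endian <- if (any(grepl("bigendian", tolower(lines)))) "big" else "little"
  what <- if (grepl("float", fmt)) numeric() else integer()
  con <- file(data_path, "rb"); on.exit(close(con))
  raw <- readBin(con, what = what, n = prod(n), size = bytes, endian = endian)
  activity_volume(array(as.numeric(raw), n), sc)
}

#' Write an experiment report
#'
#' Writes the experiment summary and its per-realization draws as CSV, the
#' run configuration (including the master seed) as YAML, and a JSON digest,
#' so that any output directory carries a config snapshot sufficient to
#' reproduce it. Identical configs reproduce byte-identical CSVs.
#'
#' @param result a `pvc_experiment` or `pvc_shift_experiment`.
#' @param outdir output directory (created if missing).
#' @param config optional named list recorded alongside (merged with the
#'   experiment's own config attribute).
#' @return character vector of files written, invisibly.
#' @export
write_report <- function(result, outdir, config = list()) {
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(outdir, 2) != 0) stop("cannot write to ", outdir)
  files <- character()
  wr <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(as.data.frame(df), p, row.names = FALSE)
    files <<- c(files, p)
  }
  wr(result, "summary.csv")
  for (att in c("draws", "rows"))
    if (!is.null(attr(result, att))) wr(attr(result, att), paste0(att, ".csv"))
  cfg <- utils::modifyList(as.list(attr(result, "config") %||% list()), config)
  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  files <- c(files, cfg_path)
  js_path <- file.path(outdir, "summary.json")
  jsonlite::write_json(as.data.frame(result), js_path, digits = NA, auto_unbox = TRUE)
  files <- c(files, js_path)
  invisible(files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a phantom/run configuration from YAML
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  yaml::read_yaml(path)
}
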