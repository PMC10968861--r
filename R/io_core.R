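# IO: scan pairs (NIfTI), feature tables (CSV), outcomes, run configuration.
#
# Analysis happens in voxel space with the stored spacing; world-coordinate
# affines are read from the NIfTI headers but not otherwise used.

#' Construct a ScanPair
#'
#' Bundles the co-registered PET (SUV) and CT (HU) volumes with the lesion
#' mask and voxel spacing for one time point of one subject. All three arrays
#' must share a grid; the mask is binarized (any value > 0 becomes 1).
#'
#' @param subject_id subject identifier.
#' @param timepoint `"baseline"` or `"eot"` (end of treatment).
#' @param pet 3D numeric array of SUV (dimensionless, >= 0).
#' @param ct 3D numeric array of Hounsfield units.
#' @param mask 3D array; any value > 0 marks a lesion voxel.
#' @param spacing numeric length-3 voxel spacing (dx, dy, dz) in mm.
#' @param scanner_id scanner identifier string.
#' @param require_roi error if the mask is empty (default TRUE).
#' @return an object of class `scan_pair`.
#' @export
scan_pair <- function(subject_id, timepoint = c("baseline", "eot"),
                      pet, ct, mask, spacing, scanner_id = "scanner_A",
                      require_roi = TRUE) {
  timepoint <- match.arg(timepoint)
  pet <- as.array(pet); ct <- as.array(ct); mask <- as.array(mask)
  if (!identical(dim(pet), dim(ct)) || !identical(dim(pet), dim(mask))) {
    stop("grid-mismatch: pet ", paste(dim(pet), collapse = "x"),
         ", ct ", paste(dim(ct), collapse = "x"),
         ", mask ", paste(dim(mask), collapse = "x"),
         " for subject ", subject_id, call. = FALSE)
  }
  if (length(dim(pet)) != 3L) stop("volumes must be 3D arrays", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be three positive numbers (mm)", call. = FALSE)
  }
  mask <- (mask > 0) * 1L
  storage.mode(mask) <- "integer"
  if (require_roi && sum(mask) == 0L) {
    stop("empty-ROI: mask has no foreground voxels for subject ", subject_id,
         call. = FALSE)
  }
  structure(list(subject_id = as.character(subject_id), timepoint = timepoint,
                 pet = pet, ct = ct, mask = mask, spacing = spacing,
                 scanner_id = as.character(scanner_id)),
            class = "scan_pair")
}

#' @method print scan_pair
#' @export
print.scan_pair <- function(x, ...) {
  cat("<scan_pair>", x$subject_id, "/", x$timepoint,
      "| grid", paste(dim(x$pet), collapse = "x"),
      "| spacing", paste(signif(x$spacing, 4), collapse = "x"), "mm",
      "| ROI", sum(x$mask), "voxels",
      "| scanner", x$scanner_id, "\n")
  invisible(x)
}

#' Read a PET/CT/mask triplet from NIfTI files
#'
#' @param pet_path,ct_path,mask_path NIfTI (.nii / .nii.gz) file paths.
#' @param subject_id,timepoint,scanner_id metadata, see [scan_pair()].
#' @param spacing optional spacing override; default taken from the PET header.
#' @return a `scan_pair`.
#' @export
read_scan_pair <- function(pet_path, ct_path, mask_path,
                           subject_id, timepoint = "baseline",
                           scanner_id = "scanner_A", spacing = NULL) {
  for (p in c(pet_path, ct_path, mask_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  pet <- RNifti::readNifti(pet_path)
  ct <- RNifti::readNifti(ct_path)
  mask <- RNifti::readNifti(mask_path)
  if (!identical(dim(pet), dim(mask))) {
    stop("grid-mismatch: mask file ", mask_path, " has shape ",
         paste(dim(mask), collapse = "x"), " but PET has ",
         paste(dim(pet), collapse = "x"), call. = FALSE)
  }
  if (is.null(spacing)) spacing <- RNifti::pixdim(pet)[1:3]
  scan_pair(subject_id, timepoint, pet = as.array(pet), ct = as.array(ct),
            mask = as.array(mask), spacing = spacing, scanner_id = scanner_id)
}

#' Write a scan pair to NIfTI files
#'
#' @param scan a `scan_pair`.
#' @param dir output directory.
#' @param compress write .nii.gz (default FALSE: plain .nii).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_scan_pair <- function(scan, dir, compress = FALSE) {
  stopifnot(inherits(scan, "scan_pair"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (compress) ".nii.gz" else ".nii"
  stem <- file.path(dir, paste0(scan$subject_id, "_", scan$timepoint))
  paths <- c(pet = paste0(stem, "_pet", ext),
             ct = paste0(stem, "_ct", ext),
             mask = paste0(stem, "_mask", ext))
  for (nm in names(paths)) {
    img <- RNifti::asNifti(scan[[nm]])
    RNifti::pixdim(img) <- scan$spacing
    RNifti::writeNifti(img, paths[[nm]])
  }
  invisible(paths)
}

#' Write a feature table to CSV
#'
#' Feature tables are data.frames with a `subject_id` column (plus optional
#' annotation columns `timepoint` and `scanner_id`) and one numeric column per
#' named feature. Missing values serialize as empty fields; values are written
#' with 15 significant digits so a write/read round trip is lossless at double
#' precision.
#'
#' @param table a feature table data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  if (anyDuplicated(names(table))) {
    stop("duplicate feature name(s): ",
         paste(unique(names(table)[duplicated(names(table))]), collapse = ", "),
         call. = FALSE)
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  out <- table
  num <- vapply(out, is.numeric, logical(1))
  # format() keeps full precision; NA becomes the empty field via write.csv
  for (j in which(num)) {
    out[[j]] <- ifelse(is.na(out[[j]]), NA_character_,
                       formatC(out[[j]], digits = 15, format = "g"))
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV path written by [write_feature_table()].
#' @return a data.frame; empty fields become `NA`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, na.strings = "",
                        stringsAsFactors = FALSE)
  if (anyDuplicated(names(df))) {
    stop("duplicate feature name(s) in ", path, call. = FALSE)
  }
  ann <- intersect(c("subject_id", "timepoint", "scanner_id"), names(df))
  for (j in setdiff(names(df), ann)) {
    if (is.character(df[[j]])) df[[j]] <- as.numeric(df[[j]])
  }
  df
}

#' Read an outcomes table
#'
#' Expects columns `subject_id`, `progression` (0/1), `ttp_months` (>= 0),
#' `event` (0/1), `scanner_id`, and optionally `deauville` (integer 1-5).
#'
#' @param path CSV path.
#' @return validated data.frame of outcome records.
#' @export
read_outcomes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_outcomes(df)
}

#' @rdname read_outcomes
#' @param df an outcomes data.frame to validate in place.
#' @export
validate_outcomes <- function(df) {
  need <- c("subject_id", "progression", "ttp_months", "event", "scanner_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("outcomes table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(df$progression %in% c(0, 1))) stop("progression must be 0/1")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0/1")
  if (any(df$ttp_months < 0)) stop("ttp_months must be >= 0")
  if ("deauville" %in% names(df) &&
      !all(is.na(df$deauville) | df$deauville %in% 1:5)) {
    stop("deauville must be integer 1-5 when present")
  }
  df
}

#' Load a run configuration file
#'
#' Flat YAML with per-stage sections; unknown keys pass through. The `seed`
#' key is mandatory: every stochastic stage derives its stream from it.
#'
#' @param path YAML config path.
#' @return a named list with class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must set a `seed`", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}
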