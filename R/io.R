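#' Dataset container schema version
#' @export
dataset_schema_version <- function() "1.0"

required_dataset_members <- function() {
  c("truth_images", "activity", "expected", "trues", "r", "noisy",
    "phantom", "schedule", "seeds", "scale", "config", "version")
}

#' Save a simulated dataset container
#'
#' The container is a versioned R list serialized with [saveRDS()];
#' all arrays and metadata round-trip losslessly.
#'
#' @param dataset A `pet_dataset`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
save_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "pet_dataset"))
  saveRDS(dataset, path)
  invisible(path)
}

#' Load and validate a dataset container
#'
#' @param path File written by [save_dataset()].
#' @return The `pet_dataset`.
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  ds <- tryCatch(readRDS(path),
                 error = function(e) stop("corrupt dataset file '", path,
                                          "': ", conditionMessage(e)))
  missing <- setdiff(required_dataset_members(), names(ds))
  if (length(missing))
    stop("dataset schema error: missing required member(s): ",
         paste(missing, collapse = ", "))
  if (!identical(ds$version, dataset_schema_version()))
    stop("dataset schema version mismatch: file has '", ds$version,
         "', this package expects '", dataset_schema_version(), "'")
  ds
}

#' Save / load a run configuration as plain-text YAML
#'
#' Configurations round-trip losslessly (`load_config(save_config(x))`
#' equals `x` for numeric/character/list content).
#'
#' @param config Named list of parameters.
#' @param path YAML file path.
#' @return `save_config` invisibly returns `path`; `load_config`
#'   returns the list.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Export an image stack as NIfTI (one volume, frames as 3rd dimension)
#'
#' @param images Pixels x frames matrix (column-major square images).
#' @param side Image side in pixels.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return Invisibly, `path`.
#' @export
export_nifti <- function(images, side, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI export requires the 'RNifti' package")
  arr <- array(as.matrix(images), dim = c(side, side, ncol(as.matrix(images))))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Write per-frame metrics to CSV and a JSON summary
#'
#' @param metrics A `pet_metrics` object (see [evaluate_recon()]).
#' @param csv_path Per-frame CSV output path.
#' @param json_path JSON summary output path.
#' @return Invisibly, the paths written.
#' @export
write_metrics <- function(metrics, csv_path, json_path) {
  stopifnot(inherits(metrics, "pet_metrics"))
  utils::write.csv(metrics$per_frame, csv_path, row.names = FALSE)
  jsonlite::write_json(list(summary = metrics$summary,
                            region_mae = as.list(metrics$region_mae),
                            n_realizations = metrics$n_realizations),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}
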