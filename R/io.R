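#' Write an EEG recording or encoded dataset to the project container
#'
#' The container is a single RDS file holding the object verbatim. For
#' plain-text interoperability, `format = "csv"` writes a directory with
#' `data.csv` (channels x samples), `trials.csv`, `montage.csv` and a
#' `meta.json` sidecar instead.
#'
#' @param obj An `eeg_recording` or `encoded_dataset`.
#' @param path Output file (RDS) or directory (CSV).
#' @param format `"rds"` or `"csv"` (recordings only).
#' @return `path`, invisibly.
#' @export
write_eeg_dataset <- function(obj, path, format = c("rds", "csv")) {
  format <- match.arg(format)
  if (format == "rds") {
    tmp <- paste0(path, ".tmp")
    saveRDS(obj, tmp)
    file.rename(tmp, path)  # atomic overwrite
    return(invisible(path))
  }
  if (!inherits(obj, "eeg_recording")) {
    stop("csv export is implemented for eeg_recording objects")
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(obj$data, file.path(path, "data.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.csv(obj$trials, file.path(path, "trials.csv"),
                   row.names = FALSE)
  mont <- data.frame(name = obj$montage$channel_names,
                     x = obj$montage$positions[, 1],
                     y = obj$montage$positions[, 2])
  utils::write.csv(mont, file.path(path, "montage.csv"), row.names = FALSE)
  jsonlite::write_json(list(fs = obj$fs, n_channels = nrow(obj$data),
                            n_samples = ncol(obj$data)),
                       file.path(path, "meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a dataset written by [write_eeg_dataset()]
#'
#' @param path RDS file or CSV directory.
#' @return The stored object.
#' @export
read_eeg_dataset <- function(path) {
  if (dir.exists(path)) {
    data <- as.matrix(utils::read.table(file.path(path, "data.csv"),
                                        sep = ","))
    dimnames(data) <- NULL
    trials <- utils::read.csv(file.path(path, "trials.csv"))
    mont <- utils::read.csv(file.path(path, "montage.csv"))
    meta <- jsonlite::read_json(file.path(path, "meta.json"))
    pos <- cbind(x = mont$x, y = mont$y)
    rownames(pos) <- mont$name
    montage <- structure(list(channel_names = mont$name, positions = pos),
                         class = "montage")
    return(new_eeg_recording(data, meta$fs, montage, trials))
  }
  readRDS(path)
}

#' Save / load a model checkpoint
#'
#' Single-file archive holding the configuration, weights, batch-norm
#' running statistics and the initialization seed.
#'
#' @param model A `spikewav_model`.
#' @param path Checkpoint file.
#' @return `path` (write) or the restored model (load).
#' @export
save_checkpoint <- function(model, path) {
  tmp <- paste0(path, ".tmp")
  saveRDS(model, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "spikewav_model")) stop("not a model checkpoint: ", path)
  model
}
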