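## per-subject dataset serialization: binary array + JSON sidecar

#' Write a subject dataset to a directory
#'
#' Stores the epoch array as little-endian float64 (`data.bin`, trial-major:
#' trials x channels x samples in R array order) plus a `meta.json` sidecar
#' with dimensions, sampling rate, channel labels, per-trial category labels,
#' behavioral accuracy and, for synthetic data, the generation ground truth.
#'
#' @param dataset an [EEGDataset-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSubject <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(dir, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(dataset@data), con, size = 8, endian = "little")
  meta <- list(
    subject = dataset@subjectId,
    dim = dim(dataset@data),
    fs = dataset@fs,
    channels = dataset@channels,
    labels = as.character(dataset@labels),
    categories = levels(dataset@labels),
    behavior = dataset@behavior,
    groundTruth = dataset@groundTruth)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a subject dataset written by [writeSubject()]
#'
#' @param dir subject directory.
#' @return An [EEGDataset-class].
#' @export
readSubject <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  n <- prod(meta$dim)
  con <- file(file.path(dir, "data.bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, what = "numeric", n = n, size = 8, endian = "little")
  gt <- if (is.null(meta$groundTruth)) list() else as.list(meta$groundTruth)
  if (!is.null(gt$categoryPatterns)) gt$categoryPatterns <- as.matrix(gt$categoryPatterns)
  beh <- as.list(meta$behavior)
  beh$perCategory <- unlist(beh$perCategory)
  new("EEGDataset",
      data = array(x, dim = meta$dim),
      labels = factor(meta$labels, levels = meta$categories),
      fs = meta$fs, channels = meta$channels,
      behavior = beh, groundTruth = gt,
      subjectId = meta$subject)
}
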