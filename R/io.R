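# Dataset interchange: long-format CSV (patient_id, modality, channel,
# timestamp, value) with missing cells omitted, plus a labels CSV
# (patient_id, label). The long format handles ragged multimodal sampling
# naturally; binary containers are used only as post-preprocessing caches.

#' Read a long-format multimodal dataset
#'
#' Parses the long CSV (`patient_id, modality, channel, timestamp, value`)
#' and the labels CSV (`patient_id, label`) into per-patient
#' `modality_record` lists. Rows are grouped by (patient, modality),
#' timestamps sorted; duplicate (patient, modality, channel, timestamp)
#' rows are rejected with the offending row number.
#'
#' @param path long CSV path.
#' @param labels_path labels CSV path (optional).
#' @return list with `records` (patients -> modalities -> `modality_record`)
#'   and `labels` (data.frame or NULL).
#' @export
read_long_csv <- function(path, labels_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "modality", "channel", "timestamp", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_amfn(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  }
  labels <- NULL
  if (!is.null(labels_path)) {
    labels <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
    if (!all(c("patient_id", "label") %in% names(labels))) {
      stop_amfn("labels CSV must have columns patient_id, label")
    }
    labels$patient_id <- as.character(labels$patient_id)
  }
  if (nrow(df) == 0L) {
    warning("empty dataset file")
    return(list(records = list(), labels = labels))
  }
  if (!is.numeric(df$timestamp) || !is.numeric(df$value)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df$timestamp))) |
                   is.na(suppressWarnings(as.numeric(df$value))))[1L]
    stop_amfn(sprintf("unparseable numeric at data row %d", bad))
  }
  key <- paste(df$patient_id, df$modality, df$channel, df$timestamp, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop_amfn(sprintf(
      "duplicate (patient, modality, channel, timestamp) at data row %d", dup[1L]))
  }
  records <- list()
  for (pid in unique(df$patient_id)) {
    dpat <- df[df$patient_id == pid, ]
    mods <- list()
    for (mod in unique(dpat$modality)) {
      dm <- dpat[dpat$modality == mod, ]
      channels <- unique(dm$channel)
      ts <- sort(unique(dm$timestamp))
      v <- matrix(NA_real_, length(channels), length(ts),
                  dimnames = NULL)
      ci <- match(dm$channel, channels)
      ti <- match(dm$timestamp, ts)
      v[cbind(ci, ti)] <- dm$value
      mods[[mod]] <- modality_record(pid, mod, channels, ts, v)
    }
    records[[pid]] <- mods
  }
  list(records = records, labels = labels)
}

#' Write a dataset in long format
#'
#' Missing cells are omitted from the file, so
#' `read_long_csv(write_long_csv(x))` reproduces `x` up to row order.
#'
#' @param records per-patient lists of `modality_record`s.
#' @param path long CSV output path.
#' @param labels optional labels data.frame; written next to `path` with
#'   suffix `_labels.csv` unless `labels_path` is given.
#' @param labels_path labels CSV output path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(records, path, labels = NULL, labels_path = NULL) {
  rows <- list()
  for (pat in records) {
    for (rec in pat) {
      obs <- which(is.finite(rec$values), arr.ind = TRUE)
      if (nrow(obs) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = rec$patient_id,
        modality = rec$modality,
        channel = rec$channels[obs[, 1L]],
        timestamp = rec$timestamps[obs[, 2L]],
        value = rec$values[obs],
        stringsAsFactors = FALSE
      )
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(0), modality = character(0),
               channel = character(0), timestamp = numeric(0),
               value = numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(labels)) {
    if (is.null(labels_path)) {
      labels_path <- sub("\\.csv$", "_labels.csv", path)
    }
    utils::write.csv(labels, labels_path, row.names = FALSE)
  }
  invisible(path)
}

write_manifest <- function(obj, path) {
  obj$provenance <- list(
    package = "amfn",
    package_version = as.character(utils::packageVersion("amfn")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
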