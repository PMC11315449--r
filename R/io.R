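# On-disk interchange: a CSV pair (counts, kinematics) plus a JSON sidecar
# carrying bin width, per-bin trial ids, per-trial condition ids, and any
# neuron labels or fold assignment. This is the format the command-line
# wrapper reads and writes.

#' Write a dataset to a CSV pair plus JSON sidecar
#'
#' Creates `<stem>_counts.csv`, `<stem>_kinematics.csv` (both with a leading
#' 0-based `bin` column) and `<stem>_meta.json`.
#'
#' @param ds A [binned_dataset()] or `synthetic_dataset`.
#' @param stem Path stem (no extension).
#' @param extra Named list merged into the JSON sidecar (e.g. fold assignment).
#' @return The sidecar path, invisibly.
#' @export
write_dataset_csv <- function(ds, stem, extra = list()) {
  sds <- NULL
  if (inherits(ds, "synthetic_dataset")) {
    sds <- ds
    ds <- ds$dataset
  }
  cts <- data.frame(bin = seq_len(nrow(ds$counts)) - 1L, ds$counts)
  names(cts)[-1L] <- paste0("n", seq_len(ncol(ds$counts)))
  kin <- data.frame(bin = seq_len(nrow(ds$kinematics)) - 1L,
                    vx = ds$kinematics[, 1L], vy = ds$kinematics[, 2L])
  write.csv(cts, paste0(stem, "_counts.csv"), row.names = FALSE)
  write.csv(kin, paste0(stem, "_kinematics.csv"), row.names = FALSE)
  meta <- c(list(
    bin_width = ds$bin_width,
    trial_id = ds$trial_id,
    condition_id = if (is.null(ds$condition_id)) NULL else unname(ds$condition_id)
  ), extra)
  if (!is.null(sds)) {
    meta$neuron_labels <- sds$neuron_labels
    meta$snr_db <- sds$snr_db
    meta$seed <- sds$seed
    write.csv(data.frame(bin = seq_len(nrow(sds$ground_truth_relevant)) - 1L,
                         sds$ground_truth_relevant),
              paste0(stem, "_ground_truth_relevant.csv"), row.names = FALSE)
  }
  path <- paste0(stem, "_meta.json")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a dataset written by [write_dataset_csv()]
#'
#' @param stem Path stem used when writing.
#' @return A [binned_dataset()]; the sidecar content is attached as
#'   `attr(, "meta")`.
#' @export
read_dataset_csv <- function(stem) {
  cts <- read.csv(paste0(stem, "_counts.csv"))
  kin <- read.csv(paste0(stem, "_kinematics.csv"))
  meta_path <- paste0(stem, "_meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  ds <- binned_dataset(
    as.matrix(cts[, -1L, drop = FALSE]),
    as.matrix(kin[, c("vx", "vy")]),
    bin_width = meta$bin_width %||% 0.1,
    trial_id = meta$trial_id,
    condition_id = meta$condition_id,
    allow_negative = TRUE
  )
  attr(ds, "meta") <- meta
  ds
}
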