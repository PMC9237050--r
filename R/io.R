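#' Read / write connectomes, parcellations and profiles
#'
#' All on-disk formats are plain tab-separated text: connectomes as square
#' matrices with node ids as header row and first column; parcellations as
#' tables with columns `node_id`, `hemisphere`, `network`, `homotope`,
#' `x`, `y`, `z`; cohort manifests with one row per subject x timepoint;
#' criticality profiles as a curve table plus a JSON sidecar holding the
#' scalar summaries.
#'
#' @param connectome a `raw_connectome`.
#' @param path file path.
#' @name neurocrit-io
NULL

#' @rdname neurocrit-io
#' @export
write_connectome <- function(connectome, path) {
  W <- connectome$W
  df <- data.frame(node_id = seq_len(nrow(W)), W, check.names = FALSE)
  colnames(df) <- c("node_id", seq_len(ncol(W)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname neurocrit-io
#' @param parcellation parcellation to attach to the read connectome.
#' @param subject_id,timepoint metadata for the read connectome.
#' @export
read_connectome <- function(path, parcellation = NULL,
                            subject_id = "unknown", timepoint = "t1") {
  df <- read.delim(path, check.names = FALSE)
  W <- as.matrix(df[, -1, drop = FALSE])
  dimnames(W) <- NULL
  new_raw_connectome(W, parcellation, subject_id, timepoint)
}

#' @rdname neurocrit-io
#' @export
write_parcellation <- function(parcellation, path) {
  write.table(as.data.frame(parcellation), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname neurocrit-io
#' @export
read_parcellation <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("parcellation", "data.frame")
  out
}

#' @rdname neurocrit-io
#' @param profile a `criticality_profile`.
#' @export
write_profile <- function(profile, path) {
  curves <- data.frame(T = profile$T_grid, mean_A = profile$mean_A,
                       sd_A = profile$sd_A, S1 = profile$S1, S2 = profile$S2)
  write.table(curves, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- sub("\\.tsv$", "", path)
  jsonlite::write_json(
    list(T_c = profile$T_c, I1 = profile$I1, I2 = profile$I2,
         monotonic_S2 = profile$monotonic_S2,
         subject_id = profile$subject_id, timepoint = profile$timepoint),
    paste0(sidecar, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname neurocrit-io
#' @export
read_profile <- function(path) {
  curves <- read.delim(path)
  meta <- jsonlite::read_json(paste0(sub("\\.tsv$", "", path), ".json"),
                              simplifyVector = TRUE)
  structure(c(list(T_grid = curves$T, mean_A = curves$mean_A,
                   sd_A = curves$sd_A, S1 = curves$S1, S2 = curves$S2),
              meta),
            class = "criticality_profile")
}
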