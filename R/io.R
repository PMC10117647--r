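#' Read a disease-free-survival table (cBioPortal export dialect)
#'
#' Parses a tab-separated table with columns `PATIENT_ID`, `DFS_MONTHS` and
#' `DFS_STATUS`. Status accepts the portal strings `"0:DiseaseFree"` and
#' `"1:Recurred/Progressed"` as well as bare `0`/`1`. Rows with a missing
#' time or status are dropped with a message reporting the count; any other
#' status string is an error naming the offending row.
#'
#' @param path Path to the TSV file.
#' @return A [survival_sample()].
#' @export
read_dfs_table <- function(path) {
  if (!file.exists(path)) stop("DFS table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("PATIENT_ID", "DFS_MONTHS", "DFS_STATUS")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  months <- suppressWarnings(as.numeric(df$DFS_MONTHS))
  status_raw <- trimws(as.character(df$DFS_STATUS))
  blank <- is.na(months) | !nzchar(status_raw) | is.na(status_raw)
  keep_status <- status_raw[!blank]
  event <- rep(NA, length(keep_status))
  event[keep_status %in% c("0", "0:DiseaseFree")] <- FALSE
  event[keep_status %in% c("1", "1:Recurred/Progressed")] <- TRUE
  if (anyNA(event)) {
    bad_row <- which(!blank)[which(is.na(event))[1]]
    stop("unparseable DFS_STATUS at row ", bad_row, ": '",
         status_raw[bad_row], "'")
  }
  if (any(blank))
    message("dropped ", sum(blank), " row(s) with missing DFS time/status")
  if (!any(!blank)) stop("no usable rows in DFS table")
  survival_sample(months[!blank], event,
                  patient_id = df$PATIENT_ID[!blank])
}

#' Write a survival sample in the disease-free-survival TSV dialect
#'
#' @param sample A [survival_sample()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dfs_table <- function(sample, path) {
  df <- data.frame(
    PATIENT_ID = sample$patient_id,
    DFS_MONTHS = sample$time,
    DFS_STATUS = ifelse(sample$event, "1:Recurred/Progressed",
                        "0:DiseaseFree"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load the bundled tumor-specific carcinogenic profiles
#'
#' Returns the packaged table of fitted carcinogenic profiles for 27
#' non-sarcoma, non-hematological cancer types: per-type fitted `r1`,
#' `rS1`, `rS`, `dS`, the three per-step log10 mutation rates, the log10
#' integrated mutation rate, the fit objective `SQ` (log-SSR) and the
#' log-rank p value of the fitted curve against the clinical curve.
#'
#' The table is validated on load: 27 rows, unique codes, and the identity
#' `log10_muI = log10_mu1 + log10_muS1 + log10_muS` to within the rounding
#' of three 3-decimal addends.
#'
#' @return A data frame of 27 carcinogenic profiles.
#' @examples
#' profiles <- load_profiles_fixture()
#' profiles[profiles$code == "KICH", "dS"]
#' @export
load_profiles_fixture <- function() {
  path <- system.file("extdata", "carcinogenic_profiles.tsv",
                      package = "locorecur", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) != 27)
    stop("corrupted profile fixture: expected 27 rows, found ", nrow(df))
  if (anyDuplicated(df$code))
    stop("corrupted profile fixture: duplicated cancer codes")
  resid <- abs(df$log10_mu1 + df$log10_muS1 + df$log10_muS - df$log10_muI)
  if (any(resid > 0.002))
    stop("corrupted profile fixture: integrated-rate identity violated for ",
         paste(df$code[resid > 0.002], collapse = ", "))
  df
}
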