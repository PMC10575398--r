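# On-disk session dialect: one CSV per channel (`time_s,value`) plus an
# annotations CSV per subject.

#' Write a session to a directory of CSV files
#'
#' Creates `subjectNN_ecg.csv` and `subjectNN_scl.csv` (`time_s,value`)
#' and `subjectNN_annotations.csv` (`start_s,end_s,stage,category,method,
#' sam`).
#'
#' @param session One element of a [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- sprintf("subject%02d", session$subject)
  paths <- character(0)
  for (ch in c("ecg", "scl")) {
    sig <- session[[ch]]
    if (is.null(sig)) next
    p <- file.path(dir, sprintf("%s_%s.csv", stem, ch))
    data.table::fwrite(data.table::data.table(time_s = signal_times(sig),
                                              value = sig$values), p)
    # sampling metadata as a JSON sidecar
    meta <- file.path(dir, sprintf("%s_%s.json", stem, ch))
    jsonlite::write_json(list(fs = sig$fs, units = sig$units,
                              channel = sig$channel, t0 = sig$t0),
                         meta, auto_unbox = TRUE)
    paths <- c(paths, p, meta)
  }
  pa <- file.path(dir, sprintf("%s_annotations.csv", stem))
  data.table::fwrite(session$annotations, pa)
  pt <- file.path(dir, sprintf("%s_triggers.csv", stem))
  data.table::fwrite(data.table::data.table(
    time_s = session$truth$trigger_times, source = "ground_truth"), pt)
  invisible(c(paths, pa, pt))
}

#' Read a session written by [write_session()]
#'
#' @param dir Directory containing the CSV dialect.
#' @param subject Subject number.
#' @return A session list (`subject`, `ecg`, `scl`, `annotations`,
#'   `truth`).
#' @export
read_session <- function(dir, subject) {
  stem <- sprintf("subject%02d", subject)
  read_channel <- function(ch) {
    p <- file.path(dir, sprintf("%s_%s.csv", stem, ch))
    if (!file.exists(p)) return(NULL)
    d <- data.table::fread(p)
    meta <- jsonlite::read_json(file.path(dir,
                                          sprintf("%s_%s.json", stem, ch)))
    signal_record(d$value, fs = meta$fs, channel = meta$channel,
                  t0 = meta$t0, units = meta$units)
  }
  ann <- as.data.frame(data.table::fread(
    file.path(dir, sprintf("%s_annotations.csv", stem))))
  trig <- as.data.frame(data.table::fread(
    file.path(dir, sprintf("%s_triggers.csv", stem))))
  list(subject = subject, ecg = read_channel("ecg"),
       scl = read_channel("scl"), annotations = ann,
       truth = list(trigger_times = trig$time_s, sam = ann$sam))
}

#' Write a cohort to disk
#' @param cohort List of sessions.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  for (s in cohort) write_session(s, dir)
  jsonlite::write_json(list(n_subjects = length(cohort)),
                       file.path(dir, "cohort.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir Directory.
#' @return List of sessions.
#' @export
read_cohort <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "cohort.json"))
  lapply(seq_len(meta$n_subjects), function(s) read_session(dir, s))
}
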