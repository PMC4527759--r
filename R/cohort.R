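#' Per-individual cohort observation records
#'
#' A cohort log holds one row per individual per observation interval:
#' the number of eggs laid in the hanging drop during the interval, the
#' number of juveniles that later hatched from those eggs (eggs stay in the
#' drop long enough for every fertile egg to hatch, so hatch counts are
#' credited to the interval in which the egg was laid), and the vital status
#' of the individual at the interval's end.
#'
#' @param records A data frame with columns `individual_id`, `interval_start`,
#'   `interval_end`, `eggs_laid`, `juveniles_hatched`, `status` (each status
#'   one of `"alive"`, `"dead"`).
#' @return A validated `cohort_records` data frame, sorted by individual and
#'   interval start.
#' @export
cohort_records <- function(records) {
  required <- c("individual_id", "interval_start", "interval_end",
                "eggs_laid", "juveniles_hatched", "status")
  missing <- setdiff(required, names(records))
  if (length(missing))
    stop("cohort log is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  records <- as.data.frame(records)[required]
  records$individual_id <- as.character(records$individual_id)
  for (col in c("interval_start", "interval_end", "eggs_laid",
                "juveniles_hatched"))
    records[[col]] <- as.numeric(records[[col]])
  records$status <- as.character(records$status)
  records <- records[order(records$individual_id, records$interval_start), ,
                     drop = FALSE]
  rownames(records) <- NULL
  validate_cohort_records(records)
  structure(records, class = c("cohort_records", "data.frame"))
}

validate_cohort_records <- function(records) {
  if (nrow(records) == 0L) return(invisible(records))
  bad_status <- !records$status %in% c("alive", "dead")
  if (any(bad_status))
    stop_record(records, which(bad_status)[1],
                "status must be 'alive' or 'dead'")
  if (anyNA(records$interval_start) || anyNA(records$interval_end) ||
      anyNA(records$eggs_laid) || anyNA(records$juveniles_hatched))
    stop("cohort log contains missing values", call. = FALSE)
  bad <- records$interval_end <= records$interval_start
  if (any(bad))
    stop_record(records, which(bad)[1], "interval_end must exceed interval_start")
  bad <- records$eggs_laid < 0 | records$juveniles_hatched < 0 |
    records$eggs_laid != round(records$eggs_laid) |
    records$juveniles_hatched != round(records$juveniles_hatched)
  if (any(bad))
    stop_record(records, which(bad)[1], "counts must be nonnegative integers")
  bad <- records$juveniles_hatched > records$eggs_laid
  if (any(bad))
    stop_record(records, which(bad)[1],
                "juveniles_hatched exceeds eggs_laid")
  for (idx in split(seq_len(nrow(records)), records$individual_id)) {
    i <- idx[order(records$interval_start[idx])]
    if (any(diff(records$interval_start[i]) <= 0))
      stop_record(records, i[1], "duplicated or unordered intervals")
    dead <- which(records$status[i] == "dead")
    if (length(dead) && any(dead < length(i)))
      stop_record(records, i[dead[1] + 1L],
                  "record present after individual was scored dead")
  }
  invisible(records)
}

stop_record <- function(records, i, msg) {
  stop(sprintf("invalid cohort record (individual %s, interval %g-%g h): %s",
               records$individual_id[i], records$interval_start[i],
               records$interval_end[i], msg), call. = FALSE)
}

#' Read a cohort observation log
#'
#' Reads a tab-separated cohort log (UTF-8, header required, `.` decimal
#' separator) with columns `individual_id`, `interval_start`, `interval_end`,
#' `eggs_laid`, `juveniles_hatched`, `status`, validates every record, and
#' returns them grouped by individual and ordered by interval start.
#'
#' @param path Path to a TSV file. Lines starting with `#` are ignored.
#' @return A `cohort_records` data frame (possibly with zero rows).
#' @export
read_cohort <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("individual_id", "interval_start", "interval_end",
                "eggs_laid", "juveniles_hatched", "status")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("cohort log '%s' is missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  cohort_records(df)
}

#' Write a cohort observation log
#'
#' @param records A `cohort_records` data frame.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  stopifnot(inherits(records, "cohort_records"))
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-individual summaries of a cohort log
#'
#' Collapses a cohort log to one row per individual: age at first egg
#' deposition, death interval (if observed), lifetime egg and juvenile
#' totals, and censoring status. Interval-censored event times (death, first
#' egg) are imputed at the midpoint of the interval in which they were
#' scored.
#'
#' @param records A `cohort_records` data frame.
#' @return A data frame with one row per individual: `individual_id`,
#'   `first_egg_age` (h, midpoint-imputed, `NA` if no egg ever),
#'   `death_age` (h, midpoint-imputed, `NA` if right-censored),
#'   `censored_at` (h, last checkpoint for censored individuals, else `NA`),
#'   `total_eggs`, `total_juveniles`.
#' @export
individual_summaries <- function(records) {
  stopifnot(inherits(records, "cohort_records"))
  ids <- unique(records$individual_id)
  out <- lapply(ids, function(id) {
    r <- records[records$individual_id == id, , drop = FALSE]
    first <- which(r$eggs_laid > 0)[1]
    dead <- which(r$status == "dead")
    data.frame(
      individual_id = id,
      first_egg_age = if (is.na(first)) NA_real_ else
        (r$interval_start[first] + r$interval_end[first]) / 2,
      death_age = if (length(dead)) (r$interval_start[dead] +
                                       r$interval_end[dead]) / 2 else NA_real_,
      censored_at = if (length(dead)) NA_real_ else
        r$interval_end[nrow(r)],
      total_eggs = sum(r$eggs_laid),
      total_juveniles = sum(r$juveniles_hatched)
    )
  })
  do.call(rbind, out)
}

#' @export
print.cohort_records <- function(x, ...) {
  n_ind <- length(unique(x$individual_id))
  cat(sprintf("<cohort_records> %d individuals, %d interval records\n",
              n_ind, nrow(x)))
  if (nrow(x)) NextMethod()
  invisible(x)
}
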