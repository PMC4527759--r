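#' Observation schedules
#'
#' An observation schedule is the ordered set of checkpoint times (hours on
#' the shared cohort clock, i.e. hours since the midpoint of the hatching
#' synchronization window) at which a cohort is inspected, together with the
#' width of the interval each checkpoint closes. Checkpoint `i` scores the
#' interval `(checkpoints[i] - widths[i], checkpoints[i]]`: eggs laid in the
#' drop during that interval, juveniles hatched from those eggs (scored after
#' the drop has been left undisturbed), and vital status at the checkpoint.
#'
#' @param checkpoints Numeric vector of checkpoint times in hours, strictly
#'   increasing and positive.
#' @param widths Numeric vector of interval widths in hours (strictly
#'   positive), one per checkpoint. If `NULL`, widths are derived from
#'   consecutive checkpoint differences (the first interval starts at 0).
#' @return An object of class `observation_schedule`: a data frame with
#'   columns `checkpoint` and `width`.
#' @examples
#' observation_schedule(c(24, 48, 54, 60), c(24, 24, 6, 6))
#' @export
observation_schedule <- function(checkpoints, widths = NULL) {
  checkpoints <- as.numeric(checkpoints)
  if (length(checkpoints) == 0L)
    stop("schedule needs at least one checkpoint", call. = FALSE)
  if (anyNA(checkpoints) || any(checkpoints <= 0))
    stop("checkpoints must be positive and non-missing", call. = FALSE)
  if (is.unsorted(checkpoints, strictly = TRUE))
    stop("checkpoints must be strictly increasing", call. = FALSE)
  if (is.null(widths)) widths <- diff(c(0, checkpoints))
  widths <- as.numeric(widths)
  if (length(widths) != length(checkpoints))
    stop("widths must match checkpoints in length", call. = FALSE)
  if (anyNA(widths) || any(widths <= 0))
    stop("interval widths must be strictly positive", call. = FALSE)
  starts <- checkpoints - widths
  if (any(starts < 0))
    stop("first interval starts before time 0", call. = FALSE)
  if (any(starts[-1] < checkpoints[-length(checkpoints)] - 1e-9))
    stop("intervals overlap: width reaches back past the previous checkpoint",
         call. = FALSE)
  structure(
    data.frame(checkpoint = checkpoints, width = widths),
    class = c("observation_schedule", "data.frame")
  )
}

#' Is a schedule contiguous?
#'
#' A schedule is contiguous when every interval starts exactly where the
#' previous one ends (and the first starts at 0), so the checkpoints tile the
#' whole observation horizon with no gaps.
#'
#' @param schedule An [observation_schedule()].
#' @param tol Numeric tolerance in hours.
#' @return Logical scalar.
#' @export
is_contiguous <- function(schedule, tol = 1e-8) {
  stopifnot(inherits(schedule, "observation_schedule"))
  starts <- schedule$checkpoint - schedule$width
  all(abs(starts - c(0, schedule$checkpoint[-nrow(schedule)])) <= tol)
}

#' Default hanging-drop observation cadence
#'
#' The standard inspection cadence for a synchronized hanging-drop cohort:
#' daily checks while juveniles develop, 6-h transfers through the period of
#' maximum egg laying (up to 126 h), 12-h transfers while fecundity declines
#' (up to 294 h), then daily checks until the observation horizon.
#'
#' @param horizon End of observation in hours (default 1200 h = 50 d, long
#'   enough that essentially all individuals have died).
#' @return An [observation_schedule()].
#' @export
default_schedule <- function(horizon = 1200) {
  if (horizon < 318) stop("horizon must be at least 318 h", call. = FALSE)
  cp <- c(seq(24, 48, by = 24),
          seq(54, 126, by = 6),
          seq(138, 294, by = 12),
          seq(318, by = 24, length.out = ceiling((horizon - 318) / 24) + 1))
  observation_schedule(cp)
}

#' Parse a compact schedule specification
#'
#' Accepts a comma-separated list of `from:to:by` segments, e.g.
#' `"0:48:24,48:126:6,126:294:12,294:1200:24"`. Each segment contributes the
#' checkpoints `from+by, from+2*by, ..., to`.
#'
#' @param spec Character scalar.
#' @return An [observation_schedule()].
#' @export
parse_schedule_spec <- function(spec) {
  segs <- strsplit(trimws(spec), ",", fixed = TRUE)[[1]]
  cps <- lapply(segs, function(s) {
    p <- as.numeric(strsplit(s, ":", fixed = TRUE)[[1]])
    if (length(p) != 3L || anyNA(p) || p[3] <= 0 || p[2] <= p[1])
      stop("bad schedule segment: ", s, call. = FALSE)
    seq(p[1] + p[3], p[2], by = p[3])
  })
  observation_schedule(sort(unique(unlist(cps))))
}

#' @export
print.observation_schedule <- function(x, ...) {
  cat(sprintf("<observation_schedule> %d checkpoints, %g–%g h%s\n",
              nrow(x), x$checkpoint[1], x$checkpoint[nrow(x)],
              if (is_contiguous(x)) ", contiguous" else ""))
  invisible(x)
}
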