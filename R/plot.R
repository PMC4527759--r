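#' Survival, fecundity and egg-production figure
#'
#' Renders the three cohort-level curves from either a cohort log or a
#' ready-made life table: the survival step curve `lx` over age, the
#' fecundity percentage (hatched/laid, mean over alive mature individuals;
#' only available from a cohort log), and the mean egg production per
#' individual rescaled to eggs per 24 h so intervals of unequal width are
#' comparable.
#'
#' @param x A `cohort_records` data frame or a [life_table()].
#' @param schedule An [observation_schedule()]; required when `x` is a
#'   cohort log.
#' @return A ggplot object (one panel per curve).
#' @export
plot_life_history <- function(x, schedule = NULL) {
  if (inherits(x, "cohort_records")) {
    if (is.null(schedule))
      stop("a schedule is required to plot a cohort log", call. = FALSE)
    lt <- build_life_table(x, schedule)
    fec <- fecundity_schedule(x)
  } else if (inherits(x, "life_table")) {
    lt <- x
    fec <- NULL
  } else {
    stop("x must be cohort_records or a life_table", call. = FALSE)
  }
  panels <- data.frame(
    time = lt$time,
    value = lt$lx,
    panel = "Survival probability (lx)"
  )
  if (nrow(lt))
    panels <- rbind(panels, data.frame(
      time = lt$time,
      value = lt$mx / lt$D * 24,
      panel = "Juveniles per individual per 24 h"
    ))
  if (!is.null(fec)) {
    has <- !is.na(fec$fecundity_pct)
    if (any(has)) {
      panels <- rbind(panels, data.frame(
        time = fec$time[has],
        value = fec$fecundity_pct[has],
        panel = "Fecundity (% eggs hatched)"
      ))
    } else {
      warning("no fecundity data to plot (no eggs laid)", call. = FALSE)
    }
  }
  ggplot2::ggplot(panels, ggplot2::aes(x = time, y = value)) +
    ggplot2::geom_step(data = panels[panels$panel ==
                                       "Survival probability (lx)", ]) +
    ggplot2::geom_line(data = panels[panels$panel !=
                                       "Survival probability (lx)", ]) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Age (h)", y = NULL) +
    ggplot2::theme_bw()
}
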