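# Conversion of sparse 0-10 self-reports into per-frame three-class labels:
# backward shift (reports lag the reaction), zero-order hold, maximum per
# frame, and a double threshold separating no-pain / moderate / severe.

PAIN_CLASSES <- c("no_pain", "moderate_pain", "severe_pain")

#' Labeling configuration
#'
#' @param shift_s Backward time shift applied to every report in seconds
#'   (default 2), compensating the subject's delayed reaction.
#' @param t_low Lower pain threshold: ratings strictly below it are
#'   no-pain (default 4).
#' @param t_high Higher threshold: ratings at or above it are severe pain
#'   (default 7). Ratings in between are moderate. Because pain resistance
#'   is subject-dependent the thresholds are free parameters, not claims
#'   about the rating scale.
#' @return An object of class `labeling_config`.
#' @export
labeling_config <- function(shift_s = 2, t_low = 4, t_high = 7) {
  stopifnot(shift_s >= 0, t_low >= 0, t_low < t_high, t_high <= 10)
  structure(list(shift_s = shift_s, t_low = t_low, t_high = t_high),
            class = "labeling_config")
}

#' Shifted zero-order-hold step function of the pain rating
#'
#' Each report time is reduced by `shift_s` (floored at 0) and its rating
#' held constant until the next shifted report; before the first report
#' the rating is 0.
#'
#' @param reports A [pain_reports()] series.
#' @param shift_s Backward shift in seconds.
#' @return An object of class `rating_step`: list with the shifted
#'   `times`, the held `ratings`, and evaluate with [step_rating()].
#' @export
rating_step_function <- function(reports, shift_s = 2) {
  stopifnot(inherits(reports, "pain_reports"), shift_s >= 0)
  structure(
    list(times = pmax(0, reports$times - shift_s), ratings = reports$ratings),
    class = "rating_step"
  )
}

#' Evaluate a rating step function at given times
#'
#' @param step A [rating_step_function()] result.
#' @param t Numeric vector of times in seconds.
#' @return The held rating at each time (0 before the first report).
#' @export
step_rating <- function(step, t) {
  stopifnot(inherits(step, "rating_step"))
  if (!length(step$times)) return(rep(0, length(t)))
  idx <- findInterval(t, step$times)
  out <- numeric(length(t))
  out[idx >= 1] <- step$ratings[idx[idx >= 1]]
  out
}

#' Label analysis frames from self-reports
#'
#' Each half-open frame `[start, start + window)` is tagged with the
#' maximum of the shifted step function over the frame, then classified:
#' `no_pain` if the maximum is strictly below `t_low`, `severe_pain` if at
#' or above `t_high`, `moderate_pain` otherwise.
#'
#' @param reports A [pain_reports()] series.
#' @param duration_s Session duration in seconds (defines the frame
#'   count).
#' @param framing A [framing_spec()].
#' @param config A [labeling_config()].
#' @return An object of class `frame_labels`: list with factor `class`,
#'   numeric `max_rating`, and `frame_start_s`.
#' @export
label_frames <- function(reports, duration_s, framing = framing_spec(),
                         config = labeling_config()) {
  stopifnot(inherits(reports, "pain_reports"),
            inherits(framing, "framing_spec"),
            inherits(config, "labeling_config"))
  step <- rating_step_function(reports, config$shift_s)
  nf <- n_frames(duration_s, framing)
  starts <- (seq_len(nf) - 1) * framing$hop_s
  max_rating <- vapply(starts, function(s) {
    e <- s + framing$window_s
    # The maximum over [s, e) is attained at the frame start (held value)
    # or at a shifted report time inside the frame.
    inside <- step$times >= s & step$times < e
    max(step_rating(step, s), if (any(inside)) step$ratings[inside] else -Inf)
  }, numeric(1))
  cls <- ifelse(max_rating < config$t_low, "no_pain",
                ifelse(max_rating >= config$t_high,
                       "severe_pain", "moderate_pain"))
  structure(
    list(class = factor(cls, levels = PAIN_CLASSES),
         max_rating = max_rating, frame_start_s = starts,
         config = config),
    class = "frame_labels"
  )
}

#' @export
print.frame_labels <- function(x, ...) {
  tab <- table(x$class)
  cat(sprintf("<frame_labels: %d frames (%s)>\n", length(x$class),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.frame_labels <- function(x, ...) {
  data.frame(frame_start_s = x$frame_start_s, max_rating = x$max_rating,
             class = x$class)
}
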