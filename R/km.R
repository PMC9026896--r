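#' Kaplan-Meier product-limit curve
#'
#' Standard product-limit estimator: at each distinct event time the
#' survival probability multiplies by `1 - d/n` (d events among n at risk).
#' Without censoring this equals the empirical survival function.
#'
#' @param times Positive event/censoring times (days).
#' @param events Logical vector aligned with `times`: TRUE = event (death),
#'   FALSE = right-censored. Defaults to all events.
#' @return An object of class `km_curve`: a tibble with one row per
#'   distinct time (`time`, `n_risk`, `n_event`, `n_censor`, `survival`),
#'   starting implicitly at S(0) = 1.
#' @examples
#' build_km(c(18, 19, 20, 21, 22))
#' @export
build_km <- function(times, events = rep(TRUE, length(times))) {
  if (length(times) == 0) abort("`times` must be nonempty.")
  if (any(times <= 0)) abort("`times` must be strictly positive.")
  if (length(events) != length(times)) {
    abort("`events` must align with `times`.")
  }
  events <- as.logical(events)
  n <- length(times)
  tab <- tibble(time = times, event = events) |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(n_event = sum(.data$event),
                     n_censor = sum(!.data$event), .groups = "drop") |>
    dplyr::arrange(.data$time)
  # at risk just before each time: everyone with time >= t
  tab$n_risk <- n - dplyr::lag(cumsum(tab$n_event + tab$n_censor), default = 0L)
  tab$survival <- cumprod(1 - tab$n_event / tab$n_risk)
  out <- tab[, c("time", "n_risk", "n_event", "n_censor", "survival")]
  class(out) <- c("km_curve", class(out))
  attr(out, "n") <- n
  out
}

#' Median survival of a Kaplan-Meier curve
#'
#' Smallest time at which the survival probability drops to 0.5 or below;
#' `NA` if the curve never reaches 0.5.
#'
#' @param km A [build_km()] result.
#' @return Median survival time in days, or `NA`.
#' @export
km_median <- function(km) {
  stopifnot(inherits(km, "km_curve"))
  hit <- km$time[km$survival <= 0.5]
  if (length(hit) == 0) NA_real_ else hit[1]
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, %d event time(s), median = %s days\n",
              attr(x, "n"), sum(x$n_event > 0),
              format(km_median(x))))
  NextMethod()
}

#' @rdname build_km
#' @param object A `km_curve`.
#' @param ... Unused.
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- tibble(time = c(0, object$time), survival = c(1, object$survival))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$survival)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Days post-inoculation", y = "Projected survival") +
    ggplot2::theme_minimal()
}

#' Mantel-Cox log-rank test for two groups
#'
#' At each distinct event time, compares the observed events in group A
#' with the expectation under the null of identical hazards, using the
#' hypergeometric variance; the statistic `(sum(O - E))^2 / sum(V)` is
#' referred to chi-square with 1 df (two-sided). With no events anywhere,
#' the statistic is 0 and p = 1.
#'
#' @param times_a,times_b Positive times per group.
#' @param events_a,events_b Logical event indicators (default all TRUE).
#' @return An object of class `logrank_test`: list with `statistic`,
#'   `p_value`, `observed_a`, `expected_a`.
#' @examples
#' logrank_test(c(1, 2), c(3, 4))
#' @export
logrank_test <- function(times_a, times_b,
                         events_a = rep(TRUE, length(times_a)),
                         events_b = rep(TRUE, length(times_b))) {
  if (length(times_a) == 0 || length(times_b) == 0) {
    abort("Both groups must be nonempty.")
  }
  time <- c(times_a, times_b)
  event <- c(as.logical(events_a), as.logical(events_b))
  in_a <- rep(c(TRUE, FALSE), c(length(times_a), length(times_b)))
  event_times <- sort(unique(time[event]))
  o_minus_e <- 0
  v_sum <- 0
  o_a <- 0
  e_a <- 0
  for (t in event_times) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n_a <- sum(at_risk & in_a)
    d_t <- sum(event & time == t)
    d_a <- sum(event & time == t & in_a)
    e <- d_t * n_a / n_t
    v <- if (n_t > 1) {
      d_t * (n_a / n_t) * (1 - n_a / n_t) * (n_t - d_t) / (n_t - 1)
    } else 0
    o_minus_e <- o_minus_e + (d_a - e)
    v_sum <- v_sum + v
    o_a <- o_a + d_a
    e_a <- e_a + e
  }
  if (v_sum == 0) {
    stat <- 0
    p <- 1
  } else {
    stat <- o_minus_e^2 / v_sum
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(
    list(statistic = stat, p_value = p, observed_a = o_a, expected_a = e_a),
    class = "logrank_test"
  )
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("<logrank_test> chi-square = %.4g (1 df), p = %.4g\n",
              x$statistic, x$p_value))
  cat(sprintf("  group A: observed %d events, expected %.3g\n",
              as.integer(x$observed_a), x$expected_a))
  invisible(x)
}

#' @rdname logrank_test
#' @param x A `logrank_test`.
#' @param ... Unused.
#' @export
tidy.logrank_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value, df = 1,
         observed_a = x$observed_a, expected_a = x$expected_a)
}

#' Compare two projected cohorts by log-rank
#'
#' Builds projected KM inputs from two [project_cohort()] results and runs
#' the Mantel-Cox test. Zero-area mice enter as censored at their
#' measurement day.
#'
#' @param proj_a,proj_b `projection` tibbles from [project_cohort()].
#' @return A [logrank_test()] result.
#' @export
compare_projected_survival <- function(proj_a, proj_b) {
  stopifnot(inherits(proj_a, "projection"), inherits(proj_b, "projection"))
  logrank_test(proj_a$km_time, proj_b$km_time,
               proj_a$km_event, proj_b$km_event)
}
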