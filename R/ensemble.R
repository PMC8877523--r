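#' Histogram of translocation or rejection times
#'
#' Bins the event times of one outcome kind into intervals
#' `[k dt - dt/2, k dt + dt/2)`. With the default normalization each bin
#' holds the fraction of successful events of that kind; with
#' `normalization = "attempts"` the denominator is every engagement attempt
#' in `events`.
#'
#' @param events A per-trial events tibble from [run_trials()]/[run_batch()].
#' @param outcome `"translocated"` or `"rejected"`.
#' @param dt Bin width in MCT.
#' @param normalization Denominator choice: `"events"` (events of the kind)
#'   or `"attempts"` (all trials).
#' @return A `patrans_time_pdf` tibble: `bin_center`, `count`, `prob`.
#' @export
time_pdf <- function(events, outcome = "translocated", dt = 1600,
                     normalization = c("events", "attempts")) {
  outcome <- match.arg(outcome, outcome_levels[1:2])
  normalization <- match.arg(normalization)
  stopifnot(dt >= 1)
  times <- events$time[events$outcome == outcome]
  denom <- if (normalization == "events") length(times) else nrow(events)
  if (length(times) == 0L) {
    warning("no ", outcome, " events; empty PDF", call. = FALSE)
    out <- tibble::tibble(bin_center = numeric(0), count = integer(0),
                          prob = numeric(0))
  } else {
    k <- round(times / dt)
    tab <- table(k)
    out <- tibble::tibble(bin_center = as.numeric(names(tab)) * dt,
                          count = as.integer(tab),
                          prob = as.integer(tab) / denom)
  }
  structure(out, class = c("patrans_time_pdf", class(out)),
            dt = dt, outcome = outcome, normalization = normalization,
            n_events = length(times), n_attempts = nrow(events))
}

#' Power-law tail exponent of a time PDF
#'
#' Least-squares slope of log10(prob) against log10(t) over the fit window,
#' the estimator compared against the predicted relaxation-tail exponent
#' -(1 + mu). The first bin (engagement transient) and bins with fewer
#' than `min_count` events are excluded.
#'
#' @param pdf A [time_pdf()] result.
#' @param window Fit window `c(t1, t2)` in MCT.
#' @param min_count Minimum events per bin.
#' @param drop_first Drop the first nonempty bin?
#' @return A `patrans_tail_fit` object; see [tidy()]/[glance()] methods.
#' @export
tail_exponent <- function(pdf, window = c(1e4, 1e5), min_count = 5L,
                          drop_first = TRUE) {
  df <- tibble::as_tibble(pdf)
  if (drop_first && nrow(df) > 0L) df <- df[-1, ]
  df <- dplyr::filter(df, .data$count >= min_count,
                      .data$bin_center >= window[1],
                      .data$bin_center <= window[2],
                      .data$bin_center > 0)
  if (nrow(df) < 5L) {
    stop("need at least 5 usable bins in the fit window; got ", nrow(df),
         call. = FALSE)
  }
  fit <- stats::lm(log10(prob) ~ log10(bin_center), data = df)
  structure(list(fit = fit, window = window, n_bins = nrow(df),
                 slope = unname(stats::coef(fit)[2]),
                 se = unname(sqrt(diag(stats::vcov(fit)))[2])),
            class = "patrans_tail_fit")
}

#' @export
print.patrans_tail_fit <- function(x, ...) {
  cat(sprintf("power-law tail fit: slope = %.3f +/- %.3f over %d bins in [%g, %g]\n",
              x$slope, x$se, x$n_bins, x$window[1], x$window[2]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a tail fit
#'
#' @param x A `patrans_tail_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per coefficient; `glance()`: one-row model
#'   summary with `slope`, `se`, `r.squared`, `n_bins`.
#' @export
tidy.patrans_tail_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(cf), estimate = cf[, 1],
                 std.error = cf[, 2], statistic = cf[, 3],
                 p.value = cf[, 4])
}

#' @rdname tidy.patrans_tail_fit
#' @export
glance.patrans_tail_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, se = x$se,
                 r.squared = summary(x$fit)$r.squared,
                 n_bins = x$n_bins)
}

#' Decay of the trapped population
#'
#' Fraction of all engagement attempts not yet absorbed at each grid time;
#' starts at 1 and is nonincreasing. The long-time decay of this curve is
#' logarithmic for disordered ensembles.
#'
#' @param events Per-trial events tibble.
#' @param grid Time grid (MCT); defaults to a logarithmic grid up to the
#'   largest recorded time.
#' @return A `patrans_trapped_curve` tibble: `t`, `fraction`.
#' @export
trapped_curve <- function(events, grid = NULL) {
  stopifnot(nrow(events) > 0L)
  if (is.null(grid)) {
    grid <- unique(round(10^seq(0, log10(max(events$time)), length.out = 200)))
  }
  absorbed <- events$time[events$outcome != "trapped"]
  frac <- 1 - vapply(grid, function(tt) mean(absorbed <= tt) *
                       length(absorbed) / nrow(events), 0)
  structure(tibble::tibble(t = grid, fraction = frac),
            class = c("patrans_trapped_curve", class(tibble::tibble())),
            n_attempts = nrow(events))
}

#' Outcome percentages resolved by charge descriptors
#'
#' Cross-tabulates attempt outcomes by net charge Q and either the head
#' window charge Qh or the minimum window charge Qmin, giving
#' attempt-weighted percentages per cell. Cells always sum to 100 within
#' rounding; empty cells are flagged by `n_attempts = 0` absence.
#'
#' @param events Per-trial events tibble carrying `Q` and the grouping
#'   descriptor (as produced by [run_batch()]).
#' @param by `"Qh"` or `"Qmin"`.
#' @return A `patrans_outcome_matrix` tibble.
#' @export
outcome_matrix <- function(events, by = c("Qh", "Qmin")) {
  by <- match.arg(by)
  out <- events |>
    dplyr::group_by(.data$Q, .data[[by]]) |>
    dplyr::summarise(
      n_attempts = dplyr::n(),
      pct_translocated = 100 * mean(.data$outcome == "translocated"),
      pct_rejected = 100 * mean(.data$outcome == "rejected"),
      pct_trapped = 100 * mean(.data$outcome == "trapped"),
      .groups = "drop"
    )
  structure(out, class = c("patrans_outcome_matrix", class(out)), by = by)
}

#' Population-percentile translocation times
#'
#' For each population fraction f, the earliest multiple of `dt` by which
#' the cumulative translocated fraction of *all* engagement attempts
#' reaches f. Fractions not reached within the recorded horizon come back
#' `NA` (unreachable at this waiting time).
#'
#' @param events Per-trial events tibble.
#' @param fractions Population fractions in (0, 1).
#' @param dt Time resolution in MCT.
#' @return A tibble: `fraction`, `time`.
#' @export
percentile_times <- function(events, fractions = (1:10) / 100, dt = 400) {
  stopifnot(all(fractions > 0 & fractions < 1), nrow(events) > 0L)
  times <- sort(events$time[events$outcome == "translocated"])
  n <- nrow(events)
  time_at <- vapply(fractions, function(f) {
    k <- ceiling(f * n) # attempts needed
    if (k > length(times)) return(NA_real_)
    ceiling(times[k] / dt) * dt
  }, 0)
  tibble::tibble(fraction = fractions, time = time_at)
}

#' Filter a record table by descriptor predicate
#'
#' Thin wrapper over [dplyr::filter()] for sequence tables, summaries or
#' event tables carrying Q/Qh/Qmin columns; predicates compose.
#'
#' @param records A tibble with descriptor columns.
#' @param ... Filter expressions, e.g. `Q == 16`, `Qmin > 0`.
#' @return The filtered tibble.
#' @export
subensemble <- function(records, ...) {
  dplyr::filter(records, ...)
}

#' @export
autoplot.patrans_time_pdf <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df[df$prob > 0, ],
                  ggplot2::aes(x = .data$bin_center, y = .data$prob)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "t  [MCT]",
                  y = paste0("P(", attr(object, "outcome"), ")"),
                  subtitle = paste0("dt = ", attr(object, "dt"), " MCT")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.patrans_trapped_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$t, y = .data$fraction)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "t  [MCT]", y = "trapped fraction") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.patrans_outcome_matrix <- function(object, ...) {
  by <- attr(object, "by")
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(dplyr::starts_with("pct_"),
                        names_to = "outcome", values_to = "pct",
                        names_prefix = "pct_")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$Q, y = .data[[by]],
                                   fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~outcome) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100)) +
    ggplot2::labs(fill = "%") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
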