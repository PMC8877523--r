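#' Simulation configuration
#'
#' Bundles the knobs shared by every Monte Carlo and exact-solver run: the
#' waiting time `tw` (in Monte Carlo time steps, MCT; one MCT is one
#' attempted whole-chain hop), the engagement direction, the number of
#' trials per sequence, the master seed, and the pore profile.
#'
#' @param tw Waiting time in MCT after which an unabsorbed chain is
#'   classified as trapped. Default 1.6e5; use 1e6 for long-horizon runs.
#' @param direction `"cis_to_trans"` (default) or `"trans_to_cis"`.
#' @param trials Trials per sequence.
#' @param seed Master seed; per-trial streams are derived from it, the
#'   sequence id and the trial index, so results are independent of batch
#'   order.
#' @param profile A [pore_profile()].
#' @return A `patrans_config` list.
#' @export
sim_config <- function(tw = 1.6e5, direction = "cis_to_trans",
                       trials = 100L, seed = 1L,
                       profile = pore_profile()) {
  direction <- check_direction(direction)
  stopifnot(tw >= 1, trials >= 1, is.finite(seed))
  structure(list(tw = tw, direction = direction, trials = as.integer(trials),
                 seed = seed, profile = profile),
            class = "patrans_config")
}

outcome_levels <- c("translocated", "rejected", "trapped")

acceptance_probs <- function(landscape) {
  E <- landscape$E
  n <- length(E)
  Et <- E[2:(n - 1)]
  list(up = pmin(1, exp(-(E[3:n] - Et))),
       dn = pmin(1, exp(-(E[1:(n - 2)] - Et))))
}

#' Run Metropolis translocation trials for one sequence
#'
#' Each trial starts from the engaged state (x = 0), attempts one +/-1
#' whole-chain hop per MCT with the standard Metropolis acceptance on the
#' landscape energy difference, and ends at absorption (translocation or
#' rejection) or at the waiting time (trapped). `run_trial()` returns a
#' single trial; `run_trials()` aggregates `config$trials` of them.
#'
#' @param charges A +/-1 charge vector.
#' @param config A [sim_config()].
#' @param id Sequence label used in output and for seed derivation.
#' @param landscape Optional precomputed [build_landscape()] (must match
#'   `charges`/`config`).
#' @return `run_trial()`: a one-row tibble with `outcome`, `time`, `x`.
#'   `run_trials()`: a list-free tibble of per-trial events.
#' @export
run_trial <- function(charges, config = sim_config(), id = NULL,
                      landscape = NULL) {
  run_trials(charges, config = modify_trials(config, 1L), id = id,
             landscape = landscape)
}

modify_trials <- function(config, trials) {
  config$trials <- as.integer(trials)
  config
}

#' @rdname run_trial
#' @export
run_trials <- function(charges, config = sim_config(), id = NULL,
                       landscape = NULL) {
  charges <- check_charges(charges)
  if (is.null(landscape)) {
    landscape <- build_landscape(charges, config$direction, config$profile,
                                 id = id)
  }
  id <- id %||% landscape$id
  acc <- acceptance_probs(landscape)
  m <- mc_trials_cpp(acc$up, acc$dn, config$tw, config$trials,
                     config$seed, fnv1a_hash(id))
  tibble::tibble(
    id = id,
    trial = seq_len(config$trials),
    outcome = factor(outcome_levels[m[, 1]], levels = outcome_levels),
    time = m[, 2],
    x = m[, 3]
  )
}

summarise_events <- function(events) {
  events |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      trials = dplyr::n(),
      n_translocated = sum(.data$outcome == "translocated"),
      n_rejected = sum(.data$outcome == "rejected"),
      n_trapped = sum(.data$outcome == "trapped"),
      pct_translocated = 100 * .data$n_translocated / .data$trials,
      pct_rejected = 100 * .data$n_rejected / .data$trials,
      pct_trapped = 100 * .data$n_trapped / .data$trials,
      mean_ttr = mean(.data$time[.data$outcome == "translocated"]),
      sd_ttr = stats::sd(.data$time[.data$outcome == "translocated"]),
      mean_trej = mean(.data$time[.data$outcome == "rejected"]),
      sd_trej = stats::sd(.data$time[.data$outcome == "rejected"]),
      .groups = "drop"
    )
}

#' Run a batch of sequences
#'
#' Applies [run_trials()] to every row of a sequence tibble. Per-trial
#' seeds are derived from `(config$seed, id, trial)`, so a batch gives
#' bit-identical results to running each sequence alone.
#'
#' @param sequences A sequence tibble (see [sequence_tbl()]).
#' @param config A [sim_config()].
#' @param keep_events Keep per-trial events (needed for time histograms)?
#' @return A list with `summary` (one row per sequence, joined with the
#'   sequence descriptors) and, if requested, `events`.
#' @export
run_batch <- function(sequences, config = sim_config(), keep_events = TRUE) {
  if (nrow(sequences) == 0L) {
    empty <- tibble::tibble(
      id = character(0), N = integer(0), Q = integer(0), Qh = integer(0),
      Qmin = integer(0), trials = integer(0), n_translocated = integer(0),
      n_rejected = integer(0), n_trapped = integer(0),
      pct_translocated = numeric(0), pct_rejected = numeric(0),
      pct_trapped = numeric(0), mean_ttr = numeric(0), sd_ttr = numeric(0),
      mean_trej = numeric(0), sd_trej = numeric(0))
    return(list(summary = empty, events = NULL))
  }
  events <- purrr::map2(sequences$seq, sequences$id, function(q, id) {
    run_trials(q, config, id = id)
  })
  events <- dplyr::bind_rows(events)
  summary <- summarise_events(events) |>
    dplyr::left_join(
      dplyr::select(sequences, "id", "N", "Q", "Qh", "Qmin"),
      by = "id") |>
    dplyr::relocate("N", "Q", "Qh", "Qmin", .after = "id")
  list(summary = summary,
       events = if (keep_events) {
         dplyr::left_join(events,
                          dplyr::select(sequences, "id", "Q", "Qh", "Qmin"),
                          by = "id")
       } else {
         NULL
       })
}
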