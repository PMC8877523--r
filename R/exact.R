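#' Absorbing birth-death chain of the hop dynamics
#'
#' The Metropolis dynamics on a landscape is exactly a discrete-time
#' birth-death chain over the transient offsets x = -5..N with per-state
#' forward probability p(x) = 1/2 min(1, exp(-[E(x+1)-E(x)])), backward
#' probability q(x) = 1/2 min(1, exp(-[E(x-1)-E(x)])) and staying
#' probability 1 - p - q, absorbed at x = -6 (rejection) and x = N+1
#' (translocation). This object is the deterministic oracle for the Monte
#' Carlo engine.
#'
#' @param landscape A [build_landscape()] result.
#' @return A `patrans_chain` object with a `states` tibble (`x`, `p_up`,
#'   `p_down`, `stay`).
#' @export
build_chain <- function(landscape) {
  acc <- acceptance_probs(landscape)
  x <- landscape$offsets[-c(1, length(landscape$offsets))]
  structure(
    list(states = tibble::tibble(x = x,
                                 p_up = acc$up / 2,
                                 p_down = acc$dn / 2,
                                 stay = 1 - acc$up / 2 - acc$dn / 2),
         N = landscape$N,
         direction = landscape$direction,
         id = landscape$id),
    class = "patrans_chain"
  )
}

#' @export
print.patrans_chain <- function(x, ...) {
  cat("absorbing birth-death chain:", nrow(x$states),
      "transient states (x =", min(x$states$x), "..", max(x$states$x), ")\n")
  invisible(x)
}

#' Splitting probability of translocation
#'
#' Probability that the chain reaches the translocation absorber before the
#' rejection absorber, starting from offset `from`. Computed by the
#' classical product-of-ratios recurrence for birth-death chains, in log
#' space; it depends only on the ratios q(x)/p(x), not on the staying
#' probabilities.
#'
#' @param chain A [build_chain()] result.
#' @param from Starting offset (default 0, the engaged state).
#' @return A probability in (0, 1).
#' @export
splitting_probability <- function(chain, from = 0L) {
  st <- chain$states
  i0 <- match(from, st$x)
  if (is.na(i0)) stop("`from` is not a transient offset", call. = FALSE)
  # P(hit top | start i) = sum_{k<i} g_k / sum_{k<=M} g_k,
  # log g_k = cumulative sum of log(q/p) over states 1..k (g_0 = 1)
  lg <- c(0, cumsum(log(st$p_down) - log(st$p_up)))
  lse <- function(v) { m <- max(v); m + log(sum(exp(v - m))) }
  exp(lse(lg[seq_len(i0)]) - lse(lg))
}

#' Exact absorption-time distribution
#'
#' Propagates a point mass at the engaged state through the transient
#' states for `t_max` steps, recording the probability absorbed as
#' translocation and as rejection at every step, plus the survival
#' probability. Mass is conserved to round-off.
#'
#' @param chain A [build_chain()] result.
#' @param t_max Number of steps.
#' @param tol Early-exit survival threshold (0 = run all `t_max` steps).
#' @return A list: `pdf` tibble (`t`, `p_translocate`, `p_reject`),
#'   `survival` at the end, `steps` actually iterated.
#' @export
absorption_time_distribution <- function(chain, t_max, tol = 0) {
  st <- chain$states
  r <- absorb_dist_cpp(st$p_up, st$p_down, t_max, tol)
  steps <- r$steps
  list(
    pdf = tibble::tibble(
      t = seq_len(steps),
      p_translocate = r$p_translocate[seq_len(steps)],
      p_reject = r$p_reject[seq_len(steps)]
    ),
    survival = r$survival,
    occupancy = r$occupancy,
    steps = steps
  )
}

#' Exact three-way classification at the waiting time
#'
#' The exact analogue of [run_trials()]: probabilities of translocation,
#' rejection and trapping by `config$tw`, plus the conditional mean and SD
#' of the translocation time given success (from the truncated absorption
#' distribution). `NA` conditional moments mark a vanishing success
#' probability.
#'
#' @param charges A +/-1 charge vector.
#' @param config A [sim_config()].
#' @param id Optional label.
#' @return A one-row tibble: `id`, `P_tr_inf`, `P_tr`, `P_rej`, `P_trap`,
#'   `mean_ttr`, `sd_ttr`.
#' @export
classify_exact <- function(charges, config = sim_config(), id = NULL) {
  landscape <- build_landscape(charges, config$direction, config$profile,
                               id = id)
  chain <- build_chain(landscape)
  # once survival is below round-off the remaining mass cannot change any
  # reported digit; stop early
  d <- absorption_time_distribution(chain, config$tw, tol = 1e-14)
  ptr <- sum(d$pdf$p_translocate)
  prej <- sum(d$pdf$p_reject)
  if (ptr > 0) {
    m1 <- sum(d$pdf$t * d$pdf$p_translocate) / ptr
    m2 <- sum(d$pdf$t^2 * d$pdf$p_translocate) / ptr
    sd1 <- sqrt(max(m2 - m1^2, 0))
  } else {
    m1 <- NA_real_
    sd1 <- NA_real_
  }
  tibble::tibble(
    id = landscape$id,
    P_tr_inf = splitting_probability(chain),
    P_tr = ptr,
    P_rej = prej,
    P_trap = max(1 - ptr - prej, 0),
    mean_ttr = m1,
    sd_ttr = sd1
  )
}

#' @rdname classify_exact
#' @param sequences A sequence tibble.
#' @export
classify_batch <- function(sequences, config = sim_config()) {
  purrr::map2(sequences$seq, sequences$id,
              function(q, id) classify_exact(q, config, id = id)) |>
    dplyr::bind_rows() |>
    dplyr::left_join(dplyr::select(sequences, "id", "N", "Q", "Qh", "Qmin"),
                     by = "id") |>
    dplyr::relocate("N", "Q", "Qh", "Qmin", .after = "id")
}

transient_matrix <- function(chain) {
  st <- chain$states
  M <- nrow(st)
  T <- diag(st$stay)
  idx <- seq_len(M - 1)
  T[cbind(idx, idx + 1)] <- st$p_up[idx]
  T[cbind(idx + 1, idx)] <- st$p_down[idx + 1]
  T
}

#' Mean first-passage times of the absorbing chain
#'
#' Unconditional mean absorption time and the side-conditioned means, from
#' the first-step linear systems: (I - T) m = 1 for the unconditional mean
#' and (I - T) u = h for the translocation-conditioned one, where h is the
#' vector of splitting probabilities and the conditional mean is u/h. The
#' identity m = P_tr mean_tr + (1 - P_tr) mean_rej holds to solver
#' precision.
#'
#' @param chain A [build_chain()] result.
#' @param from Starting offset.
#' @return A list: `mean`, `mean_translocate`, `mean_reject`, `P_tr`.
#' @export
mean_first_passage <- function(chain, from = 0L) {
  st <- chain$states
  M <- nrow(st)
  i0 <- match(from, st$x)
  if (is.na(i0)) stop("`from` is not a transient offset", call. = FALSE)
  T <- transient_matrix(chain)
  A <- diag(M) - T
  h <- vapply(st$x, function(xx) splitting_probability(chain, xx), 0)
  m <- tryCatch(solve(A, rep(1, M)),
                error = function(e) stop("first-passage solve failed: ",
                                         conditionMessage(e), call. = FALSE))
  u <- solve(A, h)        # E[tau 1_translocate]
  w <- solve(A, 1 - h)    # E[tau 1_reject]
  list(mean = m[i0],
       mean_translocate = u[i0] / h[i0],
       mean_reject = w[i0] / (1 - h[i0]),
       P_tr = h[i0])
}
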