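# Independent per-monomer energy oracle, written directly against the
# printed profile rows (positions -a..5a along the trans-to-cis axis) and
# the documented per-row bulk references. Deliberately loop-based and
# structured differently from the package internals.
oracle_monomer_energy <- function(q, s, direction, profile) {
  V <- profile$V
  is_anion <- if (direction == "cis_to_trans") q > 0 else q < 0
  if (s < -1) return(0)                                   # cis bulk
  if (s > 5) return(if (is_anion) -V else V)              # trans bulk
  j <- 6 - s  # cis-indexed site -> printed row (position axis trans->cis)
  if (is_anion) {
    val <- profile$table$anion[j]
    if (profile$anion_ref == "trans") val <- val - V
  } else {
    val <- profile$table$cation[j]
    if (profile$cation_ref == "trans") val <- val + V
  }
  val
}

oracle_chain_energy <- function(charges, x, direction, profile) {
  tot <- 0
  for (i in seq_along(charges)) {
    s <- if (direction == "cis_to_trans") (4 + x) - (i - 1) else (i - 1) - x
    tot <- tot + oracle_monomer_energy(charges[i], s, direction, profile)
  }
  tot
}

# flat landscape: every site energy zero, no trans offset
flat_profile <- function() {
  pore_profile(cation = rep(0, 7), anion = rep(0, 7), V = 0,
               cation_ref = "cis", anion_ref = "cis")
}

expect_within_3sigma <- function(phat, p, n) {
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(phat - p), 3 * se + 1e-12)
}

# shared expensive runs, computed once per test session
.run_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, .run_cache)) assign(name, force(expr), .run_cache)
  get(name, .run_cache)
}

global_n20_run <- function() {
  cached("global_n20", {
    seqs <- sample_sequences(20, 5000, seed = 71001)
    run_batch(seqs, sim_config(tw = 1.6e5, trials = 4, seed = 71002))
  })
}

# time-PDF object assembled from an exact absorption distribution, for
# fitting tails without Monte Carlo noise
pdf_from_exact <- function(p_t, dt, outcome = "translocated") {
  k <- round(seq_along(p_t) / dt)
  prob <- as.numeric(tapply(p_t, k, sum))
  centers <- as.numeric(names(tapply(p_t, k, sum))) * dt
  tot <- sum(prob)
  out <- tibble::tibble(bin_center = centers,
                        count = round(1e7 * prob),
                        prob = prob / tot)
  structure(out, class = c("patrans_time_pdf", class(out)),
            dt = dt, outcome = outcome, normalization = "events",
            n_events = 1e7, n_attempts = 1e7)
}

# summed exact translocation-time pdf over a sequence ensemble
ensemble_exact_pdf <- function(seqs, config) {
  acc <- NULL
  for (j in seq_len(nrow(seqs))) {
    l <- build_landscape(seqs$seq[[j]], config$direction, config$profile)
    d <- absorption_time_distribution(build_chain(l), config$tw)
    v <- d$pdf$p_translocate
    if (is.null(acc)) acc <- numeric(config$tw)
    acc[seq_along(v)] <- acc[seq_along(v)] + v
  }
  acc / nrow(seqs)
}
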