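toy_events <- function(times, outcome = "translocated", n_attempts = length(times)) {
  n_pad <- n_attempts - length(times)
  tibble::tibble(
    id = "x",
    trial = seq_len(n_attempts),
    outcome = factor(c(rep(outcome, length(times)), rep("rejected", n_pad)),
                     levels = c("translocated", "rejected", "trapped")),
    time = c(times, rep(1, n_pad))
  )
}

test_that("time PDFs bin to the caption convention and normalize", {
  ev <- toy_events(c(100, 2000, 3000))
  pdf <- time_pdf(ev, dt = 1600)
  expect_equal(pdf$bin_center, c(0, 1600, 3200))
  expect_equal(pdf$prob, rep(1 / 3, 3))
  expect_equal(sum(pdf$prob), 1)
  # attempt normalization divides by every engagement attempt
  ev2 <- toy_events(c(100, 2000, 3000), n_attempts = 12)
  pdf2 <- time_pdf(ev2, dt = 1600, normalization = "attempts")
  expect_equal(sum(pdf2$prob), 3 / 12)
  expect_warning(time_pdf(toy_events(numeric(0), n_attempts = 3)), "empty")
})

test_that("tail exponents recover a known power law from sampled times", {
  # inverse-CDF sample from density ~ t^-2 on [1e2, 1e6]
  set.seed(71)
  t1 <- 1e2; t2 <- 1e6
  u <- stats::runif(40000)
  tt <- 1 / (1 / t1 - u * (1 / t1 - 1 / t2))
  fit <- tail_exponent(time_pdf(toy_events(tt), dt = 1600),
                       window = c(2e3, 2e5))
  expect_lt(abs(fit$slope - (-2)), max(3 * fit$se, 0.1))
  g <- glance(fit)
  expect_gt(g$r.squared, 0.95)
  expect_identical(g$slope, fit$slope)
  td <- tidy(fit)
  expect_identical(nrow(td), 2L)
  expect_error(tail_exponent(time_pdf(toy_events(c(10, 20, 30)), dt = 10),
                             window = c(1, 100)), "bins")
})

test_that("trapped curves start at one and never increase", {
  ev <- dplyr::bind_rows(
    toy_events(c(10, 100, 1000)),
    tibble::tibble(id = "y", trial = 1:2,
                   outcome = factor("trapped",
                                    levels = c("translocated", "rejected", "trapped")),
                   time = 5000)
  )
  tc <- trapped_curve(ev, grid = c(1, 10, 100, 1000, 5000))
  expect_equal(tc$fraction[1], 1 - 0)
  expect_true(all(diff(tc$fraction) <= 0))
  expect_equal(tc$fraction[5], 2 / 5) # the two trapped attempts remain
})

test_that("outcome matrices are attempt-weighted and re-aggregate globally", {
  seqs <- sample_sequences(20, 40, seed = 81)
  b <- run_batch(seqs, sim_config(tw = 2e3, trials = 25, seed = 82))
  om <- outcome_matrix(b$events, by = "Qh")
  expect_true(all(abs(om$pct_translocated + om$pct_rejected +
                        om$pct_trapped - 100) < 1e-9))
  # attempt-weighted mean over cells equals the global percentage
  glob <- 100 * mean(b$events$outcome == "translocated")
  expect_equal(sum(om$pct_translocated * om$n_attempts) / sum(om$n_attempts),
               glob, tolerance = 1e-9)
  # single sequence: the cell is the per-sequence percentage
  one <- run_batch(reference_sequences()[1, ],
                   sim_config(tw = 1.6e5, trials = 100, seed = 83))
  om1 <- outcome_matrix(one$events, by = "Qmin")
  expect_identical(nrow(om1), 1L)
  expect_equal(om1$pct_translocated,
               one$summary$pct_translocated)
})

test_that("percentile times follow the worked cumulative-fraction example", {
  ev <- toy_events(c(350, 900, 5000), n_attempts = 100)
  pt <- percentile_times(ev, fractions = c(0.01, 0.02, 0.03, 0.10), dt = 400)
  expect_equal(pt$time, c(400, 1200, 5200, NA))
})

test_that("subensembles filter by descriptors and compose", {
  q16 <- subensemble(enumerate_sequences(20, Q = 16), Qmin > 0)
  expect_true(all(q16$Qmin > 0))
  e12 <- enumerate_sequences(12)
  # the even-Q classes partition the full enumeration
  expect_identical(sum(table(e12$Q)), 4096L)
  expect_identical(nrow(subensemble(e12, Q == 99)), 0L)
  expect_identical(
    nrow(subensemble(subensemble(e12, Q == 2), Qh == 1)),
    nrow(subensemble(e12, Q == 2, Qh == 1)))
})
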