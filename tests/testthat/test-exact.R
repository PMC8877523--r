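test_that("a flat chain gives the classical two-absorber results exactly", {
  l <- build_landscape(rep(1L, 20), profile = flat_profile())
  ch <- build_chain(l)
  expect_true(all(abs(ch$states$p_up - 0.5) < 1e-15))
  expect_true(all(abs(ch$states$stay) < 1e-15))
  expect_equal(splitting_probability(ch), 6 / 27, tolerance = 1e-12)
  m <- mean_first_passage(ch)
  expect_equal(m$mean, 126, tolerance = 1e-8)
  # splitting probability grows with the starting point
  ptr <- vapply(c(-5L, 0L, 20L), function(x) splitting_probability(ch, x), 0)
  expect_true(all(diff(ptr) > 0))
})

test_that("hop probabilities implement the Metropolis rule exactly", {
  l <- build_landscape(reference_sequences()$seq[[4]])
  ch <- build_chain(l)
  E <- l$E
  for (j in seq_len(nrow(ch$states))) {
    expect_equal(ch$states$p_up[j], 0.5 * min(1, exp(-(E[j + 2] - E[j + 1]))),
                 tolerance = 1e-14)
    expect_equal(ch$states$p_down[j], 0.5 * min(1, exp(-(E[j] - E[j + 1]))),
                 tolerance = 1e-14)
  }
  # detailed balance across each transient bond: p(x)/q(x+1) = e^{-dE}
  M <- nrow(ch$states)
  lhs <- ch$states$p_up[-M] / ch$states$p_down[-1]
  expect_equal(lhs, exp(-diff(E[2:(length(E) - 1)])), tolerance = 1e-12)
})

test_that("splitting probability matches a dense linear solve and is
           invariant under uniform rescaling of the hop rates", {
  set.seed(61)
  for (k in 1:5) {
    q <- sample(c(-1L, 1L), 10, replace = TRUE)
    ch <- build_chain(build_landscape(q))
    st <- ch$states
    M <- nrow(st)
    # dense (I - T) h = b oracle with the absorber column as source
    T <- diag(st$stay)
    T[cbind(1:(M - 1), 2:M)] <- st$p_up[-M]
    T[cbind(2:M, 1:(M - 1))] <- st$p_down[-1]
    b <- c(rep(0, M - 1), st$p_up[M])
    h <- solve(diag(M) - T, b)
    expect_lt(abs(splitting_probability(ch) - h[6]), 1e-10)
    # halving every hop probability (doubling the stay) changes nothing
    lazy <- ch
    lazy$states$p_up <- st$p_up / 2
    lazy$states$p_down <- st$p_down / 2
    lazy$states$stay <- 1 - lazy$states$p_up - lazy$states$p_down
    expect_equal(splitting_probability(lazy), splitting_probability(ch),
                 tolerance = 1e-12)
  }
})

test_that("the absorption-time distribution conserves mass to round-off", {
  q <- reference_sequences()$seq[[3]]
  ch <- build_chain(build_landscape(q))
  d <- absorption_time_distribution(ch, 5000)
  running <- cumsum(d$pdf$p_translocate + d$pdf$p_reject)
  expect_true(all(abs(running + (1 - running) - 1) < 1e-12))
  expect_lt(abs(sum(tail(running, 1)) + d$survival - 1), 1e-12)
  # nothing can be absorbed before six hops
  expect_true(all(d$pdf$p_translocate[1:5] == 0))
  expect_true(all(d$pdf$p_reject[1:5] == 0))
  # long-horizon mass recovers the splitting probability
  d2 <- absorption_time_distribution(ch, 2e5, tol = 1e-11)
  expect_lt(abs(sum(d2$pdf$p_translocate) - splitting_probability(ch)), 1e-9)
})

test_that("first-passage moments decompose across the two absorbers", {
  set.seed(62)
  for (k in 1:5) {
    q <- sample(c(-1L, 1L), 12, replace = TRUE)
    ch <- build_chain(build_landscape(q))
    m <- mean_first_passage(ch)
    expect_equal(m$mean,
                 m$P_tr * m$mean_translocate + (1 - m$P_tr) * m$mean_reject,
                 tolerance = 1e-8)
    # first moment of the time-domain distribution agrees whenever the
    # horizon actually exhausts the survival mass (deep traps need more)
    d <- absorption_time_distribution(ch, 5e5, tol = 1e-13)
    if (d$survival < 1e-12) {
      mu1 <- sum(d$pdf$t * (d$pdf$p_translocate + d$pdf$p_reject))
      expect_lt(abs(mu1 - m$mean) / m$mean, 1e-6)
    }
  }
})

test_that("exact classification is a proper three-way law with sane limits", {
  q <- reference_sequences()$seq[[6]]
  cx <- classify_exact(q, sim_config(tw = 2e4))
  expect_lt(abs(cx$P_tr + cx$P_rej + cx$P_trap - 1), 1e-10)
  # with long enough waiting the trapped class empties
  q5 <- reference_sequences()$seq[[5]]
  ch <- build_chain(build_landscape(q5))
  cx2 <- classify_exact(q5, sim_config(tw = 5e5))
  expect_lt(cx2$P_trap, 1e-6)
  expect_lt(abs(cx2$P_tr - splitting_probability(ch)), 1e-6)
  # a chain that cannot reach the far side in time has no defined moments
  cx3 <- classify_exact(rep(-1L, 20), sim_config(tw = 10))
  expect_identical(cx3$P_tr, 0)
  expect_true(is.na(cx3$mean_ttr))
})
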