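test_that("charge strings parse token by token and round-trip", {
  expect_identical(parse_charges("11-1", min_length = 1), c(1L, 1L, -1L))
  expect_identical(parse_charges(" 1 1 -1 11", min_length = 1),
                   c(1L, 1L, -1L, 1L, 1L))
  expect_error(parse_charges("11-"), "position")
  expect_error(parse_charges("11x1"), "unexpected character")
  expect_error(parse_charges("11-1"), "at least 5")
  set.seed(4)
  for (k in 1:20) {
    q <- sample(c(-1L, 1L), sample(5:40, 1), replace = TRUE)
    expect_identical(parse_charges(format_charges(q)), q)
  }
})

test_that("the reference panel reproduces the printed descriptors", {
  refs <- reference_sequences()
  expect_identical(refs$N, c(rep(20L, 7), 16L, 16L))
  expect_identical(refs$Q, c(rep(8L, 7), 4L, 4L))
  expect_identical(refs$Qh, c(3L, 1L, 1L, 1L, 1L, 1L, 3L, 3L, 1L))
  expect_identical(refs$Qmin, c(1L, 1L, 1L, -1L, 1L, -1L, -1L, -1L, -1L))
  # row (a) has exactly six antagonistic charges
  expect_identical(sum(refs$seq[[1]] == -1L), 6L)
})

test_that("descriptor edge cases and errors behave", {
  expect_identical(net_charge(rep(1L, 20)), 20L)
  expect_identical(head_charge(rep(-1L, 20)), -5L)
  expect_identical(min_window_charge(rep(1L, 9)), 5L)
  expect_error(head_charge(c(1L, -1L, 1L, -1L), window = 5), "exceeds")
  # Qmin is never above Qh: the head window is one of the scanned windows
  set.seed(11)
  for (k in 1:30) {
    q <- sample(c(-1L, 1L), 15, replace = TRUE)
    expect_lte(min_window_charge(q), head_charge(q))
  }
})

test_that("reversal is an involution and maps between engagement ends", {
  refs <- reference_sequences()
  expect_identical(reverse_charges(reverse_charges(refs$seq[[2]])),
                   refs$seq[[2]])
  # rows (b, c) and (h, i) are reversals of each other
  expect_identical(reverse_charges(refs$seq[[2]]), refs$seq[[3]])
  expect_identical(reverse_charges(refs$seq[[8]]), refs$seq[[9]])
  # head charge of the reverse is the net charge of the last five monomers
  set.seed(5)
  for (k in 1:20) {
    q <- sample(c(-1L, 1L), 12, replace = TRUE)
    expect_identical(head_charge(reverse_charges(q)),
                     as.integer(sum(rev(q)[1:5])))
  }
  rv <- reverse_sequences(refs)
  expect_identical(rv$id[1], "a_rev")
  expect_identical(rv$Qh[3], refs$Qh[2])
})

test_that("enumeration is complete, distinct and refuses huge N", {
  e5 <- enumerate_sequences(5)
  expect_identical(nrow(e5), 32L)
  expect_identical(dplyr::n_distinct(purrr::map_chr(e5$seq, format_charges)),
                   32L)
  e12 <- enumerate_sequences(12)
  expect_identical(nrow(e12), 4096L)
  # composition counts match the binomial coefficients
  expect_equal(sum(e12$Q == 0L), choose(12, 6))
  expect_equal(sum(e12$Q == 8L), choose(12, 2))
  expect_error(enumerate_sequences(20), "refused")
})

test_that("fixed-Q enumeration yields exactly the composition class", {
  q16 <- enumerate_sequences(20, Q = 16)
  expect_equal(nrow(q16), choose(20, 2))
  expect_true(all(q16$Q == 16L))
  expect_identical(dplyr::n_distinct(purrr::map_chr(q16$seq, format_charges)),
                   190L)
  # agrees with brute force at small N
  e10 <- enumerate_sequences(10)
  expect_identical(nrow(enumerate_sequences(10, Q = 4)), sum(e10$Q == 4L))
  expect_error(enumerate_sequences(10, Q = 3), "infeasible")
})

test_that("sampling is reproducible and respects constraints", {
  a <- sample_sequences(20, 50, seed = 9)
  b <- sample_sequences(20, 50, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, sample_sequences(20, 50, seed = 10)))
  cq <- sample_sequences(20, 200, seed = 1, Q = 10)
  expect_true(all(cq$Q == 10L))
  expect_true(all(purrr::map_int(cq$seq, ~ sum(.x == 1L)) == 15L))
  expect_error(sample_sequences(20, 5, seed = 1, Q = 7), "infeasible")
  # unconstrained sampling is charge-symmetric
  u <- sample_sequences(20, 1000, seed = 2)
  expect_lt(abs(mean(u$Q)), 3 * sqrt(20 / 1000))
})

test_that("protein reduction keeps charged residues in order", {
  expect_identical(reduce_protein("MKDAEKR"), c(1L, -1L, -1L, 1L, 1L))
  # favorable-unit flip: 6 basic / 10 acidic residues -> Q = +4
  aa <- paste0(c(rep("K", 3), rep("D", 5), rep("R", 3), rep("E", 5)),
               collapse = "")
  q <- reduce_protein(aa, favorable_sign = -1L)
  expect_identical(length(q), 16L)
  expect_identical(net_charge(q), 4L)
  # histidine and neutrals drop; unknown codes are named
  expect_identical(reduce_protein("KHDHEHKHR"), c(1L, -1L, -1L, 1L, 1L))
  expect_error(reduce_protein("KDBEKR"), "B")
  expect_error(reduce_protein("GGGGGG"), "at least 5")
})
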