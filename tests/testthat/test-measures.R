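test_that("worked examples of the five measures match closed forms", {
  expect_equal(aim_delta(0.7, 0.2), 0.5, tolerance = 1e-12)
  expect_equal(aim_delta(1, 0), 1)
  expect_equal(aim_delta(0.37, 0.37), 0)

  expect_equal(aim_fst(1, 0), 1)
  expect_equal(aim_fst(0.7, 0.2), 25 / 99, tolerance = 1e-12)
  expect_equal(aim_fst(0.9, 0.1), 0.64, tolerance = 1e-12)

  expect_equal(aim_fic(1, 0, m1 = 0.8), 6.25, tolerance = 1e-12)
  expect_equal(aim_fic(0.7, 0.2, m1 = 0.8), 25 / 24, tolerance = 1e-12)
  expect_equal(aim_fic(0.4, 0.4, m1 = 0.3), 0)

  expect_equal(aim_sic(1, 0, m1 = 0.5), log(2), tolerance = 1e-12)
  # entropy of the 80:20 mixture of (0.7, 0.3) and (0.2, 0.8)
  sic_exp <- 0.8 * (0.7 * log(0.7) + 0.3 * log(0.3)) +
    0.2 * (0.2 * log(0.2) + 0.8 * log(0.8)) -
    (0.6 * log(0.6) + 0.4 * log(0.4))
  expect_equal(aim_sic(0.7, 0.2, m1 = 0.8), sic_exp, tolerance = 1e-12)
  expect_equal(sic_exp, 0.084239740658, tolerance = 1e-9) # frozen oracle
  expect_equal(aim_sic(0.5, 0.5, m1 = 0.9), 0)

  expect_equal(aim_in(c(1, 0)), log(2), tolerance = 1e-12)
  in_exp <- oracle_in(rbind(c(0.7, 0.3), c(0.2, 0.8)))
  expect_equal(aim_in(rbind(c(0.7, 0.3), c(0.2, 0.8))), in_exp,
               tolerance = 1e-12)
  expect_equal(in_exp, 0.132505450917, tolerance = 1e-9) # frozen oracle
  expect_equal(aim_in(rbind(c(0.3, 0.7), c(0.3, 0.7))), 0)
})

test_that("domain errors are raised for invalid inputs", {
  expect_error(aim_delta(1.2, 0.5), "\\[0, 1\\]")
  expect_error(aim_fst(-0.1, 0.5), "\\[0, 1\\]")
  expect_error(aim_fic(0.5, 0.4, m1 = 0), "\\(0, 1\\)")
  expect_error(aim_fic(0.5, 0.4, m1 = 1), "\\(0, 1\\)")
  expect_error(aim_sic(0.5, 0.4, m1 = 1.5), "\\[0, 1\\]")
  expect_error(aim_in(rbind(c(0.5, 0.4), c(0.2, 0.8))), "sum to 1")
  expect_error(aim_in(matrix(c(0.5, 0.5), nrow = 1)), "K >= 2")
})

test_that("FIC blows up near joint fixation, rewarding fixed markers", {
  # as p1 -> 1, p2 -> 0 with a large m1, the expected admixed frequency
  # of the alternate allele approaches 0 and FIC grows without bound
  vals <- vapply(c(0.9, 0.99, 0.999, 0.9999), function(m1) {
    aim_fic(1, 0, m1 = m1)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_gt(vals[4], 1e3)
  # a zero-delta term contributes nothing even with p_A = 0
  expect_equal(aim_fic(0, 0, m1 = 0.5), 0)
})

test_that("scalar formulas agree with brute-force oracles on random pairs", {
  set.seed(401)
  for (rep in 1:200) {
    p1 <- runif(1); p2 <- runif(1); m1 <- runif(1, 0.05, 0.95)
    expect_equal(aim_delta(p1, p2), oracle_delta(p1, p2),
                 tolerance = 1e-9)
    expect_equal(aim_fst(p1, p2), oracle_fst(p1, p2), tolerance = 1e-9)
    expect_equal(aim_fic(p1, p2, m1), oracle_fic(p1, p2, m1),
                 tolerance = 1e-9)
    expect_equal(aim_sic(p1, p2, m1), oracle_sic(p1, p2, m1),
                 tolerance = 1e-9)
    expect_equal(aim_in(c(p1, p2)),
                 oracle_in(rbind(c(p1, 1 - p1), c(p2, 1 - p2))),
                 tolerance = 1e-9)
  }
})

test_that("all five measures vanish at equal frequencies", {
  set.seed(402)
  p <- runif(1000)
  m1 <- runif(1000, 0.01, 0.99)
  expect_true(all(abs(aim_delta(p, p)) <= 1e-12))
  expect_true(all(abs(aim_fst(p, p)) <= 1e-12))
  for (i in seq_len(50)) {
    expect_lt(abs(aim_fic(p[i], p[i], m1[i])), 1e-12)
    expect_lt(abs(aim_sic(p[i], p[i], m1[i])), 1e-12)
    expect_lt(abs(aim_in(c(p[i], p[i]))), 1e-12)
  }
})

test_that("measures are invariant to allele relabeling", {
  set.seed(403)
  p1 <- runif(500); p2 <- runif(500); m1 <- 0.8
  expect_equal(aim_delta(p1, p2), aim_delta(1 - p1, 1 - p2))
  expect_equal(aim_fst(p1, p2), aim_fst(1 - p1, 1 - p2),
               tolerance = 1e-12)
  expect_equal(aim_fic(p1, p2, m1), aim_fic(1 - p1, 1 - p2, m1),
               tolerance = 1e-9)
  expect_equal(aim_sic(p1, p2, m1), aim_sic(1 - p1, 1 - p2, m1),
               tolerance = 1e-12)
  for (i in 1:50) {
    expect_equal(aim_in(c(p1[i], p2[i])), aim_in(c(1 - p1[i], 1 - p2[i])),
                 tolerance = 1e-12)
  }
})

test_that("population swap: delta/fst/i_n invariant; fic/sic need m1 swap", {
  set.seed(404)
  p1 <- runif(500); p2 <- runif(500); m1 <- 0.8
  expect_equal(aim_delta(p1, p2), aim_delta(p2, p1))
  expect_equal(aim_fst(p1, p2), aim_fst(p2, p1), tolerance = 1e-12)
  for (i in 1:50) {
    expect_equal(aim_in(c(p1[i], p2[i])), aim_in(c(p2[i], p1[i])),
                 tolerance = 1e-12)
  }
  # invariance holds under a simultaneous swap m1 <-> 1 - m1 ...
  expect_equal(aim_fic(p1, p2, m1), aim_fic(p2, p1, 1 - m1),
               tolerance = 1e-9)
  expect_equal(aim_sic(p1, p2, m1), aim_sic(p2, p1, 1 - m1),
               tolerance = 1e-12)
  # ... and FIC is genuinely asymmetric without it (fixation preference)
  expect_false(isTRUE(all.equal(aim_fic(0.95, 0.2, 0.8),
                                aim_fic(0.2, 0.95, 0.8))))
})

test_that("bounds hold on random frequency pairs", {
  set.seed(405)
  p1 <- runif(10000); p2 <- runif(10000)
  d <- aim_delta(p1, p2); f <- aim_fst(p1, p2)
  s <- aim_sic(p1, p2, 0.8)
  expect_true(all(d >= 0 & d <= 1))
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(s >= -1e-12))
  i_n <- aimsel:::in_biallelic(cbind(p1, p2))
  expect_true(all(i_n >= -1e-12 & i_n <= log(2) + 1e-12))
})

test_that("score_markers scores, flags and ranks a table", {
  tab <- toy_table(c(1, 0.7, 0.5), c(0, 0.2, 0.5))
  sc <- score_markers(tab)
  expect_s3_class(sc, "measure_scores")
  expect_equal(sc$rank_delta, c(1L, 2L, 3L))
  expect_equal(sc$delta, c(1, 0.5, 0), tolerance = 1e-12)
  expect_equal(attr(sc, "config")$m1, 0.8)

  # empty table: empty scores, no error
  empty <- toy_table(numeric(0), numeric(0), pos = numeric(0))
  sc0 <- score_markers(empty)
  expect_equal(nrow(sc0), 0L)

  # equal frequencies everywhere: zero scores, deterministic tie-break
  flat <- toy_table(c(0.4, 0.4, 0.4), c(0.4, 0.4, 0.4))
  scf <- score_markers(flat)
  expect_true(all(abs(scf$delta) < 1e-12 & abs(scf$i_n) < 1e-12))
  expect_equal(scf$rank_fst, c(1L, 2L, 3L)) # (chrom, pos, id) order

  # markers monomorphic for the same allele score 0 everywhere
  mono <- toy_table(c(0, 1, 0.9), c(0, 1, 0.1))
  scm <- score_markers(mono)
  expect_true(all(scm$monomorphic[1:2]))
  expect_true(all(as.matrix(scm[1:2, c("delta", "fst", "fic", "sic",
                                       "i_n")]) == 0))

  # more than two populations is an unsupported-measure error
  tab3 <- frequency_table(c("a", "b"), "chr1", c(1, 2),
                          cbind(p1 = c(0.1, 0.2), p2 = c(0.3, 0.4),
                                p3 = c(0.5, 0.6)))
  expect_error(score_markers(tab3), "delta.*fic.*2 populations")
})

test_that("log base rescales entropy measures without changing ranks", {
  tab <- toy_table(c(0.95, 0.7, 0.55, 0.9), c(0.1, 0.3, 0.45, 0.5))
  nat <- score_markers(tab, log_base = exp(1))
  bit <- score_markers(tab, log_base = 2)
  expect_equal(bit$sic, nat$sic / log(2), tolerance = 1e-12)
  expect_equal(bit$i_n, nat$i_n / log(2), tolerance = 1e-12)
  expect_equal(bit$rank_sic, nat$rank_sic)
  expect_equal(bit$rank_i_n, nat$rank_i_n)
})

test_that("near-fixation markers dominate the FIC ranking", {
  # rs001 is fixed for opposite alleles; its FIC exceeds any polymorphic
  # marker and it must take rank 1 no matter how extreme the score gets
  tab <- toy_table(c(1, 0.9), c(0, 0.1), pos = c(1e5, 3e5))
  sc <- score_markers(tab, m1 = 1 - 1e-12)
  expect_gt(sc$fic[1], sc$fic[2])
  expect_equal(sc$rank_fic[1], 1L)
})
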