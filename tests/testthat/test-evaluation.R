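make_two_pop_data <- function(L = 30, n1 = 20, n2 = 20, F = 0.3,
                              seed = 701) {
  cfg <- sim_config(L = L, chrom_lengths = rep(1e8, 3), F = F,
                    n_admixed = 10, n_founders = 20, G = 0, seed = seed)
  ft <- generate_ancestral_freqs(cfg)
  list(ft = ft,
       g1 = generate_panel_genotypes(ft, 1, n1, seed = seed + 1),
       g2 = generate_panel_genotypes(ft, 2, n2, seed = seed + 2))
}

test_that("LDA separates fully differentiated populations perfectly", {
  tab <- toy_table(1, 0, pos = 1e5)
  g1 <- matrix(2L, 20, 1, dimnames = list(NULL, "rs001"))
  g2 <- matrix(0L, 20, 1, dimnames = list(NULL, "rs001"))
  sc <- score_markers(tab)
  curve <- lda_accuracy_curve(g1, g2, sc, "delta", n_grid = 1)
  expect_equal(curve$accuracy, 1)
})

test_that("LDA accuracy is near chance for identical populations", {
  set.seed(702)
  tab <- toy_table(rep(0.5, 10), rep(0.5, 10))
  g1 <- generate_panel_genotypes(tab, 1, 20, seed = 1)
  g2 <- generate_panel_genotypes(tab, 2, 20, seed = 2)
  sc <- score_markers(tab)
  curve <- lda_accuracy_curve(g1, g2, sc, "fst", n_grid = 10)
  expect_lt(abs(curve$accuracy - 0.5), 0.25)
})

test_that("LOOCV accuracy equals an exhaustive per-fold oracle", {
  d <- make_two_pop_data(L = 8, n1 = 10, n2 = 12)
  sc <- score_markers(d$ft)
  curve <- lda_accuracy_curve(d$g1, d$g2, sc, "i_n", n_grid = c(3, 8))

  ranked <- sc$marker_id[order(sc$rank_i_n)]
  X <- rbind(d$g1[, ranked], d$g2[, ranked])
  y <- rep(c("pop1", "pop2"), c(10, 12))
  for (row in seq_len(nrow(curve))) {
    p <- curve$n[row]
    Xp <- X[, seq_len(p), drop = FALSE]
    correct <- vapply(seq_len(nrow(Xp)), function(i) {
      fit <- aimsel:::lda_train(Xp[-i, , drop = FALSE], y[-i])
      identical(aimsel:::lda_predict(fit, Xp[i, , drop = FALSE]), y[i])
    }, logical(1))
    expect_equal(curve$accuracy[row], mean(correct))
  }
})

test_that("LDA posterior rule agrees with MASS::lda on a clean problem", {
  skip_if_not_installed("MASS")
  d <- make_two_pop_data(L = 5, n1 = 25, n2 = 35, F = 0.25, seed = 703)
  ranked <- d$ft$marker_id
  X <- rbind(d$g1[, ranked], d$g2[, ranked])
  y <- rep(c("pop1", "pop2"), c(25, 35))
  keep <- apply(X, 2, function(col) length(unique(col)) > 1)
  X <- X[, keep, drop = FALSE]
  fit <- aimsel:::lda_train(X, y)
  mine <- aimsel:::lda_predict(fit, X)
  ref <- as.character(stats::predict(MASS::lda(X, grouping = y))$class)
  expect_gt(mean(mine == ref), 0.98)
})

test_that("markers_needed finds the first threshold crossing", {
  curve <- data.frame(n = 1:3, accuracy = c(0.80, 0.92, 0.96))
  expect_equal(markers_needed(curve, 0.90), 2L)
  expect_equal(markers_needed(curve, 0.95), 3L)
  expect_true(is.na(markers_needed(data.frame(n = 1:3,
                                              accuracy = rep(0.5, 3)),
                                   0.95)))
  # non-monotone curve: the definition applies literally
  wiggly <- data.frame(n = 1:3, accuracy = c(0.91, 0.89, 0.95))
  expect_equal(markers_needed(wiggly, 0.90), 1L)
})

test_that("rmse and bias follow their definitions", {
  rb <- rmse_bias(c(0.6, 0.4), data.frame(sample_id = c("1", "2"),
                                          q_true = c(0.5, 0.5)))
  expect_equal(rb$rmse, 0.1, tolerance = 1e-12)
  expect_equal(rb$bias, 0, tolerance = 1e-12)

  q <- runif(20)
  rb2 <- rmse_bias(q, q)
  expect_equal(rb2$rmse, 0)
  expect_equal(rb2$bias, 0)

  rb3 <- rmse_bias(rep(0.71, 100), rep(0.70, 100))
  expect_equal(rb3$rmse, 0.01, tolerance = 1e-12)
  expect_equal(rb3$bias, 0.01, tolerance = 1e-12)

  # invariant to sample ordering when matched by id
  est <- structure(
    data.frame(sample_id = c("b", "a"), q_hat = c(0.2, 0.9),
               loglik = 0, n_used = 1),
    class = c("ancestry_estimate", "data.frame"))
  truth <- data.frame(sample_id = c("a", "b"), q_true = c(0.9, 0.2))
  expect_equal(rmse_bias(est, truth)$rmse, 0)
  expect_error(rmse_bias(est, data.frame(sample_id = "c", q_true = 1)),
               "missing from the truth")
})

test_that("random subset experiment is reproducible and well-behaved", {
  cfg <- sim_config(L = 1500, chrom_lengths = rep(1e8, 5), F = 0.2,
                    n_admixed = 30, n_founders = 60, G = 3, seed = 704)
  ft <- generate_ancestral_freqs(cfg)
  sim <- simulate_admixed(ft, cfg)
  sc <- score_markers(ft)
  run <- function() {
    random_subset_experiment(
      sc, ft, sim$genotypes, sim$truth,
      measures = c("delta", "i_n"), fractions = c(0.05, 0.10),
      subset_size = 10L, n_rep = 5L, min_bp = 0, seed = 99)
  }
  r1 <- run(); r2 <- run()
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  expect_equal(attr(r1, "errors"), attr(r2, "errors"))
  expect_equal(nrow(r1), 4L)
  expect_true(all(is.finite(r1$mean_error)))

  expect_error(
    random_subset_experiment(sc, ft, sim$genotypes, sim$truth,
                             measures = "i_n", fractions = 0.01,
                             subset_size = 1000L, n_rep = 2L,
                             min_bp = 0, seed = 1),
    "exceeds the top")
})

test_that("perfect AIM subsets estimate the mean almost exactly", {
  # 60 perfectly informative markers: each subset of 20 pins q_i to the
  # individual's exact ancestry dosage
  L <- 60
  tab <- toy_table(rep(1, L), rep(0, L),
                   pos = seq(2e5, by = 2e5, length.out = L))
  set.seed(705)
  n <- 40
  q_true <- rbeta(n, 7, 3)
  G <- t(vapply(q_true, function(q) rbinom(L, 2L, q), integer(L)))
  dimnames(G) <- list(sprintf("i%02d", 1:n), tab$marker_id)
  sc <- score_markers(tab)
  res <- random_subset_experiment(
    sc, tab, G, reference = mean(q_true), measures = "delta",
    fractions = 1, subset_size = 20L, n_rep = 20L, min_bp = 0,
    seed = 706)
  expect_lt(res$mean_abs_error, 0.02)
})

test_that("sensitivity overlap behaves at its fixed points", {
  set.seed(707)
  tab <- toy_table(runif(200), runif(200), pos = sample.int(1e8, 200))
  # identical contributions: everything overlaps
  so <- sensitivity_overlap(tab, "fic", m = 0.8, m_prime = 0.8,
                            fraction = 0.05)
  expect_equal(so$pct_11, 100)
  expect_equal(so$n10 + so$n01, 0)
  # delta ignores the assumed contribution entirely (control)
  sod <- sensitivity_overlap(tab, "delta", m = 0.9, m_prime = 0.2,
                             fraction = 0.05)
  expect_equal(sod$pct_11, 100)
})
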