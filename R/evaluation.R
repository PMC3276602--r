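# Panel evaluation: discriminant classification accuracy, bias/RMSE against
# simulated truth, random-subset experiments and sensitivity of FIC/SIC to
# the assumed ancestral contribution.

# Fit a two-class linear discriminant with pooled covariance, a small ridge
# term and priors proportional to class sizes. Returns the linear scoring
# functions delta_k(x) = x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + log prior_k.
lda_train <- function(X, y, ridge = 1e-6) {
  cls <- sort(unique(y))
  if (length(cls) != 2L) stop("exactly two classes required", call. = FALSE)
  n_k <- table(factor(y, levels = cls))
  if (any(n_k < 2L)) stop("each class needs at least 2 samples",
                          call. = FALSE)
  p <- ncol(X)
  mu <- lapply(cls, function(k) colMeans(X[y == k, , drop = FALSE]))
  S <- matrix(0, p, p)
  for (k in seq_along(cls)) {
    Xi <- X[y == cls[k], , drop = FALSE]
    S <- S + crossprod(sweep(Xi, 2L, mu[[k]]))
  }
  S <- S / (nrow(X) - 2L)
  lambda <- ridge * sum(diag(S)) / p
  if (lambda <= 0) lambda <- ridge # fully separated, zero-variance panels
  S <- S + diag(lambda, p)
  Sinv <- solve(S)
  priors <- as.numeric(n_k) / length(y)
  W <- vapply(mu, function(m) drop(Sinv %*% m), numeric(p))
  if (!is.matrix(W)) W <- matrix(W, nrow = p) # p = 1 panel
  b <- vapply(seq_along(cls), function(k) {
    -0.5 * sum(mu[[k]] * (Sinv %*% mu[[k]])) + log(priors[k])
  }, numeric(1))
  list(classes = cls, W = W, b = b)
}

lda_predict <- function(fit, X) {
  scores <- X %*% fit$W + rep(fit$b, each = nrow(X))
  fit$classes[max.col(scores, ties.method = "first")]
}

# Leave-one-out cross-validated accuracy: the model is refit on every fold.
lda_loocv <- function(X, y, ridge = 1e-6) {
  n <- nrow(X)
  correct <- logical(n)
  for (i in seq_len(n)) {
    fit <- lda_train(X[-i, , drop = FALSE], y[-i], ridge = ridge)
    correct[i] <- identical(lda_predict(fit, X[i, , drop = FALSE]), y[i])
  }
  mean(correct)
}

#' Classification accuracy versus number of top AIMs
#'
#' For each panel size `n` in `n_grid`, fits a two-class linear
#' discriminant (pooled covariance with a small ridge term, priors
#' proportional to class sizes) on the `n` best-ranked markers of the
#' chosen measure and reports leave-one-out cross-validated accuracy of
#' assigning individuals to their ancestral population.
#'
#' The ridge term `lambda = ridge * trace(S)/p` keeps the pooled covariance
#' invertible when the panel size approaches the sample size; with an
#' all-zero covariance (perfectly fixed markers) an absolute floor of
#' `ridge` is used so classification degenerates gracefully to nearest
#' class mean.
#'
#' @param G1,G2 genotype matrices (individuals x markers) for the two
#'   ancestral population samples; column names are marker ids.
#' @param scores a [score_markers()] result.
#' @param measure ranking to use (`"delta"`, `"fst"`, `"fic"`, `"sic"`,
#'   `"i_n"`, `"ave"`, `"min"`).
#' @param n_grid integer vector of panel sizes.
#' @param ridge relative ridge coefficient (default 1e-6).
#' @return `data.frame` with columns `n` and `accuracy`.
#' @seealso [markers_needed()]
#' @export
lda_accuracy_curve <- function(G1, G2, scores, measure = "i_n",
                               n_grid = c(1L, 2L, 5L, 10L, 20L),
                               ridge = 1e-6) {
  stopifnot(inherits(scores, "measure_scores"))
  rank_col <- paste0("rank_", measure)
  if (is.null(scores[[rank_col]])) {
    stop("no ranking `", rank_col, "` in scores", call. = FALSE)
  }
  if (nrow(G1) < 2L || nrow(G2) < 2L) {
    stop("each class needs at least 2 samples", call. = FALSE)
  }
  ranked_ids <- scores$marker_id[order(scores[[rank_col]])]
  ranked_ids <- ranked_ids[ranked_ids %in% colnames(G1) &
                             ranked_ids %in% colnames(G2)]
  if (max(n_grid) > length(ranked_ids)) {
    stop("n_grid exceeds the number of scored markers present in both ",
         "genotype matrices", call. = FALSE)
  }
  X_all <- rbind(as.matrix(G1[, ranked_ids, drop = FALSE]),
                 as.matrix(G2[, ranked_ids, drop = FALSE]))
  y <- rep(c("pop1", "pop2"), c(nrow(G1), nrow(G2)))
  acc <- vapply(n_grid, function(n) {
    lda_loocv(X_all[, seq_len(n), drop = FALSE], y, ridge = ridge)
  }, numeric(1))
  data.frame(n = as.integer(n_grid), accuracy = acc)
}

#' Smallest panel size reaching a target classification accuracy
#'
#' @param curve a `data.frame` with columns `n` and `accuracy`, e.g. from
#'   [lda_accuracy_curve()].
#' @param threshold target accuracy, typically 0.90 or 0.95.
#' @return The smallest `n` (first crossing in increasing `n`) whose
#'   accuracy is >= `threshold`, or `NA_integer_` if never reached.
#' @export
markers_needed <- function(curve, threshold = 0.90) {
  stopifnot(is.data.frame(curve), nrow(curve) > 0L,
            all(c("n", "accuracy") %in% names(curve)))
  curve <- curve[order(curve$n), , drop = FALSE]
  hit <- which(curve$accuracy >= threshold)
  if (!length(hit)) NA_integer_ else as.integer(curve$n[hit[1L]])
}

#' Bias and RMSE of admixture estimates against the truth
#'
#' `rmse = sqrt(mean((q_i - q_hat_i)^2))` over individuals and
#' `bias = |mean(q_hat) - mean(q)|` at the population level.
#'
#' @param estimate an [estimate_ancestry()] result, or a numeric vector of
#'   estimated proportions.
#' @param truth a `data.frame` with columns `sample_id` and `q_true` (as
#'   produced by [simulate_admixed()]), or a numeric vector aligned with
#'   `estimate`.
#' @return List with `rmse`, `bias` and `n` (individuals compared).
#' @export
rmse_bias <- function(estimate, truth) {
  if (inherits(estimate, "ancestry_estimate")) {
    ids <- estimate$sample_id
    q_hat <- estimate$q_hat
  } else {
    ids <- NULL
    q_hat <- as.numeric(estimate)
  }
  if (is.data.frame(truth)) {
    stopifnot(all(c("sample_id", "q_true") %in% names(truth)))
    if (!is.null(ids)) {
      idx <- match(ids, truth$sample_id)
      if (anyNA(idx)) {
        stop("sample ids in the estimate are missing from the truth",
             call. = FALSE)
      }
      q_true <- truth$q_true[idx]
    } else {
      q_true <- truth$q_true
    }
  } else {
    q_true <- as.numeric(truth)
  }
  if (length(q_hat) != length(q_true)) {
    stop("estimate and truth cover different numbers of individuals",
         call. = FALSE)
  }
  ok <- !is.na(q_hat)
  list(rmse = sqrt(mean((q_true[ok] - q_hat[ok])^2)),
       bias = abs(mean(q_hat[ok]) - mean(q_true[ok])),
       n = sum(ok))
}

#' Random-subset ancestry-estimation experiment
#'
#' For each measure and each top fraction, draws `n_rep` random subsets of
#' `subset_size` markers (uniformly, without replacement) from the
#' measure's distance-filtered top-fraction AIM panel, estimates the mean
#' admixture proportion of the sample from each subset, and summarizes the
#' signed errors against a reference value. Widening the source panel from
#' the top 1% to the top 10% admits progressively less informative markers,
#' so both the mean and the spread of the errors are expected to grow.
#'
#' @param scores a [score_markers()] result (combined rankings are added
#'   internally when `"ave"`/`"min"` are requested).
#' @param table the matching two-population [frequency_table()].
#' @param G genotype matrix of the admixed sample (individuals x markers).
#' @param reference reference mean ancestry proportion: a single number, or
#'   a truth `data.frame` (`sample_id`, `q_true`) whose mean is used.
#' @param measures rankings to evaluate (default: all five plus AVE/MIN).
#' @param fractions top fractions of the panel to draw from
#'   (default 1, 2, 5, 10%).
#' @param subset_size markers per random subset (default 20).
#' @param n_rep subsets per (measure, fraction) cell (default 100).
#' @param min_bp spacing for the underlying AIM panels (default 100 kb).
#' @param seed RNG seed; the whole experiment is reproducible from it.
#' @param eps frequency clamp for the likelihood.
#' @return `data.frame` of class `"subset_experiment"` with one row per
#'   (measure, fraction): `measure`, `fraction`, `panel_size`,
#'   `mean_error`, `sd_error`, `mean_abs_error`; the full `n_rep` error
#'   draws are kept in the `errors` attribute (a named list of matrices).
#' @export
random_subset_experiment <- function(scores, table, G, reference,
                                     measures = c("delta", "fst", "fic",
                                                  "sic", "i_n", "ave",
                                                  "min"),
                                     fractions = c(0.01, 0.02, 0.05, 0.10),
                                     subset_size = 20L, n_rep = 100L,
                                     min_bp = 100000, seed = NULL,
                                     eps = 1e-6) {
  stopifnot(inherits(scores, "measure_scores"))
  if (is.data.frame(reference)) reference <- mean(reference$q_true)
  stopifnot(is.numeric(reference), length(reference) == 1L)
  if (any(c("ave", "min") %in% measures)) {
    scores <- combined_rank(scores)
  }
  with_seed(seed, {
    rows <- list()
    all_errors <- list()
    for (msr in measures) {
      panel <- distance_filter(scores, msr, min_bp = min_bp)
      for (fr in fractions) {
        top <- select_markers(panel, top_fraction = fr)
        if (subset_size > nrow(top)) {
          stop(sprintf(
            "subset_size %d exceeds the top-%g%% panel size %d for %s",
            subset_size, 100 * fr, nrow(top), msr), call. = FALSE)
        }
        errs <- vapply(seq_len(n_rep), function(r) {
          ids <- sample(top$marker_id, subset_size)
          est <- estimate_ancestry(G, table, markers = ids, eps = eps)
          attr(est, "mean_q_hat") - reference
        }, numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          measure = msr, fraction = fr, panel_size = nrow(top),
          mean_error = mean(errs), sd_error = stats::sd(errs),
          mean_abs_error = mean(abs(errs)), stringsAsFactors = FALSE)
        all_errors[[paste(msr, fr, sep = "_")]] <- errs
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    structure(out, errors = all_errors, reference = reference,
              n_rep = n_rep, subset_size = subset_size,
              class = c("subset_experiment", "data.frame"))
  })
}

#' Sensitivity of FIC/SIC marker selection to the assumed contribution
#'
#' FIC and SIC depend on the assumed ancestral contribution `m1`. This
#' scores the table under two values `m` and `m_prime`, takes the
#' top-fraction set under each, and counts markers selected by both panels
#' (pattern `11`), only the first (`10`) or only the second (`01`). Both
#' top sets have the same size, so `n10 == n01` and the overlap percentage
#' is reported relative to that common size.
#'
#' @param table a two-population [frequency_table()].
#' @param measure `"fic"` or `"sic"` (delta/Fst/I_n ignore `m1` and serve
#'   as controls: their panels are identical for any pair of contributions).
#' @param m,m_prime the two assumed contributions of population 1.
#' @param fraction top fraction to compare (default 0.01).
#' @param min_bp spacing filter applied before taking the top fraction
#'   (default 0 = compare pure rankings).
#' @param log_base logarithm base for SIC.
#' @return List with counts `n11`, `n10`, `n01`, the common panel size
#'   `size` and `pct_11` (overlap percentage).
#' @export
sensitivity_overlap <- function(table, measure = c("fic", "sic", "delta",
                                                   "fst", "i_n"),
                                m, m_prime, fraction = 0.01, min_bp = 0,
                                log_base = exp(1)) {
  measure <- match.arg(measure)
  stopifnot(m > 0, m < 1, m_prime > 0, m_prime < 1)
  top_ids <- function(m1) {
    sc <- score_markers(table, m1 = m1, log_base = log_base)
    panel <- distance_filter(sc, measure, min_bp = min_bp)
    select_markers(panel, top_fraction = fraction)$marker_id
  }
  a <- top_ids(m)
  b <- top_ids(m_prime)
  n11 <- length(intersect(a, b))
  list(n11 = n11, n10 = length(setdiff(a, b)), n01 = length(setdiff(b, a)),
       size = length(a), pct_11 = 100 * n11 / length(a))
}
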