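#' Expected allele frequency in an admixed population
#'
#' Linear mixture of the ancestral reference-allele frequencies:
#' `m1 * p1 + (1 - m1) * p2`.
#'
#' @param p1,p2 reference-allele frequencies in the ancestral populations.
#' @param m1 contribution of population 1, in `[0, 1]`.
#' @return Numeric vector of admixed frequencies.
#' @export
#' @examples
#' admixed_freq(0.7, 0.2, 0.8) # 0.6
admixed_freq <- function(p1, p2, m1) {
  check_prob(p1); check_prob(p2); check_prob(m1, "m1")
  m1 * p1 + (1 - m1) * p2
}

#' Log-likelihood of a genotype vector under a global-admixture model
#'
#' For an individual with admixture proportion `q` from population 1, the
#' reference-allele frequency at marker l is `f_l = q p_1l + (1-q) p_2l`,
#' and genotypes are Binomial(2, f_l) under Hardy-Weinberg equilibrium with
#' inter-marker independence (panels are assumed distance-filtered, so
#' background LD is negligible). Frequencies are clamped to
#' `[eps, 1 - eps]` so fixed alleles cannot produce `-Inf`; missing
#' genotypes contribute nothing (complete-case per marker).
#'
#' @param g genotype vector (0/1/2 copies of the reference allele, `NA` =
#'   missing), aligned with the rows of `table`.
#' @param table a two-population [frequency_table()] restricted to the
#'   panel markers, or a two-column matrix of (p1, p2).
#' @param q admixture proportion from population 1, in `[0, 1]`.
#' @param eps frequency clamp (default 1e-6).
#' @return Scalar log-likelihood (natural log), including the binomial
#'   coefficient terms.
#' @export
loglik_admixture <- function(g, table, q, eps = 1e-6) {
  P <- if (inherits(table, "freq_table")) pop_freqs(table) else as.matrix(table)
  if (ncol(P) != 2L) stop("need exactly two ancestral populations",
                          call. = FALSE)
  if (length(g) != nrow(P)) {
    stop("genotype vector and frequency table cover different markers",
         call. = FALSE)
  }
  check_prob(q, "q")
  use <- !is.na(g)
  g <- g[use]
  f <- q * P[use, 1L] + (1 - q) * P[use, 2L]
  f <- pmin(pmax(f, eps), 1 - eps)
  sum(g * log(f) + (2 - g) * log1p(-f) + log(choose(2, g)))
}

#' Maximum-likelihood estimation of individual admixture proportions
#'
#' Per individual, maximizes [loglik_admixture()] over `q` in `[0, 1]` by
#' bounded one-dimensional optimization (the log-likelihood is concave in
#' `q`, so Brent's method finds the global maximum; the two boundary values
#' are checked explicitly). This is the K = 2 analogue of the EM estimator
#' used by global-ancestry software such as PSMIX: the maximizer is
#' identical, only the search differs.
#'
#' Population orientation is canonicalized internally (the population with
#' the larger total reference-allele frequency is treated as population 1,
#' flipping the result back afterwards), which makes label-swap symmetry
#' `q -> 1 - q` exact to the bit.
#'
#' @param G genotype matrix, individuals in rows, markers in columns
#'   (column names = marker ids), entries 0/1/2/`NA`.
#' @param table a two-population [frequency_table()] covering the panel
#'   markers.
#' @param markers optional panel: an `"aim_panel"`, or a character vector of
#'   marker ids; default uses every marker shared by `G` and `table`.
#' @param eps frequency clamp passed to [loglik_admixture()].
#' @param tol convergence tolerance of the one-dimensional search.
#'
#' @return A `data.frame` of class `"ancestry_estimate"` with columns
#'   `sample_id`, `q_hat` (estimated proportion from population 1),
#'   `loglik`, `n_used` (non-missing genotypes); attributes `mean_q_hat`,
#'   `sd_q_hat` (over individuals with at least one genotype) and
#'   `identifiable` (FALSE when the panel is monomorphic across populations,
#'   in which case all `q_hat` are `NA`). Individuals with no usable
#'   genotype get `q_hat = NA` and are excluded from the mean.
#' @export
estimate_ancestry <- function(G, table, markers = NULL, eps = 1e-6,
                              tol = 1e-8) {
  stopifnot(inherits(table, "freq_table"))
  if (inherits(markers, "aim_panel")) markers <- markers$marker_id
  if (is.null(markers)) {
    markers <- intersect(colnames(G), table$marker_id)
  }
  if (!length(markers)) stop("no shared markers", call. = FALSE)
  if (!all(markers %in% colnames(G)) ||
      !all(markers %in% table$marker_id)) {
    stop("panel markers missing from the genotype matrix or the frequency ",
         "table", call. = FALSE)
  }
  Gm <- as.matrix(G[, markers, drop = FALSE])
  P <- pop_freqs(table)[match(markers, table$marker_id), , drop = FALSE]
  p1 <- P[, 1L]; p2 <- P[, 2L]

  if (all(p1 == p2)) {
    warning("panel is monomorphic across populations: admixture ",
            "proportion is not identifiable", call. = FALSE)
    out <- data.frame(sample_id = rownames(Gm) %||% seq_len(nrow(Gm)),
                      q_hat = NA_real_, loglik = NA_real_,
                      n_used = rowSums(!is.na(Gm)),
                      stringsAsFactors = FALSE)
    return(structure(out, mean_q_hat = NA_real_, sd_q_hat = NA_real_,
                     identifiable = FALSE,
                     class = c("ancestry_estimate", "data.frame")))
  }

  # canonical orientation: internally call "population 1" the one with the
  # larger total reference-allele frequency (lexicographic tie-break), so a
  # label swap returns exactly 1 - q_hat
  flip <- {
    s1 <- sum(p1); s2 <- sum(p2)
    if (s1 != s2) s1 < s2 else {
      d <- p1 - p2
      i <- which(d != 0)[1L]
      d[i] < 0
    }
  }
  if (flip) { tmp <- p1; p1 <- p2; p2 <- tmp }
  PP <- cbind(p1, p2)

  n <- nrow(Gm)
  q_hat <- loglik <- rep(NA_real_, n)
  n_used <- rowSums(!is.na(Gm))
  for (i in seq_len(n)) {
    if (n_used[i] == 0L) next
    ll <- function(q) loglik_admixture(Gm[i, ], PP, q, eps = eps)
    opt <- stats::optimize(ll, interval = c(0, 1), maximum = TRUE,
                           tol = tol)
    # boundaries first: the clamp creates a flat plateau next to 0/1 and
    # ties there should resolve to the boundary itself
    cand_q <- c(0, 1, opt$maximum)
    cand_ll <- c(ll(0), ll(1), opt$objective)
    best <- which.max(cand_ll)
    # snap to a dyadic grid (2^-40 ~ 9e-13, far below the search
    # tolerance) so that 1 - q_hat is exactly representable and the
    # label-swap symmetry holds to the bit
    q_hat[i] <- round(cand_q[best] * 2^40) / 2^40
    loglik[i] <- cand_ll[best]
  }
  if (flip) q_hat <- 1 - q_hat

  out <- data.frame(sample_id = rownames(Gm) %||% as.character(seq_len(n)),
                    q_hat = q_hat, loglik = loglik, n_used = n_used,
                    stringsAsFactors = FALSE)
  structure(out,
            mean_q_hat = mean(q_hat, na.rm = TRUE),
            sd_q_hat = stats::sd(q_hat[!is.na(q_hat)]),
            identifiable = TRUE,
            class = c("ancestry_estimate", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ancestry_estimate <- function(x, ...) {
  cat(sprintf(
    "Admixture estimates for %d individuals: mean q_hat = %.4f (sd %.4f)\n",
    nrow(x), attr(x, "mean_q_hat"), attr(x, "sd_q_hat")))
  if (!isTRUE(attr(x, "identifiable"))) {
    cat("  [non-identifiable: monomorphic panel]\n")
  }
  NextMethod()
}
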