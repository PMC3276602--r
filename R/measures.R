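#' Five per-marker measures of ancestry informativeness
#'
#' Scalar (vectorized) forms of the five statistics used to rank biallelic
#' SNPs by how much information they carry about ancestry in an admixed
#' population with two ancestral sources:
#'
#' * `aim_delta()` — absolute allele-frequency difference
#'   \eqn{\delta = |p_1 - p_2|}.
#' * `aim_fst()` — two-population biallelic Fst,
#'   \eqn{(p_1-p_2)^2 / [(p_1+p_2)(2-p_1-p_2)]}.
#' * `aim_fic()` — Fisher information content
#'   \eqn{\sum_j \delta_j^2 / \hat p_{Aj}} with
#'   \eqn{\hat p_{Aj} = p_{2j} + m_1 \delta_j}; favors markers near fixation
#'   in the majority-contribution population and requires an assumed
#'   contribution \eqn{m_1 \in (0,1)}.
#' * `aim_sic()` — Shannon information content, the entropy of the admixed
#'   allele distribution minus the \eqn{m}-weighted average of the ancestral
#'   entropies (a Jensen-Shannon-type divergence, always >= 0).
#' * `aim_in()` — informativeness for assignment
#'   \eqn{I_n = \sum_j [-\bar p_j \log \bar p_j +
#'   \sum_i p_{ij} \log p_{ij} / K]}, defined for K >= 2 populations.
#'
#' `p1` and `p2` are reference-allele frequencies in the two ancestral
#' populations; all five statistics are invariant to which allele is called
#' the reference. Entropy-based measures use the natural logarithm by
#' default (`log_base = exp(1)`); switching the base rescales values but
#' never changes ranks. The convention \eqn{0 \log 0 = 0} is used
#' throughout.
#'
#' @param p1,p2 reference-allele frequencies in ancestral populations 1 and
#'   2 (vectors recycled to common length, values in `[0, 1]`).
#' @param m1 assumed contribution of ancestral population 1 to the admixed
#'   population. Strictly inside (0, 1) for `aim_fic()`; in `[0, 1]` for
#'   `aim_sic()`. Default 0.8 (majority contribution fixed at 80%).
#' @param log_base base of the logarithm for the entropy-based measures.
#' @param freqs for `aim_in()`: a K x N matrix of allele frequencies (rows =
#'   populations, each row summing to 1), or a length-K vector of
#'   reference-allele frequencies at a biallelic locus.
#'
#' @return Numeric vector of scores. `aim_delta`/`aim_fst` lie in `[0, 1]`;
#'   `aim_sic` and `aim_fic` are >= 0 (`aim_fic` returns `Inf` when an
#'   expected admixed frequency is 0 with a nonzero frequency difference);
#'   `aim_in` lies in `[0, log K]`. `aim_fst` returns 0 for markers
#'   monomorphic for the same allele in both populations (the 0/0 case,
#'   which carries no ancestry information).
#' @seealso [score_markers()] to compute all five on a [frequency_table()].
#' @export
#' @examples
#' aim_delta(0.7, 0.2)          # 0.5
#' aim_fst(0.9, 0.1)            # 0.64
#' aim_fic(1, 0, m1 = 0.8)      # 6.25
#' aim_sic(1, 0, m1 = 0.5)      # log(2)
#' aim_in(c(1, 0))              # log(2): fixed difference, K = 2
aim_delta <- function(p1, p2) {
  check_prob(p1); check_prob(p2)
  abs(p1 - p2)
}

#' @rdname aim_delta
#' @export
aim_fst <- function(p1, p2) {
  check_prob(p1); check_prob(p2)
  s <- p1 + p2
  den <- s * (2 - s)
  out <- numeric(length(den))
  poly <- den > 0
  out[poly] <- ((p1 - p2)[poly])^2 / den[poly]
  out
}

#' @rdname aim_delta
#' @export
aim_fic <- function(p1, p2, m1 = 0.8) {
  check_prob(p1); check_prob(p2)
  if (!is.numeric(m1) || length(m1) != 1L || is.na(m1) ||
      m1 <= 0 || m1 >= 1) {
    stop("`m1` must lie strictly inside (0, 1) for FIC", call. = FALSE)
  }
  d <- p1 - p2                      # delta_1; delta_2 = -d
  pa1 <- p2 + m1 * d                # expected admixed ref-allele frequency
  pa2 <- 1 - pa1
  t1 <- ifelse(d == 0, 0, d^2 / pa1)  # d != 0, pa = 0 -> Inf by design
  t2 <- ifelse(d == 0, 0, d^2 / pa2)
  t1 + t2
}

#' @rdname aim_delta
#' @export
aim_sic <- function(p1, p2, m1 = 0.8, log_base = exp(1)) {
  check_prob(p1); check_prob(p2)
  if (!is.numeric(m1) || length(m1) != 1L || is.na(m1) || m1 < 0 || m1 > 1) {
    stop("`m1` must lie in [0, 1] for SIC", call. = FALSE)
  }
  m2 <- 1 - m1
  pa <- m1 * p1 + m2 * p2
  h1 <- xlogx(p1, log_base) + xlogx(1 - p1, log_base)
  h2 <- xlogx(p2, log_base) + xlogx(1 - p2, log_base)
  ha <- xlogx(pa, log_base) + xlogx(1 - pa, log_base)
  pmax(m1 * h1 + m2 * h2 - ha, 0) # clip tiny negative rounding residue
}

#' @rdname aim_delta
#' @export
aim_in <- function(freqs, log_base = exp(1)) {
  if (is.null(dim(freqs))) {
    check_prob(freqs, "freqs")
    freqs <- cbind(freqs, 1 - freqs)
  }
  freqs <- as.matrix(freqs)
  K <- nrow(freqs)
  if (K < 2L) stop("informativeness for assignment needs K >= 2 populations",
                   call. = FALSE)
  if (any(abs(rowSums(freqs) - 1) > 1e-9)) {
    stop("each population's allele frequencies must sum to 1", call. = FALSE)
  }
  pbar <- colMeans(freqs)
  sum(-xlogx(pbar, log_base)) + sum(xlogx(freqs, log_base)) / K
}

#' Score every marker of a frequency table with all five measures
#'
#' Computes delta, Fst, FIC, SIC and the informativeness-for-assignment
#' measure for each marker, together with per-measure ranks (1 = most
#' informative). The four pairwise measures require exactly two
#' populations; `aim_in` generalizes to K >= 2, so tables with more than two
#' populations are rejected here with an error naming the unsupported
#' measures.
#'
#' Ranks are assigned in descending score order with the deterministic
#' tie-break (chromosome, position, marker id); an infinite FIC (a marker
#' whose expected admixed frequency is exactly 0 for a divergent allele)
#' ranks above every finite score. Markers monomorphic for the same allele
#' in both populations score 0 on all five measures and are flagged in the
#' `monomorphic` column.
#'
#' @param table a two-population [frequency_table()].
#' @param m1 assumed contribution of the first population, used by FIC and
#'   SIC (default 0.8).
#' @param log_base logarithm base for SIC and I_n (default natural log).
#'
#' @return A `data.frame` of class `"measure_scores"` with columns
#'   `marker_id`, `chrom`, `pos`, `monomorphic`, the five score columns
#'   (`delta`, `fst`, `fic`, `sic`, `i_n`) and five rank columns
#'   (`rank_delta`, ..., `rank_i_n`); attribute `config` records `m1` and
#'   `log_base`.
#' @seealso [distance_filter()], [combined_rank()], [write_scores()]
#' @export
#' @examples
#' ft <- frequency_table(
#'   marker_id = paste0("rs", 1:3), chrom = "chr1",
#'   pos = c(1e5, 3e5, 5e5),
#'   freqs = cbind(ceu = c(1, 0.7, 0.5), yri = c(0, 0.2, 0.5))
#' )
#' score_markers(ft)
score_markers <- function(table, m1 = 0.8, log_base = exp(1)) {
  stopifnot(inherits(table, "freq_table"))
  pops <- pop_names(table)
  if (length(pops) > 2L) {
    stop("delta, fst, fic and sic are defined for exactly 2 populations; ",
         "got ", length(pops),
         " (only i_n generalizes to K > 2 - see aim_in())", call. = FALSE)
  }
  if (length(pops) < 2L) stop("need two populations", call. = FALSE)

  P <- pop_freqs(table)
  p1 <- P[, 1L]; p2 <- P[, 2L]
  if (anyNA(p1) || anyNA(p2)) {
    stop("frequency table contains markers untyped in one population; ",
         "apply filter_shared() first", call. = FALSE)
  }
  M <- nrow(table)
  mono <- (p1 == p2) & (p1 == 0 | p1 == 1)

  out <- data.frame(
    marker_id = table$marker_id, chrom = table$chrom, pos = table$pos,
    monomorphic = mono,
    delta = aim_delta(p1, p2),
    fst = aim_fst(p1, p2),
    fic = if (M) aim_fic(p1, p2, m1) else numeric(0),
    sic = if (M) aim_sic(p1, p2, m1, log_base) else numeric(0),
    i_n = in_biallelic(cbind(p1, p2), log_base),
    stringsAsFactors = FALSE
  )
  for (msr in c("delta", "fst", "fic", "sic", "i_n")) {
    ord <- order_with_tiebreak(-out[[msr]], out$chrom, out$pos,
                               out$marker_id)
    rk <- integer(M); rk[ord] <- seq_len(M)
    out[[paste0("rank_", msr)]] <- rk
  }
  structure(out, config = list(m1 = m1, log_base = log_base),
            pops = pops,
            class = c("measure_scores", "data.frame"))
}

# Vectorized I_n across markers for the biallelic K-population case.
# P: markers x K matrix of reference-allele frequencies.
in_biallelic <- function(P, log_base = exp(1)) {
  if (nrow(P) == 0L) return(numeric(0))
  K <- ncol(P)
  pbar <- rowMeans(P)
  ref <- -xlogx(pbar, log_base) + rowSums(xlogx(P, log_base)) / K
  alt <- -xlogx(1 - pbar, log_base) + rowSums(xlogx(1 - P, log_base)) / K
  pmax(ref + alt, 0)
}

#' @export
print.measure_scores <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "Informativeness scores: %d markers (m1 = %g, log base = %g)\n",
    nrow(x), cfg$m1, cfg$log_base))
  NextMethod()
}
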