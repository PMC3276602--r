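#' Spearman rank correlation with tie-averaged ranks
#'
#' Pearson correlation of the tie-averaged ranks of the two inputs, the
#' classical Spearman coefficient. Used to quantify how similarly two
#' informativeness measures order the same markers.
#'
#' @param x,y numeric vectors of equal length >= 2; neither may be constant
#'   (the correlation is undefined then).
#' @return Correlation in `[-1, 1]`.
#' @export
#' @examples
#' spearman_rho(1:3, c(10, 20, 30)) # +1
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (anyNA(x) || anyNA(y)) stop("NA values not allowed", call. = FALSE)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    stop("Spearman correlation undefined for a constant vector",
         call. = FALSE)
  }
  stats::cor(rx, ry)
}

#' Assign markers to informativeness decile groups
#'
#' Group 1 contains the most informative tenth of the markers, group
#' `n_groups` the least informative tenth. Group sizes are equal up to one
#' marker. Ties in the score are resolved by the deterministic
#' (chromosome, position, marker id) tie-break so the labels are
#' reproducible.
#'
#' @param scores numeric informativeness scores (higher = more informative).
#' @param chrom,pos,marker_id optional tie-break keys aligned with `scores`;
#'   default to the input order.
#' @param n_groups number of quantile groups (default 10 = deciles).
#' @return Integer vector of group labels `1..n_groups` aligned with the
#'   input.
#' @export
decile_groups <- function(scores, chrom = NULL, pos = NULL,
                          marker_id = NULL, n_groups = 10L) {
  M <- length(scores)
  if (M < n_groups) {
    stop(sprintf("need at least %d markers for %d groups", n_groups,
                 n_groups), call. = FALSE)
  }
  if (is.null(chrom)) chrom <- rep("", M)
  if (is.null(pos)) pos <- seq_len(M)
  if (is.null(marker_id)) marker_id <- sprintf("m%09d", seq_len(M))
  ord <- order_with_tiebreak(-scores, chrom, pos, marker_id)
  sizes <- rep(M %/% n_groups, n_groups)
  extra <- M %% n_groups
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- rep.int(seq_len(n_groups), sizes)
  out <- integer(M)
  out[ord] <- labels
  out
}

#' Cohen's kappa agreement between two decile groupings
#'
#' Chance-corrected agreement `kappa = (Pr(a) - Pr(e)) / (1 - Pr(e))`, where
#' `Pr(a)` is the observed fraction of markers placed in the same group by
#' both measures and `Pr(e)` the agreement expected by chance from the
#' marginal group frequencies. The full contingency table is returned for
#' mosaic-plot style inspection. A negative kappa (worse than chance) is
#' reported as-is and flagged rather than clamped to zero, since clamping
#' would hide genuine disagreement.
#'
#' @param groups_a,groups_b integer group labels for the same markers (same
#'   length, same label universe).
#' @return List of class `"kappa_result"`: `kappa`, `pr_a`, `pr_e`, `table`
#'   (G x G contingency counts) and `negative` flag.
#' @export
#' @examples
#' g <- rep(1:2, c(25, 25))
#' h <- c(rep(1, 20), rep(2, 5), rep(1, 10), rep(2, 15))
#' kappa_deciles(g, h)$kappa # 0.4
kappa_deciles <- function(groups_a, groups_b) {
  stopifnot(length(groups_a) == length(groups_b), length(groups_a) > 0L)
  lev <- sort(unique(c(groups_a, groups_b)))
  tab <- table(factor(groups_a, levels = lev),
               factor(groups_b, levels = lev))
  n <- sum(tab)
  pr_a <- sum(diag(tab)) / n
  pr_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- (pr_a - pr_e) / (1 - pr_e)
  structure(list(kappa = kappa, pr_a = pr_a, pr_e = pr_e,
                 table = unclass(tab), negative = kappa < 0),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.4f (Pr(a) = %.4f, Pr(e) = %.4f)%s\n",
              x$kappa, x$pr_a, x$pr_e,
              if (x$negative) " [below chance]" else ""))
  invisible(x)
}

#' Overlap patterns of top-n AIM sets across the five measures
#'
#' Each marker in the union of the five top-n sets is assigned a 5-digit
#' binary membership pattern in the fixed measure order delta, Fst, FIC,
#' SIC, I_n: pattern `"11001"` means the marker was selected by delta, Fst
#' and I_n but not FIC or SIC. Pattern counts plus all 10 pairwise
#' intersection sizes are returned.
#'
#' @param top_sets list of five character vectors of marker ids, in the
#'   order delta, Fst, FIC, SIC, I_n (names, if present, are used for the
#'   pairwise matrix labels).
#' @return List with `patterns` (data.frame `pattern`, `count`, sorted by
#'   decreasing count) and `pairwise` (5 x 5 symmetric matrix of
#'   intersection sizes, diagonal = set sizes).
#' @export
#' @examples
#' overlap_patterns(list(delta = "A", fst = "A", fic = "B",
#'                       sic = "B", i_n = "A"))
overlap_patterns <- function(top_sets) {
  stopifnot(is.list(top_sets), length(top_sets) == 5L)
  nms <- names(top_sets)
  if (is.null(nms) || any(!nzchar(nms))) {
    nms <- c("delta", "fst", "fic", "sic", "i_n")
  }
  universe <- sort(unique(unlist(top_sets, use.names = FALSE)))
  member <- vapply(top_sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  pattern <- apply(member, 1L, function(b) paste(as.integer(b),
                                                 collapse = ""))
  counts <- table(pattern)
  patterns <- data.frame(pattern = names(counts),
                         count = as.integer(counts),
                         stringsAsFactors = FALSE)
  patterns <- patterns[order(-patterns$count, patterns$pattern), ,
                       drop = FALSE]
  rownames(patterns) <- NULL
  pairwise <- crossprod(member)
  dimnames(pairwise) <- list(nms, nms)
  list(patterns = patterns, pairwise = pairwise)
}

#' Full concordance report between the five measures
#'
#' Convenience wrapper assembling the pairwise Spearman matrix, pairwise
#' decile-kappa matrix with contingency tables, and the top-n overlap
#' pattern table, as typically exported together.
#'
#' @param scores a [score_markers()] result.
#' @param top_n size of the top sets for the overlap analysis (default 100).
#' @return List with `spearman` (5 x 5), `kappa` (5 x 5),
#'   `contingency` (named list of 10 G x G tables) and `overlap` (see
#'   [overlap_patterns()]).
#' @export
concordance_report <- function(scores, top_n = 100L) {
  stopifnot(inherits(scores, "measure_scores"))
  measures <- c("delta", "fst", "fic", "sic", "i_n")
  S <- diag(1, 5L); K <- diag(1, 5L)
  dimnames(S) <- dimnames(K) <- list(measures, measures)
  groups <- lapply(measures, function(m) {
    decile_groups(scores[[m]], scores$chrom, scores$pos, scores$marker_id)
  })
  names(groups) <- measures
  tops <- lapply(measures, function(m) {
    scores$marker_id[scores[[paste0("rank_", m)]] <= top_n]
  })
  names(tops) <- measures
  contingency <- list()
  for (a in 1:4) for (b in (a + 1):5) {
    # spearman on finite scores only (FIC can be Inf; ranks handle it, but
    # cor of ranks is what we report and rank() maps Inf to the top rank)
    S[a, b] <- S[b, a] <- spearman_rho(rank(-scores[[measures[a]]]),
                                       rank(-scores[[measures[b]]]))
    kr <- kappa_deciles(groups[[a]], groups[[b]])
    K[a, b] <- K[b, a] <- kr$kappa
    contingency[[paste(measures[a], measures[b], sep = "_")]] <- kr$table
  }
  list(spearman = S, kappa = K, contingency = contingency,
       overlap = overlap_patterns(tops))
}
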