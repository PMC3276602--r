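#' Build a distance-filtered AIM panel from per-marker scores
#'
#' Greedy selection in descending informativeness order: markers are visited
#' from the best rank down, and a candidate is rejected if an
#' already-selected marker on the same chromosome lies strictly closer than
#' `min_bp` base pairs. Markers exactly `min_bp` apart are allowed ("at
#' least" semantics). The greedy-by-score interpretation (rather than a
#' left-to-right genomic scan) keeps the most informative marker of every
#' crowded region.
#'
#' @param scores a [score_markers()] result (possibly augmented by
#'   [combined_rank()]).
#' @param measure which ranking to use: one of `"delta"`, `"fst"`, `"fic"`,
#'   `"sic"`, `"i_n"`, or a combined ranking `"ave"`/`"min"` previously added
#'   with [combined_rank()].
#' @param min_bp minimum physical spacing in base pairs between any two
#'   selected markers on the same chromosome (default 100 kb; 0 disables the
#'   filter).
#'
#' @return An `"aim_panel"` data.frame with columns `marker_id`, `chrom`,
#'   `pos`, `score`, `rank` (1 = best within the panel), ordered by rank;
#'   attributes `measure`, `rule` and `min_bp` record the provenance. For
#'   the combined rankings the `score` column holds the combined rank score,
#'   for which smaller is better.
#' @seealso [select_markers()], [combined_rank()], [write_panel()]
#' @export
#' @examples
#' ft <- frequency_table(paste0("rs", 1:3), "chr1",
#'                       pos = c(100000, 150000, 260000),
#'                       freqs = cbind(a = c(0.95, 0.9, 0.85),
#'                                     b = c(0.05, 0.1, 0.15)))
#' sc <- score_markers(ft)
#' distance_filter(sc, "delta")$marker_id # rs2 is 50 kb from rs1: dropped
distance_filter <- function(scores, measure = "i_n", min_bp = 100000) {
  stopifnot(inherits(scores, "measure_scores"), min_bp >= 0)
  rank_col <- paste0("rank_", measure)
  if (is.null(scores[[rank_col]])) {
    stop("no ranking `", rank_col, "` in scores; for 'ave'/'min' call ",
         "combined_rank() first", call. = FALSE)
  }
  if (anyNA(scores$pos)) {
    bad <- scores$marker_id[is.na(scores$pos)]
    stop("markers without map positions: ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) ", ..." else "", call. = FALSE)
  }
  ord <- order(scores[[rank_col]])
  keep <- logical(nrow(scores))
  taken <- list()  # per-chromosome sorted positions of accepted markers
  chrom <- scores$chrom
  pos <- scores$pos
  for (i in ord) {
    ch <- chrom[i]
    v <- taken[[ch]]
    if (is.null(v)) {
      taken[[ch]] <- pos[i]
      keep[i] <- TRUE
      next
    }
    j <- findInterval(pos[i], v)
    ok <- (j == 0L || pos[i] - v[j] >= min_bp) &&
      (j == length(v) || v[j + 1L] - pos[i] >= min_bp)
    if (ok) {
      taken[[ch]] <- append(v, pos[i], after = j)
      keep[i] <- TRUE
    }
  }
  sel <- scores[keep, , drop = FALSE]
  sel <- sel[order(sel[[rank_col]]), , drop = FALSE]
  score_col <- if (measure %in% c("ave", "min")) {
    paste0("score_", measure)
  } else {
    measure
  }
  new_panel(
    data.frame(marker_id = sel$marker_id, chrom = sel$chrom, pos = sel$pos,
               score = sel[[score_col]], rank = seq_len(nrow(sel)),
               stringsAsFactors = FALSE),
    measure = measure,
    rule = list(type = "distance_filter", min_bp = min_bp),
    min_bp = min_bp
  )
}

new_panel <- function(df, measure, rule, min_bp) {
  rownames(df) <- NULL
  structure(df, measure = measure, rule = rule, min_bp = min_bp,
            class = c("aim_panel", "data.frame"))
}

#' Select markers from a panel by a top-n, top-fraction or cutoff rule
#'
#' @param panel an `"aim_panel"` (ordered by rank), e.g. from
#'   [distance_filter()].
#' @param top_n keep the `n` best-ranked markers; it is an error to request
#'   more markers than the panel holds.
#' @param top_fraction keep the best `ceiling(q * M)` markers for a fraction
#'   `q` in (0, 1]; the ceiling guarantees a non-empty panel for any
#'   positive fraction.
#' @param cutoff keep all markers with score >= the threshold. Either a
#'   number, or `NULL` combined with `use_default_cutoff = TRUE` to use the
#'   conventional literature threshold for the panel's measure (see
#'   [aim_cutoffs()]).
#' @param use_default_cutoff apply the registry cutoff for the panel's
#'   measure.
#'
#' @return An `"aim_panel"` restricted to the selected markers, rank order
#'   preserved, with the selection rule recorded in the `rule` attribute.
#' @export
#' @examples
#' ft <- frequency_table(paste0("rs", 1:3), "chr1", c(1e5, 3e5, 5e5),
#'                       cbind(a = c(0.95, 0.8, 0.55),
#'                             b = c(0.05, 0.45, 0.45)))
#' pan <- distance_filter(score_markers(ft), "delta", min_bp = 0)
#' select_markers(pan, top_n = 2)$marker_id
#' select_markers(pan, cutoff = 0.3)$marker_id  # delta >= 0.3
select_markers <- function(panel, top_n = NULL, top_fraction = NULL,
                           cutoff = NULL, use_default_cutoff = FALSE) {
  stopifnot(inherits(panel, "aim_panel"))
  n_rules <- sum(!is.null(top_n), !is.null(top_fraction),
                 !is.null(cutoff) || use_default_cutoff)
  if (n_rules != 1L) {
    stop("specify exactly one of top_n, top_fraction, cutoff", call. = FALSE)
  }
  M <- nrow(panel)
  measure <- attr(panel, "measure")
  if (!is.null(top_n)) {
    if (top_n < 0 || top_n > M) {
      stop(sprintf("top_n = %d outside the panel size %d", top_n, M),
           call. = FALSE)
    }
    out <- panel[seq_len(top_n), , drop = FALSE]
    rule <- list(type = "top_n", n = top_n)
  } else if (!is.null(top_fraction)) {
    if (top_fraction <= 0 || top_fraction > 1) {
      stop("top_fraction must lie in (0, 1]", call. = FALSE)
    }
    n <- ceiling(top_fraction * M)
    out <- panel[seq_len(n), , drop = FALSE]
    rule <- list(type = "top_fraction", q = top_fraction, n = n)
  } else {
    thr <- if (use_default_cutoff && is.null(cutoff)) {
      if (measure %in% c("ave", "min")) {
        stop("no default cutoff for combined rankings", call. = FALSE)
      }
      aim_cutoffs()[[measure]]
    } else {
      cutoff
    }
    out <- panel[panel$score >= thr, , drop = FALSE]
    rule <- list(type = "cutoff", threshold = thr)
  }
  new_panel(out, measure = measure,
            rule = c(rule, list(min_bp = attr(panel, "min_bp"))),
            min_bp = attr(panel, "min_bp"))
}

#' Conventional literature cutoffs for the five measures
#'
#' Thresholds in common use for declaring a SNP an AIM: delta >= 0.3,
#' Fst >= 0.4, FIC >= 2.0, SIC >= 0.3 and I_n >= 0.3.
#'
#' @return Named list of numeric thresholds.
#' @export
aim_cutoffs <- function() {
  list(delta = 0.3, fst = 0.4, fic = 2.0, sic = 0.3, i_n = 0.3)
}

#' Combine the five measure rankings into AVE or MIN rankings
#'
#' Each marker receives a combined score equal to the mean (`"ave"`) or the
#' minimum (`"min"`) of its five per-measure ranks; the combined ranking is
#' ascending in that score with the usual (chrom, pos, id) tie-break. Raw
#' measure values are deliberately not averaged: they live on incomparable
#' scales, whereas ranks are directly commensurable.
#'
#' @param scores a [score_markers()] result with all five rank columns.
#' @param method `"ave"`, `"min"`, or both (default: both).
#'
#' @return `scores` with added columns `score_ave`/`rank_ave` and/or
#'   `score_min`/`rank_min`.
#' @export
combined_rank <- function(scores, method = c("ave", "min")) {
  stopifnot(inherits(scores, "measure_scores"))
  method <- match.arg(method, several.ok = TRUE)
  rank_cols <- paste0("rank_", c("delta", "fst", "fic", "sic", "i_n"))
  missing_cols <- setdiff(rank_cols, names(scores))
  if (length(missing_cols)) {
    stop("missing rank columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  R <- as.matrix(scores[rank_cols])
  M <- nrow(scores)
  for (meth in method) {
    comb <- if (meth == "ave") rowMeans(R) else do.call(pmin, scores[rank_cols])
    ord <- order_with_tiebreak(comb, scores$chrom, scores$pos,
                               scores$marker_id)
    rk <- integer(M); rk[ord] <- seq_len(M)
    scores[[paste0("score_", meth)]] <- comb
    scores[[paste0("rank_", meth)]] <- rk
  }
  scores
}
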