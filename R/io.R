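# Readers and writers for the on-disk exchange formats. Everything is plain
# TSV (with `#`-prefixed provenance headers where needed) or JSON; no binary
# formats. Coordinates are 1-based inclusive base pairs; strand is ignored
# because frequencies, not sequences, are exchanged.

#' Read a marker-by-population allele frequency table
#'
#' Two dialects are supported:
#'
#' * `"generic"` — a TSV with columns `marker_id`, `chrom`, `pos`,
#'   `ref_allele`, `alt_allele`, one `freq_<pop>` column per population
#'   (reference-allele frequency) and optionally `missing_fraction`.
#' * `"hapmap"` — whitespace-delimited per-population allele-frequency
#'   files in the HapMap phase III style, with columns `rs#`, `chrom`,
#'   `pos`, `strand`, `ref-allele`, `ref-allele-freq`, `other-allele`,
#'   `other-allele-freq` (one file per population, passed as a vector of
#'   paths). Files are merged by marker id, keeping the intersection;
#'   rows whose two frequencies do not sum to 1 within 0.01, or that
#'   cannot be parsed, are skipped and counted. If the reference allele
#'   of a later file disagrees with the first file but matches its
#'   alternate allele, the frequency is flipped.
#'
#' @param paths one path (`"generic"`) or one path per population
#'   (`"hapmap"`).
#' @param dialect `"generic"` or `"hapmap"`.
#' @param pop_names population labels; for `"hapmap"` defaults to
#'   `names(paths)` or `pop1, pop2, ...`.
#' @return A [frequency_table()]. The number of skipped rows is reported
#'   via `message()` and stored in the `n_rejected` attribute.
#' @export
read_frequency_table <- function(paths, dialect = c("generic", "hapmap"),
                                 pop_names = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "generic") {
    read_freq_generic(paths)
  } else {
    read_freq_hapmap(paths, pop_names)
  }
}

read_freq_generic <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  required <- c("marker_id", "chrom", "pos")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  freq_cols <- grep("^freq_", names(df), value = TRUE)
  if (!length(freq_cols)) {
    stop("missing required column(s): freq_<population>", call. = FALSE)
  }
  pops <- sub("^freq_", "", freq_cols)
  bad <- rep(FALSE, nrow(df))
  for (fc in freq_cols) {
    v <- df[[fc]]
    bad <- bad | (!is.na(v) & (v < 0 | v > 1))
  }
  if (any(bad)) {
    message(sum(bad), " row(s) with out-of-range frequencies skipped")
    df <- df[!bad, , drop = FALSE]
  }
  tab <- frequency_table(
    marker_id = df$marker_id, chrom = df$chrom, pos = df$pos,
    freqs = as.matrix(df[freq_cols]), pop_names = pops,
    missing_fraction = if ("missing_fraction" %in% names(df)) {
      df$missing_fraction
    } else 0,
    ref_allele = if ("ref_allele" %in% names(df)) df$ref_allele else "A",
    alt_allele = if ("alt_allele" %in% names(df)) df$alt_allele else "B"
  )
  attr(tab, "n_rejected") <- sum(bad)
  tab
}

read_freq_hapmap <- function(paths, pop_names = NULL) {
  if (is.null(pop_names)) {
    pop_names <- names(paths) %||% paste0("pop", seq_along(paths))
  }
  stopifnot(length(pop_names) == length(paths))
  n_rejected <- 0L
  per_pop <- vector("list", length(paths))
  for (k in seq_along(paths)) {
    raw <- utils::read.table(paths[k], header = FALSE, skip = 1L,
                             stringsAsFactors = FALSE, fill = TRUE,
                             comment.char = "")
    if (ncol(raw) < 8L) {
      stop("HapMap-dialect file needs 8 whitespace-delimited columns: ",
           paths[k], call. = FALSE)
    }
    raw <- raw[, 1:8]
    names(raw) <- c("marker_id", "chrom", "pos", "strand", "ref_allele",
                    "ref_freq", "other_allele", "other_freq")
    raw$pos <- suppressWarnings(as.numeric(raw$pos))
    raw$ref_freq <- suppressWarnings(as.numeric(raw$ref_freq))
    raw$other_freq <- suppressWarnings(as.numeric(raw$other_freq))
    ok <- !is.na(raw$pos) & !is.na(raw$ref_freq) & !is.na(raw$other_freq) &
      raw$ref_freq >= 0 & raw$ref_freq <= 1 &
      abs(raw$ref_freq + raw$other_freq - 1) <= 0.01 &
      !duplicated(raw$marker_id)
    n_rejected <- n_rejected + sum(!ok)
    per_pop[[k]] <- raw[ok, , drop = FALSE]
  }
  shared <- Reduce(intersect, lapply(per_pop, `[[`, "marker_id"))
  anchor <- per_pop[[1L]]
  anchor <- anchor[match(shared, anchor$marker_id), , drop = FALSE]
  freqs <- matrix(NA_real_, nrow = length(shared), ncol = length(paths))
  freqs[, 1L] <- anchor$ref_freq
  drop_row <- rep(FALSE, length(shared))
  for (k in seq_along(paths)[-1L]) {
    cur <- per_pop[[k]][match(shared, per_pop[[k]]$marker_id), ,
                        drop = FALSE]
    same <- cur$ref_allele == anchor$ref_allele
    flipped <- cur$ref_allele == anchor$other_allele
    freqs[same, k] <- cur$ref_freq[same]
    freqs[flipped & !same, k] <- 1 - cur$ref_freq[flipped & !same]
    drop_row <- drop_row | (!same & !flipped)
  }
  n_rejected <- n_rejected + sum(drop_row)
  keep <- !drop_row
  if (n_rejected > 0L) {
    message(n_rejected, " malformed or inconsistent row(s) skipped")
  }
  tab <- frequency_table(
    marker_id = shared[keep], chrom = anchor$chrom[keep],
    pos = anchor$pos[keep], freqs = freqs[keep, , drop = FALSE],
    pop_names = pop_names,
    ref_allele = anchor$ref_allele[keep],
    alt_allele = anchor$other_allele[keep]
  )
  attr(tab, "n_rejected") <- n_rejected
  tab
}

#' Write a frequency table as generic-dialect TSV
#' @param table a [frequency_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(table, path) {
  stopifnot(inherits(table, "freq_table"))
  pops <- pop_names(table)
  out <- data.frame(marker_id = table$marker_id, chrom = table$chrom,
                    pos = table$pos, ref_allele = table$ref_allele,
                    alt_allele = table$alt_allele,
                    missing_fraction = table$missing_fraction,
                    stringsAsFactors = FALSE)
  for (p in pops) out[[paste0("freq_", p)]] <- table[[paste0("p_", p)]]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Keep markers typed in every population with acceptable missingness
#'
#' Implements the shared-SNP filter: a marker is kept when its frequency is
#' defined in every population and its `missing_fraction` does not exceed
#' `max_missing` (markers missing in strictly more than that fraction of
#' samples are excluded; a fraction exactly at the threshold is kept).
#'
#' @param table a [frequency_table()].
#' @param max_missing maximum tolerated missing fraction (default 0.10).
#' @return The filtered [frequency_table()]; a warning is issued when
#'   nothing survives.
#' @export
filter_shared <- function(table, max_missing = 0.10) {
  stopifnot(inherits(table, "freq_table"))
  P <- pop_freqs(table)
  keep <- rowSums(is.na(P)) == 0L & table$missing_fraction <= max_missing
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("no markers survive the shared-SNP filter",
                               call. = FALSE)
  for (a in c("pops", "chrom_lengths")) {
    attr(out, a) <- attr(table, a)
  }
  class(out) <- class(table)
  out
}

#' Write / read informativeness scores
#'
#' TSV with `#`-prefixed header lines recording the scoring configuration
#' (`m1`, logarithm base), restored on read.
#'
#' @param scores a [score_markers()] result.
#' @param path file path.
#' @return `write_scores()` returns `path` invisibly; `read_scores()`
#'   returns a `"measure_scores"` data.frame.
#' @export
write_scores <- function(scores, path) {
  stopifnot(inherits(scores, "measure_scores"))
  cfg <- attr(scores, "config")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# m1=%.17g", cfg$m1), con)
  writeLines(sprintf("# log_base=%.17g", cfg$log_base), con)
  utils::write.table(as.data.frame(scores), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "# ")]
  parse_hdr <- function(key) {
    ln <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(ln)) as.numeric(sub(paste0("^# ", key, "="), "", ln[1L]))
    else NA_real_
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  df$chrom <- as.character(df$chrom)
  structure(df,
            config = list(m1 = parse_hdr("m1"),
                          log_base = parse_hdr("log_base")),
            class = c("measure_scores", "data.frame"))
}

#' Write / read an AIM panel
#'
#' TSV with `#` header lines recording the measure, the selection rule, the
#' spacing constraint and a lightweight checksum of the marker content.
#'
#' @param panel an `"aim_panel"`.
#' @param path file path.
#' @return `write_panel()` returns `path` invisibly; `read_panel()` an
#'   `"aim_panel"`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "aim_panel"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# measure=%s", attr(panel, "measure")),
    sprintf("# rule=%s", jsonlite::toJSON(attr(panel, "rule"),
                                          auto_unbox = TRUE)),
    sprintf("# min_bp=%.17g", attr(panel, "min_bp")),
    sprintf("# checksum=%d:%.0f", nrow(panel), sum(panel$pos))
  ), con)
  utils::write.table(as.data.frame(panel), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "# ")]
  get_hdr <- function(key) {
    ln <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(ln)) sub(paste0("^# ", key, "="), "", ln[1L]) else NA
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  df$chrom <- as.character(df$chrom)
  rule <- tryCatch(jsonlite::fromJSON(get_hdr("rule")),
                   error = function(e) NULL)
  new_panel(df, measure = get_hdr("measure"), rule = rule,
            min_bp = as.numeric(get_hdr("min_bp")))
}

#' Write / read admixture estimates
#'
#' TSV of per-individual estimates plus an optional JSON summary (mean and
#' SD of `q_hat`).
#'
#' @param estimate an [estimate_ancestry()] result.
#' @param path TSV path.
#' @param summary_path optional path for the JSON summary.
#' @return `write_estimates()` returns `path` invisibly;
#'   `read_estimates()` an `"ancestry_estimate"`.
#' @export
write_estimates <- function(estimate, path, summary_path = NULL) {
  stopifnot(inherits(estimate, "ancestry_estimate"))
  utils::write.table(as.data.frame(estimate), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(summary_path)) {
    jsonlite::write_json(
      list(mean_q_hat = attr(estimate, "mean_q_hat"),
           sd_q_hat = attr(estimate, "sd_q_hat"),
           n = nrow(estimate),
           identifiable = attr(estimate, "identifiable")),
      summary_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  structure(df,
            mean_q_hat = mean(df$q_hat, na.rm = TRUE),
            sd_q_hat = stats::sd(df$q_hat[!is.na(df$q_hat)]),
            identifiable = !all(is.na(df$q_hat)),
            class = c("ancestry_estimate", "data.frame"))
}

#' Write a JSON provenance record for a run
#'
#' @param config named list (parameters, seeds, input paths/checksums).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
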