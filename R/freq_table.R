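#' Construct a marker-by-population allele frequency table
#'
#' The frequency table is the central container of the package: one row per
#' biallelic SNP, one frequency column per population holding the
#' reference-allele frequency \eqn{p_{i1}} (the alternate-allele frequency is
#' \eqn{1 - p_{i1}}). Rows are sorted by (chromosome, position) and marker
#' identifiers must be unique.
#'
#' @param marker_id character vector of unique marker identifiers.
#' @param chrom chromosome labels (coerced to character).
#' @param pos 1-based base-pair positions (>= 1).
#' @param freqs numeric matrix (markers x populations) of reference-allele
#'   frequencies in `[0, 1]`; `NA` marks a population where the marker was
#'   not typed.
#' @param pop_names population labels; defaults to `colnames(freqs)`.
#' @param missing_fraction per-marker fraction of samples without a genotype
#'   call (used by [filter_shared()]); defaults to 0.
#' @param ref_allele,alt_allele optional allele labels carried through I/O;
#'   default to the synthetic labels `"A"` and `"B"`.
#'
#' @return A `data.frame` of class `"freq_table"` with columns `marker_id`,
#'   `chrom`, `pos`, `ref_allele`, `alt_allele`, `missing_fraction` and one
#'   `p_<pop>` column per population, plus attributes `pops` and (optionally)
#'   `chrom_lengths`.
#' @seealso [score_markers()], [generate_ancestral_freqs()],
#'   [read_frequency_table()]
#' @export
#' @examples
#' ft <- frequency_table(
#'   marker_id = c("rs1", "rs2"), chrom = c("chr1", "chr1"),
#'   pos = c(1e5, 3e5), freqs = cbind(popA = c(0.9, 0.5), popB = c(0.1, 0.5))
#' )
#' pop_freqs(ft)
frequency_table <- function(marker_id, chrom, pos, freqs,
                            pop_names = colnames(freqs),
                            missing_fraction = 0,
                            ref_allele = "A", alt_allele = "B") {
  freqs <- as.matrix(freqs)
  if (is.null(pop_names)) {
    pop_names <- paste0("pop", seq_len(ncol(freqs)))
  }
  stopifnot(length(marker_id) == nrow(freqs),
            length(chrom) %in% c(1L, length(marker_id)),
            length(pos) == length(marker_id),
            length(pop_names) == ncol(freqs))
  if (anyDuplicated(marker_id)) {
    stop("marker_id values must be unique", call. = FALSE)
  }
  if (length(marker_id) && any(pos < 1, na.rm = TRUE)) {
    stop("positions must be >= 1 (1-based coordinates)", call. = FALSE)
  }
  ok <- is.na(freqs) | (freqs >= 0 & freqs <= 1)
  if (!all(ok)) stop("allele frequencies must lie in [0, 1]", call. = FALSE)

  out <- data.frame(
    marker_id = as.character(marker_id),
    chrom = rep_len(as.character(chrom), length(marker_id)),
    pos = as.numeric(pos),
    ref_allele = rep_len(as.character(ref_allele), length(marker_id)),
    alt_allele = rep_len(as.character(alt_allele), length(marker_id)),
    missing_fraction = rep_len(as.numeric(missing_fraction),
                               length(marker_id)),
    stringsAsFactors = FALSE
  )
  for (k in seq_along(pop_names)) {
    out[[paste0("p_", pop_names[k])]] <- as.numeric(freqs[, k])
  }
  ord <- order(out$chrom, out$pos, out$marker_id, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, pops = as.character(pop_names),
            class = c("freq_table", "data.frame"))
}

#' Population labels of a frequency table
#' @param table a [frequency_table()].
#' @return Character vector of population names.
#' @export
pop_names <- function(table) attr(table, "pops")

#' Reference-allele frequency matrix of a table
#' @param table a [frequency_table()].
#' @return Numeric matrix (markers x populations) of reference-allele
#'   frequencies, columns named by population.
#' @export
pop_freqs <- function(table) {
  pops <- pop_names(table)
  m <- as.matrix(table[paste0("p_", pops)])
  colnames(m) <- pops
  m
}

#' Across-population mean allele frequencies
#'
#' Returns \eqn{\bar p_j}, the unweighted mean of the population allele
#' frequencies, for both alleles of each biallelic marker.
#'
#' @param table a [frequency_table()].
#' @return Two-column matrix (`ref`, `alt`) of mean frequencies.
#' @export
mean_freqs <- function(table) {
  p <- rowMeans(pop_freqs(table))
  cbind(ref = p, alt = 1 - p)
}

#' @export
`[.freq_table` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "pops") <- attr(x, "pops")
    attr(out, "chrom_lengths") <- attr(x, "chrom_lengths")
    class(out) <- class(x)
  }
  out
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("Allele frequency table: %d markers x %d populations (%s)\n",
              nrow(x), length(pop_names(x)),
              paste(pop_names(x), collapse = ", ")))
  NextMethod()
}
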