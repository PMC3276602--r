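# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards. seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # initialize the stream so it can be saved
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# x * log(x) with the entropy convention 0 * log 0 = 0.
xlogx <- function(x, base = exp(1)) {
  out <- x # preserves dim for matrix input
  out[] <- 0
  pos <- x > 0
  out[pos] <- x[pos] * log(x[pos], base = base)
  out
}

check_prob <- function(x, name = deparse(substitute(x))) {
  if (length(x) == 0L) return(invisible(x))
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    stop(sprintf("`%s` must be a numeric frequency in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

# Deterministic tie-break ordering used everywhere a rank is assigned:
# primary key(s) first, then (chrom, pos, marker_id).
order_with_tiebreak <- function(primary, chrom, pos, marker_id) {
  order(primary, chrom, pos, marker_id, method = "radix")
}
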