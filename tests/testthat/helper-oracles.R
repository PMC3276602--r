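# Independent brute-force oracles: each re-evaluates the printed formula
# with explicit per-allele loops, sharing no code with the implementation.

oracle_delta <- function(p1, p2) abs(p1 - p2)

oracle_fst <- function(p1, p2) {
  num <- (p1 - p2)^2
  den <- (p1 + p2) * (2 - (p1 + p2))
  if (den == 0) 0 else num / den
}

oracle_fic <- function(p1, p2, m1) {
  pj <- rbind(c(p1, 1 - p1), c(p2, 1 - p2))
  total <- 0
  for (j in 1:2) {
    dj <- pj[1, j] - pj[2, j]
    paj <- pj[2, j] + m1 * dj
    total <- total + if (dj == 0) 0 else dj^2 / paj
  }
  total
}

oracle_sic <- function(p1, p2, m1, base = exp(1)) {
  xl <- function(p) if (p > 0) p * log(p, base) else 0
  pj <- rbind(c(p1, 1 - p1), c(p2, 1 - p2))
  m <- c(m1, 1 - m1)
  total <- 0
  for (i in 1:2) for (j in 1:2) total <- total + m[i] * xl(pj[i, j])
  for (j in 1:2) {
    paj <- m[1] * pj[1, j] + m[2] * pj[2, j]
    total <- total - xl(paj)
  }
  total
}

oracle_in <- function(freqs, base = exp(1)) {
  xl <- function(p) if (p > 0) p * log(p, base) else 0
  K <- nrow(freqs); N <- ncol(freqs)
  total <- 0
  for (j in seq_len(N)) {
    pbar <- mean(freqs[, j])
    term <- -xl(pbar)
    for (i in seq_len(K)) term <- term + xl(freqs[i, j]) / K
    total <- total + term
  }
  total
}

# O(n^2) tie-averaged ranks, independent of base::rank
oracle_avg_rank <- function(v) {
  vapply(v, function(x) sum(v < x) + (sum(v == x) + 1) / 2, numeric(1))
}

oracle_spearman <- function(x, y) {
  rx <- oracle_avg_rank(x); ry <- oracle_avg_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# small deterministic frequency table for unit tests
toy_table <- function(p1, p2, chrom = "chr1",
                      pos = seq(1e5, by = 2e5, length.out = length(p1))) {
  frequency_table(
    marker_id = sprintf("rs%03d", seq_along(p1)),
    chrom = chrom, pos = pos,
    freqs = cbind(popA = p1, popB = p2)
  )
}
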