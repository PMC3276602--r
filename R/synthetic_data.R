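#' Configuration for the synthetic admixture study
#'
#' Bundles every knob of the synthetic-data generator: marker density,
#' genome layout, the Balding-Nichols differentiation level of the two
#' ancestral populations, and the demography of the admixed deme (initial
#' contribution, generations of random mating, sample sizes,
#' recombination).
#'
#' The defaults describe a CEU/YRI-like scenario: 20,000 common SNPs on 22
#' chromosomes of 125 Mb, differentiation `F = 0.15`, an admixed deme
#' founded with a 70% contribution from population 1 and mated randomly for
#' 10 generations at constant size 200, from which 100 diploid individuals
#' are sampled. `chbjpt_config()` is a preset for a weakly differentiated
#' pair (`F = 0.015`, initial contribution 72%).
#'
#' @param L number of biallelic markers.
#' @param chrom_lengths base pairs per chromosome (names become chromosome
#'   labels; unnamed vectors are labelled `chr1`, `chr2`, ...).
#' @param F Balding-Nichols differentiation coefficient in (0, 1).
#' @param m0 initial contribution of ancestral population 1 to the admixed
#'   deme, in `[0, 1]`.
#' @param G generations of random mating after founding (>= 0).
#' @param n_admixed diploid individuals sampled from the final generation.
#' @param n_founders founders of the admixed deme (also its constant size;
#'   must be >= 2 and >= `n_admixed`).
#' @param recomb_rate recombination rate in Morgans per base pair (default
#'   1e-8, the genome-wide human average).
#' @param seed RNG seed recorded in the configuration and used by the
#'   generator functions.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(L = 20000L, chrom_lengths = rep(125e6, 22),
                       F = 0.15, m0 = 0.7, G = 10L, n_admixed = 100L,
                       n_founders = 200L, recomb_rate = 1e-8,
                       seed = NULL) {
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  stopifnot(L >= 1L, all(chrom_lengths > 0), G >= 0L,
            n_admixed >= 1L, recomb_rate >= 0)
  if (!(F > 0 && F < 1)) stop("F must lie in (0, 1)", call. = FALSE)
  if (!(m0 >= 0 && m0 <= 1)) stop("m0 must lie in [0, 1]", call. = FALSE)
  if (n_founders < 2L) {
    stop("n_founders must be >= 2 for random mating", call. = FALSE)
  }
  if (n_admixed > n_founders) {
    stop("n_admixed cannot exceed the deme size (n_founders)",
         call. = FALSE)
  }
  structure(list(L = as.integer(L), chrom_lengths = chrom_lengths, F = F,
                 m0 = m0, G = as.integer(G),
                 n_admixed = as.integer(n_admixed),
                 n_founders = as.integer(n_founders),
                 recomb_rate = recomb_rate, seed = seed),
            class = "sim_config")
}

#' @rdname sim_config
#' @param ... overrides passed on to [sim_config()].
#' @export
chbjpt_config <- function(...) {
  args <- list(...)
  defaults <- list(F = 0.015, m0 = 0.72)
  do.call(sim_config, utils::modifyList(defaults, args))
}

#' Generate ancestral allele frequencies under the Balding-Nichols model
#'
#' Each marker receives an ancestral frequency `p ~ Uniform(0.05, 0.95)`
#' (mimicking a common-variant filter), and each of the two population
#' frequencies is drawn independently from
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)`, so that `F` controls the
#' expected differentiation. Marker positions are uniform over the genome
#' defined by `chrom_lengths` and sorted by (chromosome, position).
#'
#' @param config a [sim_config()].
#' @return A two-population [frequency_table()] (populations `pop1`,
#'   `pop2`) carrying `chrom_lengths` as an attribute for the simulator.
#' @export
generate_ancestral_freqs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    L <- config$L
    lens <- config$chrom_lengths
    chrom <- sample(names(lens), L, replace = TRUE,
                    prob = lens / sum(lens))
    pos <- floor(stats::runif(L, 1, lens[chrom] + 1))
    # avoid coincident positions so spacing rules stay well-defined
    while (anyDuplicated(cbind(chrom, pos))) {
      dup <- duplicated(cbind(chrom, pos))
      pos[dup] <- floor(stats::runif(sum(dup), 1, lens[chrom[dup]] + 1))
    }
    p_anc <- stats::runif(L, 0.05, 0.95)
    shape_scale <- (1 - config$F) / config$F
    p1 <- stats::rbeta(L, p_anc * shape_scale, (1 - p_anc) * shape_scale)
    p2 <- stats::rbeta(L, p_anc * shape_scale, (1 - p_anc) * shape_scale)
    ord <- order(chrom, pos, method = "radix")
    tab <- frequency_table(
      marker_id = sprintf("snp%06d", seq_len(L)),
      chrom = chrom[ord], pos = pos[ord],
      freqs = cbind(pop1 = p1[ord], pop2 = p2[ord])
    )
    attr(tab, "chrom_lengths") <- lens
    tab
  })
}

#' Sample genotypes for an ancestral population panel
#'
#' Hardy-Weinberg sampling: genotypes are Binomial(2, p) draws at each
#' marker, independent across markers and individuals.
#'
#' @param table a [frequency_table()].
#' @param pop population index or name.
#' @param n number of diploid individuals.
#' @param seed optional RNG seed.
#' @return Integer genotype matrix (individuals x markers) with sample ids
#'   as row names and marker ids as column names.
#' @export
generate_panel_genotypes <- function(table, pop = 1L, n, seed = NULL) {
  stopifnot(inherits(table, "freq_table"))
  P <- pop_freqs(table)
  if (is.character(pop)) pop <- match(pop, pop_names(table))
  stopifnot(!is.na(pop), pop >= 1L, pop <= ncol(P))
  with_seed(seed, {
    M <- nrow(P)
    g <- matrix(stats::rbinom(M * n, 2L, P[, pop]), nrow = M, ncol = n)
    g <- t(g)
    dimnames(g) <- list(sprintf("%s_ind%04d", colnames(P)[pop],
                                seq_len(n)),
                        table$marker_id)
    g
  })
}

#' Forward-time simulation of an admixed population with ancestry tracking
#'
#' Founds an admixed deme of `n_founders` diploids: each founder is drawn
#' wholly from ancestral population 1 with probability `m0` (otherwise
#' population 2), with both haplotypes sampled per-locus from that
#' population's allele frequencies. The deme then mates randomly
#' (monoecious, non-overlapping generations, constant size, two distinct
#' parents per offspring, no selection or mutation) for `G` generations.
#' Meioses recombine with crossover counts Poisson(`recomb_rate` x
#' chromosome length in bp) per chromosome (Haldane model) and uniform
#' crossover positions; chromosomes assort independently.
#'
#' Every allele copy carries an ancestry label propagated through meiosis,
#' and an individual's true ancestry `q_i` is the fraction of its `2L`
#' allele copies labelled population 1 (marker-weighted, exactly the
#' quantity the genotype-based estimator targets).
#'
#' @param table a two-population [frequency_table()], typically from
#'   [generate_ancestral_freqs()]. Chromosome lengths are taken from its
#'   `chrom_lengths` attribute when present, otherwise from the largest
#'   observed position per chromosome.
#' @param config a [sim_config()]; its `seed` makes the run deterministic.
#' @param keep_labels also return the per-locus ancestry indicator matrices
#'   (haploid, markers x individuals); heavy, off by default.
#' @return List of class `"admix_sim"`: `genotypes` (individuals x markers,
#'   0/1/2 copies of the reference allele), `truth` (`data.frame` with
#'   `sample_id`, `q_true`), `config`, and optionally `labels`.
#' @export
simulate_admixed <- function(table, config, keep_labels = FALSE) {
  stopifnot(inherits(table, "freq_table"), inherits(config, "sim_config"))
  P <- pop_freqs(table)
  if (ncol(P) != 2L) stop("need exactly two ancestral populations",
                          call. = FALSE)
  if (anyNA(table$pos)) stop("markers must have map positions",
                             call. = FALSE)
  M <- nrow(table)
  chroms <- unique(table$chrom)
  chr_idx <- lapply(chroms, function(ch) which(table$chrom == ch))
  chr_pos <- lapply(chr_idx, function(ix) table$pos[ix])
  lens <- attr(table, "chrom_lengths")
  chr_len <- if (!is.null(lens) && all(chroms %in% names(lens))) {
    unname(lens[chroms])
  } else {
    vapply(chr_pos, max, numeric(1))
  }
  lambda <- chr_len * config$recomb_rate # expected crossovers (Morgans)

  with_seed(config$seed, {
    n <- config$n_founders
    founder_pop1 <- stats::runif(n) < config$m0
    Pf <- P[, ifelse(founder_pop1, 1L, 2L), drop = FALSE] # M x n
    A1 <- matrix(stats::rbinom(M * n, 1L, Pf), M, n)
    A2 <- matrix(stats::rbinom(M * n, 1L, Pf), M, n)
    Z1 <- matrix(rep(founder_pop1, each = M), M, n)
    Z2 <- Z1

    gamete <- function(a1, a2, z1, z2) {
      a <- a1; z <- z1
      for (c in seq_along(chr_idx)) {
        idx <- chr_idx[[c]]
        nco <- stats::rpois(1L, lambda[c])
        if (nco == 0L) {
          if (stats::runif(1L) < 0.5) {
            a[idx] <- a2[idx]; z[idx] <- z2[idx]
          }
        } else {
          bp <- sort(stats::runif(nco, 0, chr_len[c]))
          seg <- findInterval(chr_pos[[c]], bp)
          take2 <- (seg + (stats::runif(1L) < 0.5)) %% 2L == 1L
          sel <- idx[take2]
          a[sel] <- a2[sel]; z[sel] <- z2[sel]
        }
      }
      list(a = a, z = z)
    }

    for (gen in seq_len(config$G)) {
      nA1 <- A1; nA2 <- A2; nZ1 <- Z1; nZ2 <- Z2
      for (k in seq_len(n)) {
        par <- sample.int(n, 2L) # two distinct parents
        g1 <- gamete(A1[, par[1L]], A2[, par[1L]],
                     Z1[, par[1L]], Z2[, par[1L]])
        g2 <- gamete(A1[, par[2L]], A2[, par[2L]],
                     Z1[, par[2L]], Z2[, par[2L]])
        nA1[, k] <- g1$a; nZ1[, k] <- g1$z
        nA2[, k] <- g2$a; nZ2[, k] <- g2$z
      }
      A1 <- nA1; A2 <- nA2; Z1 <- nZ1; Z2 <- nZ2
    }

    pick <- sample.int(n, config$n_admixed)
    ids <- sprintf("adm_ind%04d", seq_len(config$n_admixed))
    geno <- t(A1[, pick, drop = FALSE] + A2[, pick, drop = FALSE])
    dimnames(geno) <- list(ids, table$marker_id)
    q_true <- (colSums(Z1[, pick, drop = FALSE]) +
                 colSums(Z2[, pick, drop = FALSE])) / (2 * M)
    out <- list(genotypes = geno,
                truth = data.frame(sample_id = ids, q_true = q_true,
                                   stringsAsFactors = FALSE),
                config = config)
    if (keep_labels) {
      out$labels <- list(hap1 = Z1[, pick, drop = FALSE],
                         hap2 = Z2[, pick, drop = FALSE])
    }
    structure(out, class = "admix_sim")
  })
}

#' @export
print.admix_sim <- function(x, ...) {
  cat(sprintf(
    paste0("Simulated admixed population: %d individuals x %d markers\n",
           "  m0 = %g, G = %d generations; realized mean q_true = %.4f\n"),
    nrow(x$genotypes), ncol(x$genotypes), x$config$m0, x$config$G,
    mean(x$truth$q_true)))
  invisible(x)
}
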