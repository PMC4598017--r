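#' Observed and expected heterozygosity per population
#'
#' `H_o` is the mean over loci of the fraction of heterozygous individuals;
#' `H_e` is the mean over loci of the unbiased gene diversity
#' `(2n / (2n - 1)) * (1 - sum(p_i^2))` (small-sample corrected, appropriate
#' for the modest per-region samples these surveys produce). Missing
#' genotypes are dropped per locus.
#'
#' @param x an [msat_genotypes()] table.
#' @param population optional single population; defaults to all.
#' @return data frame with columns `population`, `Ho`, `He`.
#' @export
heterozygosity <- function(x, population = NULL) {
  stopifnot(inherits(x, "msat_geno"))
  pops <- if (is.null(population)) unique(x$population) else population
  if (!all(pops %in% x$population)) {
    stop("population(s) not in table: ", paste(setdiff(pops, x$population), collapse = ", "))
  }
  loci <- attr(x, "loci")
  out <- lapply(pops, function(p) {
    rows <- x$population == p
    ho <- he <- numeric(0)
    for (l in loci) {
      g <- locus_pairs(x, l)[rows, , drop = FALSE]
      g <- g[stats::complete.cases(g), , drop = FALSE]
      n <- nrow(g)
      if (n < 1) next
      ho <- c(ho, mean(g[, 1] != g[, 2]))
      cnt <- table(c(g[, 1], g[, 2]))
      pfrac <- cnt / sum(cnt)
      he <- c(he, (2 * n / (2 * n - 1)) * (1 - sum(pfrac^2)))
    }
    if (!length(ho)) stop(sprintf("population %s has no genotyped locus", p))
    data.frame(population = p, Ho = mean(ho), He = mean(he),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies, `sum_i [1 - C(N - N_i, g) / C(N, g)]`, averaged over loci
#' (hypergeometric rarefaction, correcting richness for unequal sample
#' sizes).
#'
#' @param x an [msat_genotypes()] table.
#' @param g rarefaction size in gene copies; default: the smallest number of
#'   non-missing gene copies over all population-locus combinations.
#' @return data frame with columns `population`, `Ar`; attribute `g`.
#' @export
rarefied_allelic_richness <- function(x, g = NULL) {
  stopifnot(inherits(x, "msat_geno"))
  loci <- attr(x, "loci")
  pops <- unique(x$population)
  copies <- function(p, l) {
    gm <- locus_pairs(x, l)[x$population == p, , drop = FALSE]
    a <- c(gm[, 1], gm[, 2])
    a[!is.na(a)]
  }
  if (is.null(g)) {
    g <- min(vapply(pops, function(p) {
      min(vapply(loci, function(l) length(copies(p, l)), integer(1)))
    }, integer(1)))
  }
  g <- as.integer(g)
  if (g < 1) stop("g must be >= 1")
  out <- lapply(pops, function(p) {
    ar <- vapply(loci, function(l) {
      a <- copies(p, l)
      N <- length(a)
      if (g > N) {
        stop(sprintf("g = %d exceeds the %d gene copies at %s / %s", g, N, p, l))
      }
      Ni <- as.integer(table(a))
      sum(1 - exp(lchoose(N - Ni, g) - lchoose(N, g)))
    }, numeric(1))
    data.frame(population = p, Ar = mean(ar), stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out), g = g)
}

#' Nucleotide diversity from haplotype frequencies
#'
#' `pi = (n / (n - 1)) * sum_{i<j} 2 f_i f_j d_ij` where `f` are haplotype
#' frequencies from carrier counts, `d_ij` the per-site proportion of
#' differing positions between haplotypes, and `n` the total count.
#'
#' @param seqs named character vector of equal-length haplotype sequences.
#' @param counts named numeric vector of carrier counts (names resolve into
#'   `seqs`); or a populations x haplotypes count matrix for a per-population
#'   result.
#' @return a single value, or a data frame `population`, `pi` for matrix
#'   input.
#' @export
nucleotide_diversity <- function(seqs, counts) {
  if (length(unique(nchar(seqs))) != 1) stop("sequences must have equal length")
  if (is.matrix(counts)) {
    out <- lapply(rownames(counts), function(p) {
      data.frame(population = p, pi = nucleotide_diversity(seqs, counts[p, ]),
                 stringsAsFactors = FALSE)
    })
    return(do.call(rbind, out))
  }
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("need at least 2 gene copies")
  if (length(counts) < 2) return(0)
  use <- seqs[names(counts)]
  if (anyNA(use)) stop("counts name haplotypes absent from seqs")
  len <- nchar(use[1])
  f <- counts / n
  tot <- 0
  for (i in seq_along(use)[-length(use)]) {
    for (j in (i + 1):length(use)) {
      tot <- tot + 2 * f[i] * f[j] * hamming(use[i], use[j]) / len
    }
  }
  unname((n / (n - 1)) * tot)
}

#' Jukes-Cantor corrected nucleotide distance
#'
#' `d = -(3/4) log(1 - (4/3) p)` with `p` the proportion of mismatching
#' sites; the one-parameter substitution model appropriate for closely
#' related amplicon alleles.
#'
#' @param a,b equal-length ACGT sequences; if `b` is `NULL`, `a` must be a
#'   vector of sequences and the full pairwise distance matrix is returned.
#' @return distance in substitutions per site (scalar or matrix).
#' @export
jc69_distance <- function(a, b = NULL) {
  if (is.null(b)) {
    n <- length(a)
    d <- matrix(0, n, n, dimnames = list(names(a), names(a)))
    if (n > 1) {
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- jc69_distance(a[[i]], a[[j]])
      }
    }
    return(d)
  }
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  if (grepl("[^ACGT]", a) || grepl("[^ACGT]", b)) stop("sequences must be ACGT only")
  p <- hamming(a, b) / nchar(a)
  if (p >= 0.75) stop(sprintf("mismatch proportion %.3f is saturated under JC69", p))
  -0.75 * log(1 - 4 * p / 3)
}

# ---- AMOVA ------------------------------------------------------------

# One-level AMOVA variance decomposition from a squared-distance matrix and
# a grouping factor (Excoffier sums of squares).
amova_core <- function(D2, groups) {
  groups <- as.factor(as.character(groups))
  N <- nrow(D2)
  k <- nlevels(groups)
  n_g <- as.vector(table(groups))
  ss_total <- sum(D2) / (2 * N)
  ss_within <- 0
  for (l in levels(groups)) {
    idx <- which(groups == l)
    ss_within <- ss_within + sum(D2[idx, idx]) / (2 * length(idx))
  }
  ss_among <- ss_total - ss_within
  df_among <- k - 1
  df_within <- N - k
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  n_prime <- (N - sum(n_g^2) / N) / (k - 1)
  sigma_within <- ms_within
  sigma_among <- (ms_among - ms_within) / n_prime
  tot <- sigma_among + sigma_within
  # no molecular variance at all (all units identical): no differentiation
  phi <- if (tot == 0) 0 else sigma_among / tot
  list(ss = c(among = ss_among, within = ss_within, total = ss_total),
       df = c(among = df_among, within = df_within),
       sigma = c(among = sigma_among, within = sigma_within),
       pct_among = 100 * phi,
       phi_st = phi, n = N, k = k)
}

amova_result <- function(core, p, n_perm, statistic) {
  structure(c(core, list(p_value = p, n_perm = n_perm, statistic = statistic)),
            class = "amova")
}

#' Analysis of molecular variance (one level)
#'
#' Partitions squared genetic distances among sampled units into among- and
#' within-population variance components; `Phi_ST` is the among-population
#' fraction. Significance is assessed by shuffling units among populations,
#' with `(b + 1) / (m + 1)` smoothing of the one-sided p-value.
#'
#' Methods:
#' \itemize{
#'   \item `mhc_geno`: units are allele carriages (each individual
#'     contributes one unit per allele carried, so haplotype frequencies are
#'     reflected), with Jukes-Cantor distances between allele sequences.
#'   \item `msat_geno`: units are gene copies with 0/1 allele-identity
#'     distance; sums of squares and variance components are accumulated
#'     over loci and permutations shuffle whole individuals.
#'   \item default: any distance matrix (e.g. the Jaccard distances of a
#'     binary encoding) plus a grouping vector.
#' }
#'
#' @param x data object (see methods).
#' @param ... passed between methods.
#' @return object of class `amova`: sums of squares, degrees of freedom,
#'   variance components, `pct_among`, `phi_st`, `p_value`, `n_perm`.
#' @export
amova <- function(x, ...) UseMethod("amova")

#' @rdname amova
#' @param d distances (matrix or `dist`) between units (default method).
#' @param groups grouping vector aligned with the rows of `d`.
#' @param n_perm number of permutations (0 skips the test).
#' @param seed RNG seed for the permutation test.
#' @export
amova.default <- function(x, groups = NULL, n_perm = 10000, seed = NULL,
                          d = NULL, ...) {
  D <- as.matrix(d %||% x)
  groups <- as.factor(as.character(groups))
  if (length(groups) != nrow(D)) stop("groups must match the distance matrix")
  n_g <- table(groups)
  if (nlevels(groups) < 2) stop("need at least 2 populations")
  if (any(n_g < 2)) {
    stop("population(s) of size 1: ", paste(names(n_g)[n_g < 2], collapse = ", "))
  }
  D2 <- D^2
  obs <- amova_core(D2, groups)
  p <- NA_real_
  if (n_perm > 0) {
    phi_perm <- with_seed(seed %||% 1L, {
      vapply(seq_len(n_perm), function(b) {
        amova_core(D2, sample(groups))$phi_st
      }, numeric(1))
    })
    p <- (sum(phi_perm >= obs$phi_st) + 1) / (n_perm + 1)
  }
  amova_result(obs, p, n_perm, "phi_st (distance units)")
}

#' @rdname amova
#' @param allele_seqs named character vector of allele sequences (for the
#'   `mhc_geno` method); defaults to JC69 distances between them.
#' @export
amova.mhc_geno <- function(x, allele_seqs, n_perm = 10000, seed = NULL, ...) {
  u <- mhc_carriage_units(x, allele_seqs)
  amova.default(u$D, groups = u$pop, n_perm = n_perm, seed = seed)
}

# Expand an MHC table into allele-carriage units with a JC69 distance matrix.
mhc_carriage_units <- function(x, allele_seqs) {
  ids <- unique(unlist(x$alleles))
  missing <- setdiff(ids, names(allele_seqs))
  if (length(missing)) {
    stop("allele sequences missing for: ", paste(missing, collapse = ", "))
  }
  d_allele <- jc69_distance(allele_seqs[ids])
  unit_allele <- unlist(x$alleles)
  unit_pop <- rep(x$population, lengths(x$alleles))
  D <- d_allele[unit_allele, unit_allele]
  list(D = D, pop = unit_pop, allele = unit_allele)
}

#' @rdname amova
#' @export
amova.msat_geno <- function(x, n_perm = 10000, seed = NULL, ...) {
  obs <- msat_amova_core(x, x$population)
  p <- NA_real_
  if (n_perm > 0) {
    phi_perm <- with_seed(seed %||% 1L, {
      vapply(seq_len(n_perm), function(b) {
        msat_amova_core(x, sample(x$population))$phi_st
      }, numeric(1))
    })
    p <- (sum(phi_perm >= obs$phi_st) + 1) / (n_perm + 1)
  }
  amova_result(obs, p, n_perm, "fst (allele identity, multilocus)")
}

# Multilocus AMOVA over gene copies with 0/1 allele-identity distance,
# computed from allele counts (algebraically identical to the explicit
# squared-distance decomposition, see tests). Components are summed over
# loci; permutations relabel whole individuals.
msat_amova_core <- function(x, pop) {
  loci <- attr(x, "loci")
  pop <- as.character(pop)
  pops <- unique(pop)
  if (length(pops) < 2) stop("need at least 2 populations")
  sig_a <- sig_w <- 0
  ss_a <- ss_w <- ss_t <- 0
  df_a <- df_w <- 0
  for (l in loci) {
    g <- locus_pairs(x, l)
    keep <- stats::complete.cases(g)
    a <- c(g[keep, 1], g[keep, 2])
    p_of_copy <- rep(pop[keep], 2)
    N <- length(a)
    k <- length(unique(p_of_copy))
    if (k < 2 || N < 4) next
    cnt_tot <- table(a)
    sst <- (N^2 - sum(cnt_tot^2)) / (2 * N)
    ssw <- 0
    n_g <- numeric(0)
    for (pp in unique(p_of_copy)) {
      ai <- a[p_of_copy == pp]
      n_g <- c(n_g, length(ai))
      cnt <- table(ai)
      ssw <- ssw + (length(ai)^2 - sum(cnt^2)) / (2 * length(ai))
    }
    ssa <- sst - ssw
    dfa <- k - 1
    dfw <- N - k
    msa <- ssa / dfa
    msw <- ssw / dfw
    n_prime <- (N - sum(n_g^2) / N) / dfa
    sig_w_l <- msw
    sig_a_l <- (msa - msw) / n_prime
    sig_a <- sig_a + sig_a_l
    sig_w <- sig_w + sig_w_l
    ss_a <- ss_a + ssa; ss_w <- ss_w + ssw; ss_t <- ss_t + sst
    df_a <- df_a + dfa; df_w <- df_w + dfw
  }
  if (df_a == 0) stop("no informative locus for AMOVA")
  phi <- if (sig_a + sig_w == 0) 0 else sig_a / (sig_a + sig_w)
  list(ss = c(among = ss_a, within = ss_w, total = ss_t),
       df = c(among = df_a, within = df_w),
       sigma = c(among = sig_a, within = sig_w),
       pct_among = 100 * phi,
       phi_st = phi, n = nrow(x), k = length(pops))
}

#' @export
print.amova <- function(x, ...) {
  cat("AMOVA (", x$statistic, ")\n", sep = "")
  cat(sprintf("  variance among populations:  %.5f (%.2f%%)\n",
              x$sigma["among"], x$pct_among))
  cat(sprintf("  variance within populations: %.5f\n", x$sigma["within"]))
  cat(sprintf("  Phi_ST = %.4f", x$phi_st))
  if (!is.na(x$p_value)) cat(sprintf(", p = %.4g (%d permutations)", x$p_value, x$n_perm))
  cat("\n")
  invisible(x)
}

#' Pairwise population differentiation
#'
#' Each off-diagonal cell is the two-population statistic restricted to that
#' pair — an [amova()] `Phi_ST`/`F_ST`, or [jost_dest()] — with its own
#' one-sided permutation p-value.
#'
#' @param x an `mhc_geno` or `msat_geno` table.
#' @param statistic `"phist"` (MHC sequence AMOVA), `"fst"` (microsatellite
#'   allele-identity AMOVA) or `"dest"`.
#' @param allele_seqs allele sequences (required for `phist`).
#' @param n_perm permutations per pair (0 skips p-values; `dest` reports no
#'   permutation test).
#' @param seed RNG seed.
#' @return list of class `pairwise_diff`: `populations`, `stat` (symmetric
#'   matrix, zero diagonal), `p` (diagonal 1), `statistic`, `n_perm`.
#' @export
pairwise_differentiation <- function(x, statistic = c("phist", "fst", "dest"),
                                     allele_seqs = NULL, n_perm = 1000,
                                     seed = NULL) {
  statistic <- match.arg(statistic)
  pops <- unique(x$population)
  k <- length(pops)
  if (k < 2) stop("need at least 2 populations")
  stat <- matrix(0, k, k, dimnames = list(pops, pops))
  pmat <- matrix(1, k, k, dimnames = list(pops, pops))
  seed <- seed %||% 1L

  prep <- NULL
  if (statistic == "phist") {
    if (is.null(allele_seqs)) stop("allele_seqs required for phist")
    prep <- mhc_carriage_units(x, allele_seqs)
    prep$D2 <- prep$D^2
  }

  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    pi_ <- pops[i]; pj <- pops[j]
    pair_seed <- derive_seed(seed, paste0("pair", i, "_", j))
    if (statistic == "phist") {
      idx <- which(prep$pop %in% c(pi_, pj))
      D2 <- prep$D2[idx, idx]
      g <- factor(prep$pop[idx])
      obs <- amova_core(D2, g)
      stat[i, j] <- stat[j, i] <- obs$phi_st
      if (n_perm > 0) {
        perm <- with_seed(pair_seed, {
          vapply(seq_len(n_perm), function(b) amova_core(D2, sample(g))$phi_st,
                 numeric(1))
        })
        pmat[i, j] <- pmat[j, i] <- (sum(perm >= obs$phi_st) + 1) / (n_perm + 1)
      }
    } else if (statistic == "fst") {
      sub <- x[x$population %in% c(pi_, pj), , drop = FALSE]
      attr(sub, "loci") <- attr(x, "loci")
      class(sub) <- class(x)
      obs <- msat_amova_core(sub, sub$population)
      stat[i, j] <- stat[j, i] <- obs$phi_st
      if (n_perm > 0) {
        perm <- with_seed(pair_seed, {
          vapply(seq_len(n_perm), function(b) {
            msat_amova_core(sub, sample(sub$population))$phi_st
          }, numeric(1))
        })
        pmat[i, j] <- pmat[j, i] <- (sum(perm >= obs$phi_st) + 1) / (n_perm + 1)
      }
    } else {
      cnt <- marker_allele_counts(x)
      stat[i, j] <- stat[j, i] <- if (is.list(cnt)) {
        mean(vapply(cnt, function(m) jost_dest(m[c(pi_, pj), , drop = FALSE]),
                    numeric(1)))
      } else {
        jost_dest(cnt[c(pi_, pj), , drop = FALSE])
      }
      pmat[i, j] <- pmat[j, i] <- NA_real_
    }
  }
  structure(list(populations = pops, stat = stat, p = pmat,
                 statistic = statistic, n_perm = n_perm),
            class = "pairwise_diff")
}

#' @export
print.pairwise_diff <- function(x, digits = 3, ...) {
  cat(sprintf("Pairwise %s over %d populations (%d permutations)\n",
              x$statistic, length(x$populations), x$n_perm))
  print(round(x$stat, digits))
  invisible(x)
}

# Per-population allele counts: matrix for mhc_geno (carrier counts), list
# of per-locus gene-copy count matrices for msat_geno.
marker_allele_counts <- function(x) {
  pops <- unique(x$population)
  if (inherits(x, "mhc_geno")) {
    ids <- sort(unique(unlist(x$alleles)))
    m <- matrix(0L, length(pops), length(ids), dimnames = list(pops, ids))
    for (i in seq_len(nrow(x))) {
      m[x$population[i], x$alleles[[i]]] <- m[x$population[i], x$alleles[[i]]] + 1L
    }
    m
  } else if (inherits(x, "msat_geno")) {
    loci <- attr(x, "loci")
    out <- lapply(loci, function(l) {
      g <- locus_pairs(x, l)
      keep <- stats::complete.cases(g)
      a <- c(g[keep, 1], g[keep, 2])
      p <- rep(x$population[keep], 2)
      labs <- sort(unique(a))
      m <- matrix(0L, length(pops), length(labs),
                  dimnames = list(pops, as.character(labs)))
      t <- table(p, a)
      m[rownames(t), colnames(t)] <- as.integer(t)
      m
    })
    names(out) <- loci
    out
  } else stop("unsupported table type")
}

#' Jost's D differentiation estimator
#'
#' `D_EST = (k / (k - 1)) * (H_T - H_S) / (1 - H_S)` over `k` populations,
#' with the nearly unbiased heterozygosity estimators: each population's
#' `sum(p^2)` is replaced by `sum(n_i (n_i - 1)) / (n (n - 1))`, and `H_T`
#' uses the unweighted mean of population frequencies. Unlike fixation
#' indices, `D` partitions diversity into independent within- and
#' between-population components, which matters when within-population
#' diversity is high.
#'
#' @param counts populations x alleles count matrix (rows = populations).
#' @return scalar estimate (can be slightly negative in the undifferentiated
#'   case; exactly 1 for fixed differences).
#' @export
jost_dest <- function(counts) {
  counts <- as.matrix(counts)
  k <- nrow(counts)
  if (k < 2) stop("need at least 2 populations")
  n <- rowSums(counts)
  if (any(n < 2)) stop("every population needs at least 2 gene copies")
  sum_p2 <- vapply(seq_len(k), function(i) {
    sum(counts[i, ] * (counts[i, ] - 1)) / (n[i] * (n[i] - 1))
  }, numeric(1))
  H_S <- mean(1 - sum_p2)
  pbar <- colMeans(sweep(counts, 1, n, "/"))
  H_T <- 1 - sum(pbar^2)
  if (abs(1 - H_S) < 1e-12) stop("within-population heterozygosity is 1; D undefined")
  (k / (k - 1)) * (H_T - H_S) / (1 - H_S)
}

#' MHC-like genotype diversity
#'
#' Two individuals share an MHC-like genotype iff their allele *sets* are
#' equal; the set is the natural genotype unit when alleles cannot be
#' ascribed to loci. `GT` counts distinct sets per population and `P_GT`
#' those private to a single population.
#'
#' @param x an [mhc_genotypes()] table.
#' @return list: `per_population` (data frame `population`, `GT`, `P_GT`),
#'   `global_unique` (distinct sets in the whole data set).
#' @export
mhc_genotype_diversity <- function(x) {
  stopifnot(inherits(x, "mhc_geno"))
  if (nrow(x) == 0) stop("empty genotype table")
  key <- vapply(x$alleles, paste, "", collapse = ";")
  pops <- unique(x$population)
  pop_of_key <- split(x$population, key)
  n_pops_of_key <- vapply(pop_of_key, function(p) length(unique(p)), integer(1))
  per_pop <- lapply(pops, function(p) {
    keys_p <- unique(key[x$population == p])
    data.frame(population = p, GT = length(keys_p),
               P_GT = sum(n_pops_of_key[keys_p] == 1),
               stringsAsFactors = FALSE)
  })
  list(per_population = do.call(rbind, per_pop),
       global_unique = length(unique(key)))
}

#' Individual allele-diversity index
#'
#' The number of alleles an individual carries divided by the maximum number
#' of alleles observed within any individual in the whole data set. With a
#' data-set maximum of 5 the index ranges from 0.4 (2 alleles) to 1
#' (5 alleles), making within-individual diversity comparable across
#' populations.
#'
#' @param x an [mhc_genotypes()] table.
#' @return list: `individual` (data frame `individual`, `population`, `A`),
#'   `population` (mean `A` per population), `max_alleles`.
#' @export
allele_diversity_index <- function(x) {
  stopifnot(inherits(x, "mhc_geno"))
  if (nrow(x) == 0) stop("empty genotype table")
  mx <- max(lengths(x$alleles))
  ind <- data.frame(individual = x$individual, population = x$population,
                    A = lengths(x$alleles) / mx, stringsAsFactors = FALSE)
  pop <- stats::aggregate(A ~ population, data = ind, FUN = mean)
  list(individual = ind, population = pop, max_alleles = mx)
}

#' Binary (dominant) encoding of both marker classes
#'
#' Each allele becomes a separate dominant 0/1 locus: a cell is 1 iff the
#' individual carries at least one copy (homozygotes collapse to a single
#' presence). Only individuals present in both tables are encoded; column
#' order is deterministic (locus, then allele label).
#'
#' @param mhc an [mhc_genotypes()] table.
#' @param msat an [msat_genotypes()] table.
#' @return list of class `binary_encoding`: `mhc` and `msat` 0/1 matrices
#'   over the same individuals (rownames), `individuals`, `populations`,
#'   `dropped` (ids absent from one table).
#' @export
binary_encode <- function(mhc, msat) {
  stopifnot(inherits(mhc, "mhc_geno"), inherits(msat, "msat_geno"))
  ids <- intersect(mhc$individual, msat$individual)
  if (length(ids) == 0) stop("the two tables share no individuals")
  dropped <- setdiff(union(mhc$individual, msat$individual), ids)

  mhc_sub <- mhc[match(ids, mhc$individual), ]
  alleles <- sort(unique(unlist(mhc_sub$alleles)))
  M <- matrix(0L, length(ids), length(alleles), dimnames = list(ids, alleles))
  for (i in seq_along(ids)) M[i, mhc_sub$alleles[[i]]] <- 1L

  msat_sub <- msat[match(ids, msat$individual), ]
  loci <- attr(msat, "loci")
  cols <- list()
  for (l in loci) {
    g <- locus_pairs(msat_sub, l)
    labs <- sort(unique(c(g[, 1], g[, 2])))
    labs <- labs[!is.na(labs)]
    for (al in labs) {
      cols[[paste0(l, "_", al)]] <-
        as.integer(!is.na(g[, 1]) & (g[, 1] == al | g[, 2] == al))
    }
  }
  S <- do.call(cbind, cols)
  rownames(S) <- ids

  structure(list(mhc = M, msat = S, individuals = ids,
                 populations = stats::setNames(mhc_sub$population, ids),
                 dropped = dropped),
            class = "binary_encoding")
}

#' Relative MHC allele frequencies per population
#'
#' Numerator: number of individuals in the population carrying the allele;
#' denominator: total allele carriage in the population (the sum of
#' within-individual set sizes). Frequencies therefore sum to 1 within a
#' population (no individual can carry a duplicate allele in a set).
#'
#' @param x an [mhc_genotypes()] table.
#' @return populations x alleles matrix of frequencies.
#' @export
relative_allele_frequencies <- function(x) {
  stopifnot(inherits(x, "mhc_geno"))
  cnt <- marker_allele_counts(x)
  carriage <- vapply(rownames(cnt), function(p) {
    sum(lengths(x$alleles[x$population == p]))
  }, numeric(1))
  sweep(cnt, 1, carriage, "/")
}

#' Per-population diversity report for both marker classes
#'
#' Assembles the standard survey table: sample size, microsatellite `Ho`,
#' `He` and rarefied allelic richness `Ar`, and for the MHC the number of
#' distinct alleles `H`, nucleotide diversity `pi`, MHC-like genotype counts
#' `GT` and `P_GT`, and the mean individual allele-diversity index `A`.
#'
#' @param mhc an [mhc_genotypes()] table.
#' @param msat an [msat_genotypes()] table.
#' @param allele_seqs named allele sequences for `pi`.
#' @param g rarefaction size (see [rarefied_allelic_richness()]).
#' @return data frame, one row per population.
#' @export
diversity_report <- function(mhc, msat, allele_seqs, g = NULL) {
  het <- heterozygosity(msat)
  ar <- rarefied_allelic_richness(msat, g = g)
  gt <- mhc_genotype_diversity(mhc)$per_population
  ai <- allele_diversity_index(mhc)$population
  cnt <- marker_allele_counts(mhc)
  pops <- unique(mhc$population)
  out <- data.frame(
    population = pops,
    n = as.integer(table(mhc$population)[pops]),
    Ho = het$Ho[match(pops, het$population)],
    He = het$He[match(pops, het$population)],
    Ar = ar$Ar[match(pops, ar$population)],
    H = apply(cnt[pops, , drop = FALSE] > 0, 1, sum),
    pi = vapply(pops, function(p) nucleotide_diversity(allele_seqs, cnt[p, ]),
                numeric(1)),
    GT = gt$GT[match(pops, gt$population)],
    P_GT = gt$P_GT[match(pops, gt$population)],
    A = ai$A[match(pops, ai$population)],
    row.names = NULL, stringsAsFactors = FALSE
  )
  out
}
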