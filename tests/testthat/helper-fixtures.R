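# Shared fixtures, built in code.

# A small study configuration used across tests (fast to simulate).
small_config <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(samples_per_population = 10,
                   read_model = list(mean_depth = 300),
                   seed = seed)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Toy MHC table: two populations, hand-set allele sets.
toy_mhc <- function() {
  mhc_genotypes(
    individual = c("i1", "i2", "i3", "i4", "i5", "i6"),
    population = c("X", "X", "X", "Y", "Y", "Y"),
    alleles = list(c("a", "b"), c("a", "b"), c("a", "c"),
                   c("b", "c"), c("c", "d"), c("a", "b", "c", "d", "e"))
  )
}

# Toy microsatellite table: two loci, two populations.
toy_msat <- function() {
  geno <- rbind(c(100, 102, 200, 200),
                c(100, 102, 200, 202),
                c(102, 102, 202, 202),
                c(104, 104, 200, 200),
                c(104, 106, 200, 202),
                c(106, 106, 202, 202))
  colnames(geno) <- c("L1.1", "L1.2", "L2.1", "L2.2")
  msat_genotypes(paste0("i", 1:6), rep(c("X", "Y"), each = 3), geno)
}

# Direct sums-of-squares AMOVA oracle (independent of amova()).
amova_oracle <- function(D, groups) {
  D2 <- as.matrix(D)^2
  groups <- as.character(groups)
  N <- nrow(D2)
  k <- length(unique(groups))
  ss <- function(idx) {
    if (length(idx) < 2) return(0)
    sub <- D2[idx, idx]
    sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_tot <- ss(seq_len(N))
  ss_w <- sum(vapply(unique(groups), function(g) ss(which(groups == g)), numeric(1)))
  ss_a <- ss_tot - ss_w
  ms_a <- ss_a / (k - 1)
  ms_w <- ss_w / (N - k)
  n_g <- table(groups)
  n_prime <- (N - sum(n_g^2) / N) / (k - 1)
  sig_a <- (ms_a - ms_w) / n_prime
  list(sigma = c(among = sig_a, within = ms_w),
       phi = sig_a / (sig_a + ms_w))
}

# Build an mhc_calls-like named list of allele sets for concordance tests.
sets_named <- function(ids, sets) stats::setNames(sets, ids)

# Genotype columns of an msat table as a plain matrix.
locus_pairs_for_test <- function(x) {
  m <- as.matrix(as.data.frame(x)[, -(1:2)])
  storage.mode(m) <- "integer"
  unname(m)
}
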