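test_that("heterozygosity matches hand-computed unbiased gene diversity", {
  # monomorphic locus
  g <- cbind(L1.1 = rep(100L, 4), L1.2 = rep(100L, 4))
  x <- msat_genotypes(paste0("i", 1:4), rep("X", 4), g)
  h <- heterozygosity(x)
  expect_equal(h$Ho, 0)
  expect_equal(h$He, 0)

  # n = 2, both (a/b): Ho = 1, He = (4/3)(1 - 0.5) = 2/3
  g2 <- cbind(L1.1 = c(1L, 1L), L1.2 = c(2L, 2L))
  x2 <- msat_genotypes(c("i1", "i2"), c("X", "X"), g2)
  h2 <- heterozygosity(x2)
  expect_equal(h2$Ho, 1)
  expect_equal(h2$He, 2 / 3)

  # large-n limit at p = 0.5 approaches 0.5
  n <- 500
  g3 <- cbind(L1.1 = rep(1L, n), L1.2 = rep(2L, n))
  x3 <- msat_genotypes(paste0("i", 1:n), rep("X", n), g3)
  expect_equal(heterozygosity(x3)$He, 0.5, tolerance = 2e-3)

  expect_error(heterozygosity(toy_msat(), "Z"), "not in table")
})

test_that("rarefied allelic richness equals the exhaustive subsample oracle", {
  # counts (3, 1), g = 2: 1 + (1 - C(3,2)/C(4,2)) = 1.5
  g <- cbind(L1.1 = c(1L, 1L), L1.2 = c(1L, 2L))
  x <- msat_genotypes(c("i1", "i2"), c("X", "X"), g)
  expect_equal(rarefied_allelic_richness(x, g = 2)$Ar, 1.5)

  # exhaustive enumeration oracle for N <= 8 gene copies
  rarefy_oracle <- function(copies, g) {
    subs <- utils::combn(length(copies), g)
    mean(apply(subs, 2, function(idx) length(unique(copies[idx]))))
  }
  set.seed(42)
  for (rep in 1:5) {
    copies <- sample(1:4, 8, replace = TRUE)
    gm <- cbind(L1.1 = copies[1:4], L1.2 = copies[5:8])
    xr <- msat_genotypes(paste0("i", 1:4), rep("X", 4), gm)
    for (gg in 2:8) {
      expect_equal(rarefied_allelic_richness(xr, g = gg)$Ar,
                   rarefy_oracle(copies, gg), tolerance = 1e-10)
    }
    # monotone in g; equals observed count at g = N
    ar <- vapply(1:8, function(gg) rarefied_allelic_richness(xr, g = gg)$Ar,
                 numeric(1))
    expect_true(all(diff(ar) >= -1e-12))
    expect_equal(ar[8], length(unique(copies)))
  }

  # monomorphic locus: Ar = 1 for any g
  gm <- cbind(L1.1 = rep(9L, 3), L1.2 = rep(9L, 3))
  xm <- msat_genotypes(paste0("i", 1:3), rep("X", 3), gm)
  expect_equal(rarefied_allelic_richness(xm, g = 4)$Ar, 1)

  expect_error(rarefied_allelic_richness(xm, g = 7), "exceeds")
})

test_that("nucleotide diversity follows the frequency-weighted formula", {
  seqs <- c(h1 = strrep("A", 185),
            h2 = paste0(strrep("A", 184), "C"))
  expect_equal(nucleotide_diversity(seqs, c(h1 = 5)), 0)
  # two haplotypes differing at 1/185 sites, counts (1,1):
  # (2/1) * 2 * 0.5 * 0.5 * (1/185) = 1/185
  expect_equal(nucleotide_diversity(seqs, c(h1 = 1, h2 = 1)), 1 / 185)
  # doubling counts changes pi only through n/(n-1)
  pi2 <- nucleotide_diversity(seqs, c(h1 = 2, h2 = 2))
  raw <- 2 * 0.5 * 0.5 * (1 / 185)
  expect_equal(pi2, (4 / 3) * raw)
  expect_error(nucleotide_diversity(c(a = "AA", b = "AAA"), c(a = 1, b = 1)),
               "equal length")
})

test_that("JC69 distances match the closed form and flag saturation", {
  s1 <- strrep("A", 185)
  expect_equal(jc69_distance(s1, s1), 0)
  s2 <- paste0(strrep("C", 10), strrep("A", 175))
  p <- 10 / 185
  expect_equal(jc69_distance(s1, s2), -0.75 * log(1 - 4 * p / 3))
  expect_equal(jc69_distance(s1, s2), 0.0561, tolerance = 1e-3)
  s3 <- paste0(strrep("C", 139), strrep("A", 46))   # p = 0.7514
  expect_error(jc69_distance(s1, s3), "saturated")
  # matrix form is symmetric with zero diagonal
  m <- jc69_distance(c(a = s1, b = s2))
  expect_equal(m, t(m))
  expect_equal(diag(m), c(a = 0, b = 0))
})

test_that("AMOVA variance components equal the brute-force oracle", {
  set.seed(7)
  for (rep in 1:4) {
    n <- 12
    g <- sample(rep(c("a", "b", "c"), c(3, 4, 5)))
    D <- as.matrix(dist(matrix(rnorm(2 * n), n)))
    res <- amova(D, groups = g, n_perm = 0)
    orc <- amova_oracle(D, g)
    expect_equal(unname(res$sigma), unname(orc$sigma), tolerance = 1e-9)
    expect_equal(res$phi_st, unname(orc$phi), tolerance = 1e-9)
  }

  # fixed difference between two populations: Phi = 1 and significant
  D <- matrix(1, 10, 10) - diag(10)
  D[1:5, 1:5] <- 0; D[6:10, 6:10] <- 0
  res <- amova(D, groups = rep(c("X", "Y"), each = 5), n_perm = 199, seed = 5)
  expect_equal(res$phi_st, 1)
  expect_lte(res$p_value, 0.05)

  # null case: populations from identical frequencies
  nonsig <- vapply(1:10, function(s) {
    set.seed(s + 100)
    D <- as.matrix(dist(matrix(rnorm(40), 20)))
    amova(D, groups = rep(c("X", "Y"), 10), n_perm = 99, seed = s)$p_value > 0.05
  }, logical(1))
  expect_gte(mean(nonsig), 0.8)

  expect_error(amova(matrix(0, 3, 3), groups = c("a", "a", "b")), "size 1")
})

test_that("multilocus microsatellite AMOVA equals explicit gene-copy AMOVA", {
  # count-based sums of squares must agree with an explicit 0/1-distance
  # decomposition per locus
  cfg <- small_config(seed = 31, samples_per_population = 8, n_populations = 3,
                      n_microsat_loci = 3)
  truth <- simulate_genotypes(build_allele_pool(cfg), cfg)
  x <- truth$msat
  res <- amova(x, n_perm = 0)

  sig_a <- sig_w <- 0
  for (l in attr(x, "loci")) {
    gm <- as.matrix(as.data.frame(x)[, paste(l, 1:2, sep = ".")])
    a <- c(gm[, 1], gm[, 2])
    pops <- rep(x$population, 2)
    D <- outer(a, a, "!=") * 1
    orc <- amova_oracle(D, pops)
    sig_a <- sig_a + orc$sigma["among"]
    sig_w <- sig_w + orc$sigma["within"]
  }
  expect_equal(res$phi_st, unname(sig_a / (sig_a + sig_w)), tolerance = 1e-9)
})

test_that("pairwise differentiation cells equal standalone two-population runs", {
  cfg <- small_config(seed = 32, n_populations = 3, samples_per_population = 8)
  pool <- build_allele_pool(cfg)
  truth <- simulate_genotypes(pool, cfg)

  pw <- pairwise_differentiation(truth$msat, "fst", n_perm = 0)
  expect_equal(pw$stat, t(pw$stat))
  expect_equal(unname(diag(pw$stat)), rep(0, 3))
  pops <- unique(truth$msat$population)
  sub <- truth$msat[truth$msat$population %in% pops[1:2], ]
  attr(sub, "loci") <- attr(truth$msat, "loci")
  class(sub) <- class(truth$msat)
  solo <- amova(sub, n_perm = 0)
  expect_equal(pw$stat[pops[1], pops[2]], solo$phi_st, tolerance = 1e-12)

  pwh <- pairwise_differentiation(truth$mhc, "phist", allele_seqs = pool,
                                  n_perm = 0)
  subh <- truth$mhc[truth$mhc$population %in% pops[1:2], ]
  class(subh) <- class(truth$mhc)
  soloh <- amova(subh, allele_seqs = pool, n_perm = 0)
  expect_equal(pwh$stat[pops[1], pops[2]], soloh$phi_st, tolerance = 1e-12)
})

test_that("Jost's D matches hand evaluation and its boundary cases", {
  # fixed difference: D = 1
  cnt <- rbind(X = c(10, 0), Y = c(0, 10))
  expect_equal(jost_dest(cnt), 1)

  # hand oracle for counts (8,2) vs (2,8):
  # H_S = 1 - 58/90, H_T = 0.5, D = 2 * (13/90) / (58/90) = 26/58
  cnt2 <- rbind(X = c(8, 2), Y = c(2, 8))
  expect_equal(jost_dest(cnt2), 26 / 58, tolerance = 1e-12)

  # identical counts: D <= 0 (nearly unbiased estimator)
  cnt3 <- rbind(X = c(6, 4), Y = c(6, 4))
  expect_lte(jost_dest(cnt3), 0)

  expect_error(jost_dest(cnt[1, , drop = FALSE]), "at least 2")
})

test_that("MHC-like genotype diversity counts distinct and private sets", {
  x <- mhc_genotypes(
    paste0("i", 1:6),
    c("X", "X", "X", "Y", "Y", "Y"),
    list(c("a", "b"), c("a", "b"), c("a", "c"),
         c("a", "b"), c("c", "d"), c("c", "d"))
  )
  gd <- mhc_genotype_diversity(x)
  per <- gd$per_population
  expect_equal(per$GT[per$population == "X"], 2L)   # {a,b}, {a,c}
  expect_equal(per$GT[per$population == "Y"], 2L)   # {a,b}, {c,d}
  # {a,b} occurs in both populations: private to neither
  expect_equal(per$P_GT[per$population == "X"], 1L) # {a,c}
  expect_equal(per$P_GT[per$population == "Y"], 1L) # {c,d}
  expect_equal(gd$global_unique, 3L)
  expect_true(all(per$GT >= per$P_GT))

  # everyone shares one set
  x2 <- mhc_genotypes(paste0("i", 1:4), c("X", "X", "Y", "Y"),
                      replicate(4, c("a", "b"), simplify = FALSE))
  gd2 <- mhc_genotype_diversity(x2)
  expect_true(all(gd2$per_population$GT == 1L))
  expect_true(all(gd2$per_population$P_GT == 0L))
})

test_that("the allele-diversity index scales counts by the data-set maximum", {
  ad <- allele_diversity_index(toy_mhc())   # maximum is 5
  A <- stats::setNames(ad$individual$A, ad$individual$individual)
  expect_equal(unname(A["i1"]), 0.4)  # 2 alleles
  expect_equal(unname(A["i6"]), 1.0)  # 5 alleles
  x3 <- mhc_genotypes(c("a", "b"), c("X", "X"),
                      list(c("p", "q", "r"), c("p", "q", "r", "s", "t")))
  A3 <- allele_diversity_index(x3)$individual$A
  expect_equal(A3, c(0.6, 1.0))
  expect_equal(allele_diversity_index(x3)$max_alleles, 5L)
})

test_that("binary encoding collapses dosage and aligns individuals", {
  be <- binary_encode(toy_mhc(), toy_msat())
  expect_setequal(be$individuals, paste0("i", 1:6))
  # i1 carries {a, b} of the 5-allele universe: row sum 2
  expect_equal(sum(be$mhc["i1", ]), 2)
  # heterozygote 100/102 at L1: both columns set
  expect_equal(be$msat["i1", "L1_100"], 1L)
  expect_equal(be$msat["i1", "L1_102"], 1L)
  # homozygote 102/102: a single presence
  expect_equal(unname(be$msat["i3", c("L1_100", "L1_102", "L1_104", "L1_106")]),
               c(0L, 1L, 0L, 0L))

  # intersection rule
  mhc_extra <- mhc_genotypes(c(toy_mhc()$individual, "i9"),
                             c(toy_mhc()$population, "Z"),
                             c(toy_mhc()$alleles, list("a")))
  be2 <- binary_encode(mhc_extra, toy_msat())
  expect_equal(be2$dropped, "i9")
  expect_error(binary_encode(
    mhc_genotypes("zz", "X", list("a")), toy_msat()), "no individuals")
})

test_that("relative allele frequencies use carriage-count denominators", {
  x <- mhc_genotypes(c("i1", "i2"), c("X", "X"),
                     list(c("a", "b"), c("a", "c")))
  f <- relative_allele_frequencies(x)
  expect_equal(unname(f["X", "a"]), 0.5)    # 2 carriers / 4 carriages
  expect_equal(unname(f["X", "b"]), 0.25)
  expect_equal(unname(f["X", "c"]), 0.25)
  expect_equal(sum(f["X", ]), 1)

  x2 <- mhc_genotypes("i1", "X", list(c("a", "b")))
  f2 <- relative_allele_frequencies(x2)
  expect_equal(unname(f2["X", c("a", "b")]), c(0.5, 0.5))

  # allele absent from a population is 0
  x3 <- mhc_genotypes(c("i1", "i2"), c("X", "Y"), list(c("a", "b"), c("c", "d")))
  expect_equal(unname(relative_allele_frequencies(x3)["X", "c"]), 0)
})

test_that("the diversity report assembles all per-population statistics", {
  cfg <- small_config(seed = 33, n_populations = 3, samples_per_population = 8)
  pool <- build_allele_pool(cfg)
  truth <- simulate_genotypes(pool, cfg)
  rep_ <- diversity_report(truth$mhc, truth$msat, pool)
  expect_equal(nrow(rep_), 3)
  expect_true(all(rep_$Ho >= 0 & rep_$Ho <= 1))
  expect_true(all(rep_$He >= 0 & rep_$He <= 1))
  expect_true(all(rep_$A >= 0.4 - 1e-9 & rep_$A <= 1))
  expect_true(all(rep_$GT >= rep_$P_GT))
  expect_true(all(is.finite(unlist(rep_[, -1]))))
})
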