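test_that("Jaccard S3 distances match the closed form pair by pair", {
  B <- rbind(i1 = c(1, 1, 0, 0),
             i2 = c(1, 1, 0, 0),
             i3 = c(0, 0, 1, 1),
             i4 = c(1, 0, 1, 0))
  d <- jaccard_s3_distance(B)
  expect_equal(d["i1", "i2"], 0)                 # identical rows
  expect_equal(d["i1", "i3"], 1)                 # disjoint rows
  # a = 1, b = 1, c = 1 between i1 and i4: s = 1/3
  expect_equal(d["i1", "i4"], sqrt(1 - 1 / 3))

  # brute-force oracle over random binary matrices
  set.seed(9)
  for (rep in 1:3) {
    M <- matrix(rbinom(30, 1, 0.5), 6)
    M[rowSums(M) == 0, 1] <- 1
    dm <- jaccard_s3_distance(M)
    for (i in 1:5) for (j in (i + 1):6) {
      a <- sum(M[i, ] & M[j, ]); b <- sum(M[i, ] & !M[j, ])
      cc <- sum(!M[i, ] & M[j, ])
      expect_equal(dm[i, j], sqrt(1 - a / (a + b + cc)), tolerance = 1e-12)
    }
  }
  # hand case a=1, b=1, c=0: s = 0.5, d = sqrt(0.5)
  B2 <- rbind(c(1, 1), c(1, 0))
  expect_equal(jaccard_s3_distance(B2)[1, 2], sqrt(0.5))

  expect_error(jaccard_s3_distance(rbind(c(1, 0), c(0, 0))), "all-zero")
  expect_error(jaccard_s3_distance(rbind(c(2, 0), c(0, 1))), "0/1")
})

test_that("principal coordinates reproduce Euclidean geometry", {
  # planar points round-trip to 1e-8
  set.seed(4)
  pts <- matrix(rnorm(10), 5)
  D <- as.matrix(dist(pts))
  ord <- principal_coordinates(D, correction = "none")
  Dhat <- as.matrix(dist(ord$scores))
  expect_equal(unname(Dhat), unname(D), tolerance = 1e-8)
  expect_true(all(diff(ord$eigenvalues) <= 1e-9))
  expect_lte(ncol(ord$scores), 4)

  # two points at distance 1: coordinates +-0.5 on one axis
  D2 <- matrix(c(0, 1, 1, 0), 2)
  ord2 <- principal_coordinates(D2, correction = "none")
  expect_equal(unname(sort(ord2$scores[, 1])), c(-0.5, 0.5))

  # equidistant points (regular simplex): all nontrivial eigenvalues equal
  D3 <- matrix(1, 4, 4) - diag(4)
  ord3 <- principal_coordinates(D3, correction = "none")
  expect_equal(ord3$eigenvalues, rep(ord3$eigenvalues[1], 3))

  # a non-Euclidean matrix triggers a warning without correction, and
  # Lingoes correction restores embeddability
  Dn <- matrix(1, 4, 4) - diag(4)
  Dn[1, 2] <- Dn[2, 1] <- 2.2
  expect_warning(principal_coordinates(Dn, correction = "none"), "negative")
  ordc <- principal_coordinates(Dn, correction = "lingoes")
  expect_true(all(ordc$eigenvalues > -1e-9))
})

test_that("between-class analysis maximizes among-group variance", {
  # two groups separated along axis 1 only
  set.seed(11)
  X <- cbind(c(rnorm(10, -4), rnorm(10, 4)), rnorm(20, 0, 1))
  rownames(X) <- paste0("i", 1:20)
  ord <- structure(list(ids = rownames(X), scores = X,
                        eigenvalues = c(2, 1), kind = "pcoa"),
                   class = "ordination")
  groups <- rep(c("g1", "g2"), each = 10)
  bca <- between_class_analysis(ord, groups)
  # the first between-class axis aligns with the separating axis
  w <- cor(bca$scores[, 1], X %*% c(1, 0))
  expect_gte(abs(w), 0.99)
  expect_gt(bca$between_fraction, 0.8)

  # identical group centroids: zero between-class inertia
  Y <- rbind(diag(4), diag(4))
  rownames(Y) <- paste0("r", 1:8)
  ordy <- structure(list(ids = rownames(Y), scores = Y,
                         eigenvalues = rep(1, 4), kind = "pcoa"),
                    class = "ordination")
  bca0 <- between_class_analysis(ordy, rep(c("a", "b"), each = 4))
  expect_equal(bca0$between_fraction, 0)

  # permuting row order changes nothing up to sign
  idx <- sample(20)
  ordp <- structure(list(ids = rownames(X)[idx], scores = X[idx, ],
                         eigenvalues = c(2, 1), kind = "pcoa"),
                    class = "ordination")
  bcap <- between_class_analysis(ordp, groups[idx])
  expect_equal(abs(bcap$scores[rownames(X), 1]), abs(bca$scores[, 1]),
               tolerance = 1e-9)

  expect_error(between_class_analysis(ord, rep("g1", 20)), "at least 2")
})

test_that("co-inertia RV satisfies identity, rotation and scaling invariance", {
  set.seed(12)
  X <- matrix(rnorm(40 * 3), 40)
  rownames(X) <- paste0("i", 1:40)
  mk <- function(M) structure(list(ids = rownames(M), scores = M,
                                   eigenvalues = rep(1, ncol(M)), kind = "pcoa"),
                              class = "ordination")
  # identity
  ci <- coinertia(mk(X), mk(X), n_perm = 0)
  expect_equal(ci$rv, 1, tolerance = 1e-12)
  expect_equal(max(ci$vector_lengths), 0, tolerance = 1e-10)
  # orthogonal rotation and global scaling
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  ci2 <- coinertia(mk(X), mk(3.7 * X %*% Q), n_perm = 0)
  expect_equal(ci2$rv, 1, tolerance = 1e-10)
  # eigenvalue fractions sum to 1, first is largest
  Y <- matrix(rnorm(40 * 3), 40); rownames(Y) <- rownames(X)
  ci3 <- coinertia(mk(X), mk(Y), n_perm = 49, seed = 2)
  expect_equal(sum(ci3$eig_fraction), 1)
  expect_true(all(diff(ci3$eigenvalues) <= 1e-12))
  expect_true(ci3$rv >= 0 && ci3$rv <= 1)

  expect_error(coinertia(mk(X), mk(Y[1:30, ])), "same row ids")
})

test_that("the RV permutation p-value is uniform under independence", {
  ps <- vapply(1:20, function(s) {
    set.seed(s + 900)
    X <- matrix(rnorm(50 * 4), 50); Y <- matrix(rnorm(50 * 4), 50)
    rownames(X) <- rownames(Y) <- paste0("i", 1:50)
    mk <- function(M) structure(list(ids = rownames(M), scores = M,
                                     eigenvalues = rep(1, 4), kind = "pcoa"),
                                class = "ordination")
    coinertia(mk(X), mk(Y), n_perm = 99, seed = s)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("group-level co-inertia reports population arrows", {
  cfg <- small_config(seed = 41, n_populations = 4, samples_per_population = 8)
  truth <- simulate_genotypes(build_allele_pool(cfg), cfg)
  be <- binary_encode(truth$mhc, truth$msat)
  bx <- between_class_analysis(principal_coordinates(jaccard_s3_distance(be$mhc)),
                               be$populations)
  by <- between_class_analysis(principal_coordinates(jaccard_s3_distance(be$msat)),
                               be$populations)
  coa <- coinertia(bx, by, n_perm = 49, seed = 1)
  expect_true(coa$grouped)
  expect_equal(nrow(coa$pop_scores_x), 4)
  expect_equal(length(coa$vector_lengths), 4)
  expect_true(all(coa$vector_lengths >= 0))
  expect_equal(sum(coa$eig_fraction), 1)
  # vector length equals the Euclidean gap between paired population scores
  gap <- sqrt(rowSums((coa$pop_scores_x[, 1:2, drop = FALSE] -
                         coa$pop_scores_y[, 1:2, drop = FALSE])^2))
  expect_equal(unname(coa$vector_lengths), unname(gap))
})
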