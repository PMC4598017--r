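# Great-circle distances in km between population coordinates (haversine,
# Earth radius 6371 km).
geographic_distance_km <- function(coords) {
  stopifnot(all(c("population", "lon", "lat") %in% names(coords)))
  n <- nrow(coords)
  pts <- as.matrix(coords[, c("lon", "lat")])
  d <- matrix(0, n, n, dimnames = list(coords$population, coords$population))
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <-
        geosphere::distHaversine(pts[i, ], pts[j, ], r = 6371000) / 1000
    }
  }
  d
}

#' Log-transformed geographic distance matrix
#'
#' Pairwise great-circle distances (haversine, Earth radius 6371 km) between
#' population coordinates, natural-log transformed to improve the linearity
#' of the distance-differentiation relationship in Mantel tests. The
#' diagonal stays 0; coincident population pairs are an error (their log
#' distance is undefined).
#'
#' @param coords data frame with columns `population`, `lon`, `lat`
#'   (degrees).
#' @param exclude optional population labels to drop before computing (e.g.
#'   a geographically detached reference region).
#' @return symmetric matrix of log-km distances.
#' @export
geographic_log_distance <- function(coords, exclude = NULL) {
  if (!is.null(exclude)) coords <- coords[!coords$population %in% exclude, ]
  if (nrow(coords) < 2) stop("need at least 2 populations")
  d <- geographic_distance_km(coords)
  off <- d[upper.tri(d)]
  if (any(off <= 0)) stop("coincident populations: log distance undefined")
  ld <- log(d)
  diag(ld) <- 0
  ld
}

#' Simple Mantel test
#'
#' Pearson correlation between the off-diagonal upper triangles of two
#' distance matrices; significance by simultaneous row/column permutation of
#' the second matrix, one-sided for positive association by default (the
#' isolation-by-distance hypothesis), with `(b + 1) / (m + 1)` smoothing.
#'
#' @param dA,dB symmetric distance matrices over the same labels.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return object of class `mantel_result` with `r`, `p`, `n_perm`, `kind`.
#' @export
mantel <- function(dA, dB, n_perm = 1000, seed = NULL,
                   alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  dA <- check_square_labeled(dA, "dA")
  dB <- check_square_labeled(dB, "dB")
  if (nrow(dA) != nrow(dB)) stop("matrices must have the same dimension")
  if (!is.null(rownames(dA)) && !is.null(rownames(dB)) &&
      !identical(rownames(dA), rownames(dB))) {
    stop("matrices must share the same labels in the same order")
  }
  a <- upper_tri(dA)
  b <- upper_tri(dB)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance in a distance matrix")
  }
  r <- stats::cor(a, b)
  p <- NA_real_
  if (n_perm > 0) {
    n <- nrow(dB)
    rp <- with_seed(seed %||% 1L, {
      vapply(seq_len(n_perm), function(k) {
        idx <- sample(n)
        stats::cor(a, upper_tri(dB[idx, idx]))
      }, numeric(1))
    })
    p <- if (alternative == "greater") {
      (sum(rp >= r) + 1) / (n_perm + 1)
    } else {
      (sum(abs(rp) >= abs(r)) + 1) / (n_perm + 1)
    }
  }
  structure(list(r = r, p = p, n_perm = n_perm, kind = "simple",
                 alternative = alternative),
            class = "mantel_result")
}

#' Partial Mantel test
#'
#' Correlation between `dA` and `dB` after removing the linear effect of a
#' covariate matrix `dC` from both (correlation of triangle residuals).
#' Significance follows the residual-permutation scheme: the residual matrix
#' of `dA` given `dC` is label-permuted and re-correlated with the residuals
#' of `dB` given `dC`.
#'
#' @inheritParams mantel
#' @param dC covariate distance matrix.
#' @return `mantel_result` with `kind = "partial"`.
#' @export
partial_mantel <- function(dA, dB, dC, n_perm = 1000, seed = NULL,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  dA <- check_square_labeled(dA, "dA")
  dB <- check_square_labeled(dB, "dB")
  dC <- check_square_labeled(dC, "dC")
  if (!(nrow(dA) == nrow(dB) && nrow(dA) == nrow(dC))) {
    stop("matrices must be conformable")
  }
  a <- upper_tri(dA); b <- upper_tri(dB); cc <- upper_tri(dC)
  if (stats::sd(a) == 0 || stats::sd(b) == 0 || stats::sd(cc) == 0) {
    stop("zero variance in a distance matrix")
  }
  if (abs(stats::cor(a, cc)) > 1 - 1e-10 || abs(stats::cor(b, cc)) > 1 - 1e-10) {
    # perfectly collinear covariate: residuals are identically 0
    if (abs(stats::cor(b, cc)) > 1 - 1e-10) stop("dB is collinear with dC")
  }

  tri_to_mat <- function(v, n) {
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- v
    m + t(m)
  }
  n <- nrow(dA)
  res_a <- stats::resid(stats::lm(a ~ cc))
  res_b <- stats::resid(stats::lm(b ~ cc))
  if (stats::sd(res_b) <= 1e-12 * stats::sd(b)) stop("dB is collinear with dC")
  # dA identical to dC up to numerical noise: nothing left to correlate
  r <- if (stats::sd(res_a) <= 1e-12 * stats::sd(a)) 0
       else stats::cor(res_a, res_b)

  p <- NA_real_
  if (n_perm > 0) {
    RA <- tri_to_mat(res_a, n)
    rp <- with_seed(seed %||% 1L, {
      vapply(seq_len(n_perm), function(k) {
        idx <- sample(n)
        ra <- upper_tri(RA[idx, idx])
        if (stats::sd(ra) == 0) return(0)
        stats::cor(ra, res_b)
      }, numeric(1))
    })
    p <- if (alternative == "greater") {
      (sum(rp >= r) + 1) / (n_perm + 1)
    } else {
      (sum(abs(rp) >= abs(r)) + 1) / (n_perm + 1)
    }
  }
  structure(list(r = r, p = p, n_perm = n_perm, kind = "partial",
                 alternative = alternative),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("%s Mantel test: r = %.3f, p = %.4g (%d permutations, %s)\n",
              if (x$kind == "partial") "Partial" else "Simple",
              x$r, x$p, x$n_perm, x$alternative))
  invisible(x)
}

#' Pearson correlation between two per-population diversity measures
#'
#' @param x,y numeric vectors of per-population values (n >= 3).
#' @return list with `r`, `p` (two-sided, t distribution on n - 2 df), `n`.
#' @export
diversity_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 populations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
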