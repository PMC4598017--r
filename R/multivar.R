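#' Jaccard (S3) distances for binary presence/absence data
#'
#' For two rows with `a` shared presences and `b`, `c` asymmetric ones, the
#' similarity is `s = a / (a + b + c)` and the distance the
#' Euclidean-embeddable transform `d = sqrt(1 - s)`.
#'
#' @param x 0/1 matrix (rows = individuals); all-zero rows are rejected.
#' @return symmetric distance matrix with the row names of `x`.
#' @export
jaccard_s3_distance <- function(x) {
  x <- as.matrix(x)
  if (!all(x %in% c(0, 1))) stop("matrix must contain only 0/1")
  if (any(rowSums(x) == 0)) {
    stop("all-zero rows: ", paste(rownames(x)[rowSums(x) == 0], collapse = ", "))
  }
  d <- sqrt(as.matrix(vegan::vegdist(x, method = "jaccard", binary = TRUE)))
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

#' Principal-coordinate embedding of a distance matrix
#'
#' Classical scaling of the double-centred squared-distance matrix; when the
#' input is not Euclidean-embeddable the Lingoes correction (default) adds
#' the smallest constant to all squared distances that makes every
#' eigenvalue non-negative. With `correction = "none"` a negative eigenvalue
#' whose magnitude exceeds 1e-8 of the total is recorded as a warning.
#'
#' @param d symmetric, zero-diagonal distance matrix.
#' @param correction `"lingoes"` or `"none"`.
#' @return object of class `ordination`: `ids`, `scores` (rows x axes),
#'   `eigenvalues` (non-increasing, positive axes only), `kind = "pcoa"`.
#' @export
principal_coordinates <- function(d, correction = c("lingoes", "none")) {
  correction <- match.arg(correction)
  d <- check_square_labeled(d)
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have a zero diagonal")
  ids <- rownames(d) %||% as.character(seq_len(nrow(d)))

  pc <- ape::pcoa(stats::as.dist(d),
                  correction = if (correction == "lingoes") "lingoes" else "none")
  corrected <- !is.null(pc$vectors.cor)
  vec <- if (corrected) pc$vectors.cor else pc$vectors
  eig <- if (corrected) pc$values$Corr_eig else pc$values$Eigenvalues
  if (correction == "none") {
    neg <- min(eig)
    if (neg < -1e-8 * sum(abs(eig))) {
      warning(sprintf("negative eigenvalue (%.3g) without correction", neg))
    }
  }
  keep <- which(eig > max(eig) * 1e-9)
  keep <- keep[keep <= ncol(vec)]
  scores <- vec[, keep, drop = FALSE]
  rownames(scores) <- ids
  colnames(scores) <- paste0("Axis", seq_along(keep))
  structure(list(ids = ids, scores = scores, eigenvalues = eig[keep],
                 kind = "pcoa", correction = correction,
                 corrected = corrected),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("%s ordination: %d rows, %d axes\n",
              x$kind, length(x$ids), ncol(x$scores)))
  frac <- x$eigenvalues / sum(x$eigenvalues)
  cat("  leading eigenvalue fractions:",
      paste(sprintf("%.3f", utils::head(frac, 4)), collapse = ", "), "\n")
  if (!is.null(x$between_fraction)) {
    cat(sprintf("  between-class inertia fraction: %.3f\n", x$between_fraction))
  }
  invisible(x)
}

#' Between-class analysis of an ordination
#'
#' Principal axes of the cloud of group centroids (weighted by group size)
#' in the ordination space, maximizing among-group variance; individuals are
#' projected onto those axes. Each axis is oriented so that its
#' largest-magnitude loading is positive, making signs deterministic.
#'
#' @param ord an [principal_coordinates()] result (or any `ordination`).
#' @param groups grouping vector aligned with `ord$ids` (or named by id).
#' @return `ordination` of kind `"between_class"` with row `scores`, group
#'   `group_scores`, `eigenvalues` and the `between_fraction` of total
#'   inertia explained among groups.
#' @export
between_class_analysis <- function(ord, groups) {
  stopifnot(inherits(ord, "ordination"))
  if (!is.null(names(groups))) groups <- groups[ord$ids]
  groups <- as.factor(as.character(groups))
  if (length(groups) != length(ord$ids) || anyNA(groups)) {
    stop("every row must be assigned to exactly one group")
  }
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  n_g <- table(groups)
  if (any(n_g == 0)) stop("empty group")

  X <- scale(ord$scores, center = TRUE, scale = FALSE)
  n <- nrow(X)
  G <- rowsum(X, groups) / as.vector(n_g)          # centroids
  w <- as.vector(n_g) / n
  Cb <- crossprod(G * sqrt(w))                     # weighted centroid covariance
  ev <- eigen(Cb, symmetric = TRUE)
  keep <- which(ev$values > max(ev$values, 0) * 1e-9)
  if (!length(keep)) {
    # identical centroids: no between-class structure
    axes <- matrix(0, ncol(X), 0)
    eigs <- numeric(0)
  } else {
    axes <- ev$vectors[, keep, drop = FALSE]
    eigs <- ev$values[keep]
    for (j in seq_len(ncol(axes))) {
      if (axes[which.max(abs(axes[, j])), j] < 0) axes[, j] <- -axes[, j]
    }
  }
  scores <- X %*% axes
  gscores <- G %*% axes
  if (ncol(axes) > 0) {
    colnames(scores) <- colnames(gscores) <- paste0("BCA", seq_len(ncol(axes)))
  }
  rownames(scores) <- ord$ids
  total_inertia <- sum(X^2) / n
  between_inertia <- sum(w * rowSums(G^2))
  structure(list(ids = ord$ids, scores = scores, eigenvalues = eigs,
                 kind = "between_class", groups = groups,
                 group_scores = gscores,
                 between_fraction = if (total_inertia > 0)
                   between_inertia / total_inertia else 0),
            class = "ordination")
}

#' Co-inertia analysis of two ordinations over the same observations
#'
#' Singular decomposition of the cross-covariance between two centred score
#' tables. The RV coefficient measures global co-structure:
#' `RV = tr(Cxy Cyx) / sqrt(tr(Cxx^2) tr(Cyy^2))`, in `[0, 1]`, invariant
#' to rotation and global scaling of either table. Its significance is
#' tested by permuting the rows of the second table (`(b + 1) / (m + 1)`
#' smoothing).
#'
#' When both inputs are [between_class_analysis()] results the analysis is
#' carried out at the *population* level: the tables are the group-size
#' weighted centroid clouds and the permutation test shuffles population
#' rows. This is the level at which the two markers' structures are being
#' compared; a permutation of individuals would instead test the (trivially
#' present) within-population block structure and declare co-structure for
#' any pair of group-structured markers. For plain ordinations the rows are
#' the observations themselves with uniform weights.
#'
#' Per-population paired scores locate each population in the common space
#' for each marker; the length of the arrow connecting them (first two
#' axes) is inversely related to the between-marker agreement for that
#' population.
#'
#' @param bca_x,bca_y two ordinations with identical row ids; `bca_x`
#'   conventionally holds the first marker (e.g. MHC) and `bca_y` the
#'   second (e.g. microsatellites).
#' @param n_perm permutations for the RV test.
#' @param seed RNG seed.
#' @return object of class `coinertia`: `eigenvalues`, `eig_fraction`,
#'   `rv`, `p_value`, `n_perm`, per-population scores (`pop_scores_x`,
#'   `pop_scores_y`), `vector_lengths`, and individual `row_scores_x`/`_y`
#'   when the inputs carry them.
#' @export
coinertia <- function(bca_x, bca_y, n_perm = 1000, seed = NULL) {
  stopifnot(inherits(bca_x, "ordination"), inherits(bca_y, "ordination"))
  if (!identical(sort(bca_x$ids), sort(bca_y$ids))) {
    stop("the two ordinations must cover the same row ids")
  }
  ord <- match(bca_x$ids, bca_y$ids)
  grouped <- !is.null(bca_x$groups) && !is.null(bca_y$groups)

  if (grouped) {
    gx <- bca_x$groups
    gy <- bca_y$groups[ord]
    if (!identical(as.character(gx), as.character(gy))) {
      stop("the two ordinations assign rows to different groups")
    }
    X <- bca_x$group_scores
    Y <- bca_y$group_scores[rownames(X), , drop = FALSE]
    w <- as.vector(table(gx)[rownames(X)]) / length(gx)
    labels <- rownames(X)
  } else {
    X <- bca_x$scores
    Y <- bca_y$scores[ord, , drop = FALSE]
    w <- rep(1 / nrow(X), nrow(X))
    labels <- bca_x$ids
  }

  center_w <- function(M, w) sweep(M, 2, colSums(M * w))
  Xc <- center_w(X, w)
  Yc <- center_w(Y, w)

  rv_of <- function(A, B) {
    Cxy <- crossprod(A * w, B)
    Cxx <- crossprod(A * w, A)
    Cyy <- crossprod(B * w, B)
    den <- sqrt(sum(Cxx^2) * sum(Cyy^2))
    if (den == 0) return(0)
    sum(Cxy^2) / den
  }

  Cxy <- crossprod(Xc * w, Yc)
  sv <- svd(Cxy)
  naxes <- max(1L, sum(sv$d > max(sv$d) * 1e-9))
  u <- sv$u[, seq_len(naxes), drop = FALSE]
  v <- sv$v[, seq_len(naxes), drop = FALSE]
  for (j in seq_len(naxes)) {
    if (u[which.max(abs(u[, j])), j] < 0) {
      u[, j] <- -u[, j]
      v[, j] <- -v[, j]
    }
  }
  eig <- sv$d[seq_len(naxes)]^2

  sx <- Xc %*% u
  sy <- Yc %*% v
  colnames(sx) <- colnames(sy) <- paste0("CoA", seq_len(naxes))
  rownames(sx) <- rownames(sy) <- labels

  rv <- rv_of(Xc, Yc)
  p <- NA_real_
  if (n_perm > 0) {
    n <- nrow(Xc)
    rv_perm <- with_seed(seed %||% 1L, {
      vapply(seq_len(n_perm), function(b) {
        Yp <- Y[sample(n), , drop = FALSE]
        rv_of(Xc, center_w(Yp, w))
      }, numeric(1))
    })
    p <- (sum(rv_perm >= rv) + 1) / (n_perm + 1)
  }

  row_x <- row_y <- NULL
  if (grouped) {
    pop_x <- sx
    pop_y <- sy
    # individual projections onto the co-inertia axes, for plotting
    Xi <- sweep(bca_x$scores, 2, colSums(X * w))
    Yi <- sweep(bca_y$scores[ord, , drop = FALSE], 2, colSums(Y * w))
    row_x <- Xi %*% u
    row_y <- Yi %*% v
    rownames(row_x) <- rownames(row_y) <- bca_x$ids
  } else {
    pop_x <- sx
    pop_y <- sy
    row_x <- sx
    row_y <- sy
  }
  ax <- seq_len(min(2, naxes))
  vlen <- sqrt(rowSums((pop_x[, ax, drop = FALSE] - pop_y[, ax, drop = FALSE])^2))

  structure(list(eigenvalues = eig, eig_fraction = eig / sum(eig),
                 rv = rv, p_value = p, n_perm = n_perm,
                 grouped = grouped,
                 row_scores_x = row_x, row_scores_y = row_y,
                 pop_scores_x = pop_x, pop_scores_y = pop_y,
                 vector_lengths = vlen),
            class = "coinertia")
}

#' @export
print.coinertia <- function(x, ...) {
  cat(sprintf("Co-inertia analysis: %d axes, RV = %.4f", length(x$eigenvalues), x$rv))
  if (!is.na(x$p_value)) cat(sprintf(", p = %.4g (%d permutations)", x$p_value, x$n_perm))
  cat("\n")
  cat("  eigenvalue fractions:",
      paste(sprintf("%.3f", utils::head(x$eig_fraction, 4)), collapse = ", "), "\n")
  if (!is.null(x$vector_lengths)) {
    cat("  population vector lengths (marker disagreement):\n")
    print(round(x$vector_lengths, 3))
  }
  invisible(x)
}

#' Diagnostic plot of a co-inertia analysis
#'
#' Arrows run from each population's position in the second table (dot,
#' e.g. microsatellites) to its position in the first (tip, e.g. MHC) on the
#' first factorial plane.
#'
#' @param x a [coinertia()] result.
#' @param ... passed to [plot()].
#' @export
plot.coinertia <- function(x, ...) {
  if (is.null(x$pop_scores_x) || ncol(x$pop_scores_x) < 2) {
    stop("population scores with >= 2 axes required for plotting")
  }
  px <- x$pop_scores_x[, 1:2]
  py <- x$pop_scores_y[, 1:2]
  lim <- range(c(px, py))
  plot(py, xlim = lim, ylim = lim, pch = 16,
       xlab = sprintf("CoA1 (%.0f%%)", 100 * x$eig_fraction[1]),
       ylab = sprintf("CoA2 (%.0f%%)", 100 * x$eig_fraction[2]), ...)
  graphics::arrows(py[, 1], py[, 2], px[, 1], px[, 2], length = 0.08)
  graphics::text(py, labels = rownames(py), pos = 3, cex = 0.8)
  invisible(x)
}
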