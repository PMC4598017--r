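#' Codon alignment container
#'
#' Equal-length, frame-trimmed coding sequences. `frame_offset` leading
#' bases and any trailing remainder are removed so that the stored length is
#' a positive multiple of 3; internal stop codons are an error (a terminal
#' stop is trimmed off).
#'
#' @param seqs named character vector of DNA sequences (>= 2).
#' @param frame_offset reading-frame offset (0, 1 or 2) to trim.
#' @return object of class `codon_alignment` (named character vector).
#' @export
codon_alignment <- function(seqs, frame_offset = 0) {
  if (length(seqs) < 2) stop("need at least 2 sequences")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (length(unique(nchar(seqs))) != 1) stop("sequences must have equal length")
  seqs <- toupper(seqs)
  if (any(grepl("[^ACGT]", seqs))) stop("sequences must be ACGT only")
  trimmed <- substr(seqs, frame_offset + 1L, nchar(seqs))
  ncod <- unname(nchar(trimmed[1])) %/% 3L
  if (ncod < 1) stop("no complete codon after trimming")
  trimmed <- substr(trimmed, 1L, 3L * ncod)
  code <- Biostrings::GENETIC_CODE
  aa <- lapply(trimmed, function(s) unname(code[split_codons(s)]))
  # drop a shared terminal stop column, reject internal stops
  if (all(vapply(aa, function(x) x[ncod] == "*", logical(1)))) {
    trimmed <- substr(trimmed, 1L, 3L * (ncod - 1L))
    ncod <- ncod - 1L
    aa <- lapply(aa, function(x) x[-length(x)])
  }
  internal <- vapply(aa, function(x) any(x == "*"), logical(1))
  if (any(internal)) {
    stop("internal stop codon in: ", paste(names(seqs)[internal], collapse = ", "))
  }
  structure(trimmed, n_codons = ncod, class = "codon_alignment")
}

# Fraction of synonymous one-step changes per position of a codon (changes
# into stop codons count as nonsynonymous), and the codon's synonymous site
# count S = sum of fractions.
ng86_site_table <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    code <- Biostrings::GENETIC_CODE
    bases <- c("A", "C", "G", "T")
    codons <- names(code)[code != "*"]
    S <- stats::setNames(numeric(length(codons)), codons)
    for (cd in codons) {
      s <- 0
      ch <- strsplit(cd, "")[[1]]
      for (pos in 1:3) for (b in setdiff(bases, ch[pos])) {
        alt <- ch
        alt[pos] <- b
        alt <- paste(alt, collapse = "")
        if (code[[alt]] != "*" && code[[alt]] == code[[cd]]) s <- s + 1 / 3
      }
      S[cd] <- s
    }
    cache <<- S
    cache
  }
})

# Synonymous/nonsynonymous difference counts between two codons, averaged
# over all shortest mutational pathways with equal weight; pathways passing
# through a stop codon are excluded (unless every pathway does).
ng86_path_diff <- function(c1, c2) {
  code <- Biostrings::GENETIC_CODE
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd_tot <- length(pos)
  if (nd_tot == 0) return(c(sd = 0, nd = 0))
  perms <- if (nd_tot == 1) list(pos)
           else if (nd_tot == 2) list(pos, rev(pos))
           else {
    idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    lapply(idx, function(i) pos[i])
  }
  b2 <- strsplit(c2, "")[[1]]
  walk <- function(order) {
    cur <- strsplit(c1, "")[[1]]
    sd <- nd <- 0
    for (p in order) {
      prev <- paste(cur, collapse = "")
      cur[p] <- b2[p]
      nxt <- paste(cur, collapse = "")
      if (code[[nxt]] == "*" && nxt != c2) return(NULL)  # stop intermediate
      if (code[[prev]] != "*" && code[[prev]] == code[[nxt]]) sd <- sd + 1
      else nd <- nd + 1
    }
    c(sd = sd, nd = nd)
  }
  res <- Filter(Negate(is.null), lapply(perms, walk))
  if (!length(res)) {
    # every pathway blocked by a stop: fall back to unweighted inclusion
    res <- lapply(perms, function(o) {
      cur <- strsplit(c1, "")[[1]]; sd <- nd <- 0
      for (p in o) {
        prev <- paste(cur, collapse = ""); cur[p] <- b2[p]
        nxt <- paste(cur, collapse = "")
        if (code[[prev]] == code[[nxt]]) sd <- sd + 1 else nd <- nd + 1
      }
      c(sd = sd, nd = nd)
    })
  }
  colMeans(do.call(rbind, res))
}

#' Nei-Gojobori (1986) dN/dS with a bootstrap Z-test of positive selection
#'
#' For every sequence pair, synonymous and nonsynonymous sites are counted
#' per codon (each position contributes its fraction of synonymous one-step
#' changes under the standard code; `S + N = 3 x codons` exactly) and
#' differences are counted over all shortest mutational pathways with equal
#' weight, excluding pathways through stop codons. Proportions are
#' Jukes-Cantor corrected; `dN` and `dS` are averaged over pairs. The
#' standard error of `dN - dS` comes from a seeded codon bootstrap and the
#' one-sided Z-test asks whether `dN > dS` (the signature of positive
#' selection, as expected at antigen-binding codons).
#'
#' @param aln a [codon_alignment()] (or named sequence vector, trimmed via
#'   `frame_offset`).
#' @param bootstrap_reps bootstrap replicates for the SE.
#' @param seed RNG seed for the bootstrap.
#' @param frame_offset used only when `aln` is not yet a `codon_alignment`.
#' @return object of class `dnds_result`: `dN`, `dS`, `Z`, `p`, `se`,
#'   `n_pairs`, `saturated_pairs`, `bootstrap_reps`, `seed`.
#' @export
ng86_dnds <- function(aln, bootstrap_reps = 1000, seed = NULL, frame_offset = 0) {
  if (!inherits(aln, "codon_alignment")) aln <- codon_alignment(aln, frame_offset)
  ncod <- attr(aln, "n_codons")
  nseq <- length(aln)
  codons <- lapply(aln, split_codons)
  site_tab <- ng86_site_table()

  pair_idx <- utils::combn(nseq, 2)
  np <- ncol(pair_idx)
  S_pc <- N_pc <- Sd_pc <- Nd_pc <- matrix(0, np, ncod)
  for (k in seq_len(np)) {
    ci <- codons[[pair_idx[1, k]]]
    cj <- codons[[pair_idx[2, k]]]
    s_i <- site_tab[ci]
    s_j <- site_tab[cj]
    S_pc[k, ] <- (s_i + s_j) / 2
    N_pc[k, ] <- 3 - S_pc[k, ]
    for (c in which(ci != cj)) {
      d <- ng86_path_diff(ci[c], cj[c])
      Sd_pc[k, c] <- d["sd"]
      Nd_pc[k, c] <- d["nd"]
    }
  }

  jc <- function(p) ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
  pair_d <- function(cols) {
    pS <- rowSums(Sd_pc[, cols, drop = FALSE]) / rowSums(S_pc[, cols, drop = FALSE])
    pN <- rowSums(Nd_pc[, cols, drop = FALSE]) / rowSums(N_pc[, cols, drop = FALSE])
    cbind(dS = jc(pS), dN = jc(pN))
  }

  obs <- pair_d(seq_len(ncod))
  saturated <- which(is.na(obs[, "dS"]) | is.na(obs[, "dN"]))
  if (length(saturated)) {
    warning(sprintf("%d saturated pair(s) excluded (p >= 0.75)", length(saturated)))
  }
  dS <- mean(obs[, "dS"], na.rm = TRUE)
  dN <- mean(obs[, "dN"], na.rm = TRUE)

  identical_aln <- all(Sd_pc == 0) && all(Nd_pc == 0)
  Z <- p <- se <- NA_real_
  if (!identical_aln && bootstrap_reps > 0) {
    diffs <- with_seed(seed %||% 1L, {
      vapply(seq_len(bootstrap_reps), function(b) {
        cols <- sample.int(ncod, ncod, replace = TRUE)
        d <- pair_d(cols)
        mean(d[, "dN"], na.rm = TRUE) - mean(d[, "dS"], na.rm = TRUE)
      }, numeric(1))
    })
    se <- stats::sd(diffs, na.rm = TRUE)
    if (is.finite(se) && se > 0) {
      Z <- (dN - dS) / se
      p <- stats::pnorm(Z, lower.tail = FALSE)
    }
  }

  structure(list(dN = dN, dS = dS, Z = Z, p = p, se = se,
                 n_pairs = np, saturated_pairs = length(saturated),
                 bootstrap_reps = bootstrap_reps, seed = seed,
                 n_codons = ncod,
                 identical_sequences = identical_aln),
            class = "dnds_result")
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf("NG86 dN/dS over %d pairs (%d codons)\n", x$n_pairs, x$n_codons))
  if (x$identical_sequences) {
    cat("  all sequences identical: dN = dS = 0, Z-test undefined\n")
    return(invisible(x))
  }
  cat(sprintf("  dN = %.4f, dS = %.4f, dN - dS = %.4f\n", x$dN, x$dS, x$dN - x$dS))
  if (is.finite(x$Z)) {
    cat(sprintf("  Z = %.3f, one-sided p = %.4g (codon bootstrap, %d reps)\n",
                x$Z, x$p, x$bootstrap_reps))
  }
  invisible(x)
}

#' Codon-model fit record
#'
#' A label, maximized log-likelihood and number of parameters in the omega
#' distribution for one externally fitted codon model; the raw material of
#' [lrt()]. Maximum-likelihood fitting itself is out of scope here.
#'
#' @param label model name (e.g. `"M1a"`).
#' @param lnL maximized log-likelihood.
#' @param k number of parameters in the omega distribution (>= 1).
#' @return object of class `model_fit`.
#' @export
model_fit <- function(label, lnL, k) {
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  structure(list(label = label, lnL = as.numeric(lnL), k = k),
            class = "model_fit")
}

#' Likelihood-ratio test between nested codon models
#'
#' `statistic = 2 (lnL_alt - lnL_null)` compared to a chi-square with
#' `df = k_alt - k_null` degrees of freedom.
#'
#' @param null,alt [model_fit()] records; `alt` must have more parameters
#'   and a log-likelihood no worse than `null` (tiny negative differences
#'   from printed rounding are clamped to 0).
#' @return object of class `lrt_result`: `statistic`, `df`, `p`, labels.
#' @export
lrt <- function(null, alt) {
  stopifnot(inherits(null, "model_fit"), inherits(alt, "model_fit"))
  if (alt$k <= null$k) {
    stop(sprintf("models not nested: alt k = %d <= null k = %d", alt$k, null$k))
  }
  if (alt$lnL < null$lnL - 1e-6) {
    stop("alternative log-likelihood is below the null: not a valid nested fit")
  }
  statistic <- max(0, 2 * (alt$lnL - null$lnL))
  df <- alt$k - null$k
  p <- stats::pchisq(statistic, df, lower.tail = FALSE)
  structure(list(statistic = statistic, df = df, p = p,
                 null = null$label, alt = alt$label),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT %s vs %s: 2*dlnL = %.2f, df = %d, p = %.4g\n",
              x$null, x$alt, x$statistic, x$df, x$p))
  invisible(x)
}
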