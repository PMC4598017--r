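#' Configuration for the synthetic amplicon study generator
#'
#' Builds and validates the parameter set used by [build_allele_pool()],
#' [simulate_genotypes()] and [simulate_reads()]. Defaults emulate a
#' nine-region carnivore survey genotyped at a 185-bp MHC class II DRB
#' exon 2 amplicon (2-5 co-amplifying alleles per individual from a pool of
#' 10, loci unresolvable) together with 11 diploid microsatellite loci, with
#' an isolation-by-distance gradient at the neutral marker and nearly
#' homogenized MHC allele frequencies.
#'
#' Population differentiation follows an F-model: population allele
#' frequencies are drawn from `Dirichlet(base * (1 - F) / F)` so that the
#' expected fixation index among populations equals `divergence_F` for each
#' marker class. When `ibd_slope > 0` the base frequencies themselves drift
#' along the (geographically ordered) chain of populations, with a drift
#' intensity of `ibd_slope * log(km)` per consecutive step, producing a
#' monotone increase of divergence with log geographic distance.
#'
#' @param n_populations number of populations.
#' @param samples_per_population integer vector (recycled) of individuals per
#'   population; the default mirrors a 269-individual, nine-region design
#'   with samples ranging from 13 to 56.
#' @param mhc_pool_size number of distinct true MHC alleles.
#' @param amplicon_length amplicon insert length in bp.
#' @param frame_offset reading-frame offset (0, 1 or 2) of the insert. The
#'   default 2 translates 183 of 185 bp into 61 codons.
#' @param alleles_per_individual_weights named probability weights over the
#'   number of MHC alleles carried per individual (names "2".."5").
#' @param n_microsat_loci number of diploid microsatellite loci.
#' @param microsat_alleles_per_locus size of the allele pool per locus.
#' @param divergence_F list with elements `mhc` and `microsat`, each a target
#'   fixation index in `[0, 1)`.
#' @param ibd_slope list with elements `mhc` and `microsat`: drift intensity
#'   per log-km of inter-population distance (0 disables the gradient).
#' @param coordinates data frame with columns `population`, `lon`, `lat`
#'   (degrees). The row order defines the one-dimensional chain along which
#'   isolation by distance is induced.
#' @param read_model list: `mean_depth`, `depth_dispersion` (negative
#'   binomial size; small values give the heavy depth variation typical of
#'   pooled pyrosequencing runs), `per_base_error_rate`, `chimera_rate`,
#'   `noise_variant_rate`, `allele_amplification_bias_sd` (SD of the
#'   log-normal per-allele amplification bias).
#' @param mid_scheme list with `forward` and `reverse` character vectors of
#'   MID tag sequences; combinations of tags index individuals.
#' @param primers list with `forward` and `reverse` primer sequences.
#' @param seed integer seed; all downstream generation is deterministic in it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_populations = 9,
                       samples_per_population = c(26, 16, 35, 56, 41, 19, 13, 28, 35),
                       mhc_pool_size = 10,
                       amplicon_length = 185,
                       frame_offset = 2,
                       alleles_per_individual_weights = c("2" = 0.267, "3" = 0.304,
                                                          "4" = 0.399, "5" = 0.030),
                       n_microsat_loci = 11,
                       microsat_alleles_per_locus = 8,
                       divergence_F = list(mhc = 0.01, microsat = 0.10),
                       ibd_slope = list(mhc = 0, microsat = 0.005),
                       coordinates = NULL,
                       read_model = list(),
                       mid_scheme = NULL,
                       primers = NULL,
                       seed = 1L) {
  n_populations <- as.integer(n_populations)
  if (n_populations < 1) stop("n_populations must be >= 1")
  samples_per_population <- rep_len(as.integer(samples_per_population), n_populations)
  if (any(samples_per_population < 1)) stop("samples_per_population must be positive")

  if (amplicon_length - frame_offset < 3) {
    stop("amplicon_length - frame_offset must be >= 3")
  }
  if (!frame_offset %in% 0:2) stop("frame_offset must be 0, 1 or 2")

  w <- alleles_per_individual_weights
  if (is.null(names(w)) || !all(names(w) %in% as.character(2:5))) {
    stop("alleles_per_individual_weights must be named with sizes in 2..5")
  }
  if (any(w < 0) || sum(w) <= 0) stop("alleles_per_individual_weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-6) stop("alleles_per_individual_weights must sum to 1")
  w <- w / sum(w)

  for (m in c("mhc", "microsat")) {
    f <- divergence_F[[m]]
    if (is.null(f) || f < 0 || f >= 1) {
      stop(sprintf("divergence_F$%s must be in [0, 1)", m))
    }
    s <- ibd_slope[[m]]
    if (is.null(s) || s < 0) stop(sprintf("ibd_slope$%s must be >= 0", m))
  }

  if (is.null(coordinates)) {
    coordinates <- data.frame(
      population = paste0("P", seq_len(n_populations)),
      lon = seq(-160, -88, length.out = n_populations),
      lat = c(62, 63, 64, 60, 57, 55, 55, 54, 52)[
        ((seq_len(n_populations) - 1) %% 9) + 1],
      stringsAsFactors = FALSE
    )
  }
  if (!all(c("population", "lon", "lat") %in% names(coordinates))) {
    stop("coordinates must have columns population, lon, lat")
  }
  if (nrow(coordinates) != n_populations) {
    stop("coordinates must have one row per population")
  }

  rm_default <- list(mean_depth = 1412, depth_dispersion = 1.04,
                     per_base_error_rate = 1e-3, chimera_rate = 0.02,
                     noise_variant_rate = 0.01,
                     allele_amplification_bias_sd = 0.3)
  unknown <- setdiff(names(read_model), names(rm_default))
  if (length(unknown)) stop("unknown read_model fields: ", paste(unknown, collapse = ", "))
  read_model <- utils::modifyList(rm_default, read_model)
  if (read_model$mean_depth < 0) stop("read_model$mean_depth must be >= 0")
  for (f in c("per_base_error_rate", "chimera_rate", "noise_variant_rate")) {
    if (read_model[[f]] < 0 || read_model[[f]] > 1) {
      stop(sprintf("read_model$%s must be in [0, 1]", f))
    }
  }

  if (is.null(mid_scheme)) {
    mid_scheme <- list(forward = default_mid_tags(14, offset = 0),
                       reverse = default_mid_tags(8, offset = 14))
  }
  if (is.null(primers)) {
    primers <- list(forward = "GTGACCTGGAATCGCTACAG",
                    reverse = "CCAGTTGAAGCTCACGTTCA")
  }

  structure(list(
    n_populations = n_populations,
    samples_per_population = samples_per_population,
    mhc_pool_size = as.integer(mhc_pool_size),
    amplicon_length = as.integer(amplicon_length),
    frame_offset = as.integer(frame_offset),
    alleles_per_individual_weights = w,
    n_microsat_loci = as.integer(n_microsat_loci),
    microsat_alleles_per_locus = as.integer(microsat_alleles_per_locus),
    divergence_F = divergence_F,
    ibd_slope = ibd_slope,
    coordinates = coordinates,
    read_model = read_model,
    mid_scheme = mid_scheme,
    primers = primers,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Deterministic 10-bp MID tags with pairwise Hamming distance >= 5,
# generated from a fixed internal stream so that default schemes are stable
# across sessions and platforms.
default_mid_tags <- function(n, len = 10, min_dist = 5, offset = 0) {
  with_seed(990001L, {
    tags <- character(0)
    total <- n + offset
    attempts <- 0
    while (length(tags) < total) {
      cand <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
      ok <- all(vapply(tags, function(t) hamming(t, cand) >= min_dist, logical(1)))
      if (ok) tags <- c(tags, cand)
      attempts <- attempts + 1
      if (attempts > 10000) stop("could not generate enough distinct MID tags")
    }
    tags[(offset + 1):total]
  })
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic amplicon study configuration\n")
  cat(sprintf("  populations: %d (n = %s)\n", x$n_populations,
              paste(x$samples_per_population, collapse = ", ")))
  cat(sprintf("  MHC: %d alleles x %d bp (frame offset %d), F = %.3g, IBD slope %.3g\n",
              x$mhc_pool_size, x$amplicon_length, x$frame_offset,
              x$divergence_F$mhc, x$ibd_slope$mhc))
  cat(sprintf("  microsatellites: %d loci x %d alleles, F = %.3g, IBD slope %.3g\n",
              x$n_microsat_loci, x$microsat_alleles_per_locus,
              x$divergence_F$microsat, x$ibd_slope$microsat))
  cat(sprintf("  reads: mean depth %g (dispersion %g), error %g/bp, chimera %g, noise %g\n",
              x$read_model$mean_depth, x$read_model$depth_dispersion,
              x$read_model$per_base_error_rate, x$read_model$chimera_rate,
              x$read_model$noise_variant_rate))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Generate a pool of distinct, ORF-clean amplicon allele sequences
#'
#' An ancestral sequence is built codon-wise from the 61 sense codons (plus
#' random out-of-frame flanking bases) and each allele derives from it by
#' 3-10 point substitutions, mirroring a real allelic series where alleles
#' differ by a few percent of sites (so Jukes-Cantor distances stay far from
#' saturation and per-population nucleotide diversity lands near observed
#' amplicon values). Candidates are rejected until no sequence carries a
#' stop codon in the configured reading frame and every pair differs by at
#' least 3 nucleotides, so the downstream 1-2 bp artifact rule can never
#' confuse two true alleles.
#'
#' @param config a [sim_config()] object.
#' @return named character vector of class `allele_pool` (names `A01`, ...),
#'   with attributes `amplicon_length` and `frame_offset`.
#' @export
build_allele_pool <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  pool_size <- config$mhc_pool_size
  len <- config$amplicon_length
  off <- config$frame_offset
  if (pool_size < 2) stop("mhc_pool_size must be >= 2 (genotypes carry at least 2 alleles)")
  if (len < 3) stop("amplicon_length must be >= 3")
  if (log(pool_size) > len * log(4)) {
    stop("mhc_pool_size exceeds the sequence space for this amplicon length")
  }

  code <- Biostrings::GENETIC_CODE
  sense_codons <- names(code)[code != "*"]
  n_codons <- (len - off) %/% 3L
  n_rem <- (len - off) %% 3L
  bases <- c("A", "C", "G", "T")

  stop_free <- function(s) {
    trimmed <- substr(s, off + 1L, off + 3L * n_codons)
    !any(code[split_codons(trimmed)] == "*")
  }

  with_seed(derive_seed(config$seed, "allele_pool"), {
    ancestor <- paste0(
      paste(sample(bases, off, replace = TRUE), collapse = ""),
      paste(sample(sense_codons, n_codons, replace = TRUE), collapse = ""),
      paste(sample(bases, n_rem, replace = TRUE), collapse = "")
    )
    mutate <- function(s, k) {
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      pos <- sample.int(len, k)
      for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
      paste(ch, collapse = "")
    }
    pool <- character(0)
    attempts <- 0
    while (length(pool) < pool_size) {
      attempts <- attempts + 1
      if (attempts > 1000 * pool_size) {
        stop("could not build an allele pool satisfying the pairwise-distance constraint")
      }
      cand <- mutate(ancestor, sample(3:10, 1))
      if (stop_free(cand) &&
          all(vapply(pool, function(p) hamming(p, cand) >= 3, logical(1)))) {
        pool <- c(pool, cand)
      }
    }
    names(pool) <- sprintf("A%02d", seq_along(pool))
    structure(pool, class = "allele_pool",
              amplicon_length = len, frame_offset = off)
  })
}

#' Simulate ground-truth genotypes under the F-model
#'
#' Draws per-population allele frequencies for both marker classes around
#' marker-specific base frequencies with dispersion controlled by the target
#' fixation index (`Dirichlet(base * (1 - F) / F)`; `F = 0` copies the base
#' exactly). With a positive `ibd_slope` the base frequencies drift along the
#' population chain with intensity proportional to the log-km distance
#' between consecutive populations. MHC genotypes are allele *sets* (sampled
#' without replacement, sizes drawn from the configured weights) because the
#' amplicon co-amplifies an unknown number of unresolvable loci;
#' microsatellite genotypes are unordered diploid pairs drawn per locus.
#'
#' @param pool an [build_allele_pool()] result.
#' @param config the [sim_config()] used to build the pool.
#' @return a list of class `truth_set` with elements `allele_sequences`,
#'   `mhc` (an [mhc_genotypes()] table), `msat` (an [msat_genotypes()]
#'   table), `pop_freqs` (list `mhc` matrix and `msat` per-locus matrices),
#'   `coordinates` and `config`.
#' @export
simulate_genotypes <- function(pool, config) {
  stopifnot(inherits(config, "sim_config"), inherits(pool, "allele_pool"))
  if (length(pool) < 5 && any(names(config$alleles_per_individual_weights) > length(pool))) {
    stop("allele pool smaller than the largest genotype size")
  }
  npop <- config$n_populations
  pops <- config$coordinates$population
  nind <- config$samples_per_population

  # log-km steps between consecutive populations along the chain
  step_logkm <- if (npop > 1) {
    d <- geographic_distance_km(config$coordinates)
    log(pmax(d[cbind(1:(npop - 1), 2:npop)], 1.01))
  } else numeric(0)

  with_seed(derive_seed(config$seed, "genotypes"), {
    draw_pop_freqs <- function(base, f_target, slope) {
      freqs <- matrix(NA_real_, npop, length(base))
      cur <- base
      for (j in seq_len(npop)) {
        if (j > 1 && slope > 0) {
          fstep <- min(0.95, slope * step_logkm[j - 1])
          if (fstep > 0) cur <- rdirichlet1(cur * (1 - fstep) / fstep)
        }
        freqs[j, ] <- if (f_target > 0) {
          rdirichlet1(cur * (1 - f_target) / f_target)
        } else cur
      }
      freqs
    }

    # --- MHC ---
    base_mhc <- rdirichlet1(rep(1, length(pool)))
    mhc_freqs <- draw_pop_freqs(base_mhc, config$divergence_F$mhc, config$ibd_slope$mhc)
    dimnames(mhc_freqs) <- list(pops, names(pool))

    sizes <- as.integer(names(config$alleles_per_individual_weights))
    ids <- sprintf("I%04d", seq_len(sum(nind)))
    ind_pop <- rep(pops, nind)
    k_alleles <- sizes[sample.int(length(sizes), sum(nind), replace = TRUE,
                                  prob = config$alleles_per_individual_weights)]
    allele_sets <- vector("list", sum(nind))
    for (i in seq_along(ids)) {
      p <- mhc_freqs[ind_pop[i], ]
      allele_sets[[i]] <- sort(sample(names(pool), k_alleles[i],
                                      replace = FALSE, prob = p))
    }
    mhc_tab <- mhc_genotypes(ids, ind_pop, allele_sets)

    # --- microsatellites ---
    loci <- sprintf("L%02d", seq_len(config$n_microsat_loci))
    allele_labels <- 100L + 2L * seq_len(config$microsat_alleles_per_locus)
    msat_freqs <- vector("list", length(loci))
    names(msat_freqs) <- loci
    geno <- matrix(NA_integer_, sum(nind), 2L * length(loci))
    for (l in seq_along(loci)) {
      base_l <- rdirichlet1(rep(1, length(allele_labels)))
      fr <- draw_pop_freqs(base_l, config$divergence_F$microsat,
                           config$ibd_slope$microsat)
      dimnames(fr) <- list(pops, as.character(allele_labels))
      msat_freqs[[l]] <- fr
      for (j in seq_len(npop)) {
        rows <- which(ind_pop == pops[j])
        geno[rows, 2 * l - 1] <- sample(allele_labels, length(rows),
                                        replace = TRUE, prob = fr[j, ])
        geno[rows, 2 * l] <- sample(allele_labels, length(rows),
                                    replace = TRUE, prob = fr[j, ])
      }
    }
    colnames(geno) <- paste(rep(loci, each = 2), c(1, 2), sep = ".")
    msat_tab <- msat_genotypes(ids, ind_pop, geno, loci = loci)

    structure(list(
      allele_sequences = pool,
      mhc = mhc_tab,
      msat = msat_tab,
      pop_freqs = list(mhc = mhc_freqs, msat = msat_freqs),
      coordinates = config$coordinates,
      config = config
    ), class = "truth_set")
  })
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("Synthetic truth set: %d individuals, %d populations\n",
              nrow(x$mhc), length(unique(x$mhc$population))))
  cat(sprintf("  MHC pool: %d alleles of %d bp; microsatellites: %d loci\n",
              length(x$allele_sequences),
              attr(x$allele_sequences, "amplicon_length"),
              length(attr(x$msat, "loci"))))
  invisible(x)
}

#' Simulate tagged, artifact-bearing amplicon reads from a truth set
#'
#' Per individual, total depth is drawn from a negative binomial around the
#' configured mean (overdispersed, as in pooled pyrosequencing runs) and
#' reads are allocated to the individual's alleles with multiplicative
#' log-normal amplification biases. Each read is then, independently, turned
#' into a uniform-random off-pool noise sequence (probability
#' `noise_variant_rate`) or a single-crossover chimera of two of the
#' individual's alleles (probability `chimera_rate`), and point substitution
#' errors are added at `per_base_error_rate` per base. Reads are flanked by
#' the individual's forward MID + forward primer and the reverse complement
#' of reverse primer + reverse MID.
#'
#' @param truth a [simulate_genotypes()] result.
#' @param config the matching [sim_config()].
#' @return list of class `read_set`: `reads` (named character vector),
#'   `provenance` (data frame with one truth label per read: the source
#'   allele id, `"chimera"` or `"noise"`, plus the number of point errors),
#'   `assignment` (individual to MID-pair map) and `scheme` (a
#'   [tag_scheme()] ready for [demultiplex()]).
#' @export
simulate_reads <- function(truth, config) {
  stopifnot(inherits(truth, "truth_set"), inherits(config, "sim_config"))
  rm <- config$read_model
  len <- config$amplicon_length
  pool <- truth$allele_sequences
  ids <- truth$mhc$individual
  sets <- truth$mhc$alleles

  combos <- expand.grid(fwd = config$mid_scheme$forward,
                        rev = config$mid_scheme$reverse,
                        stringsAsFactors = FALSE)
  if (nrow(combos) < length(ids)) {
    stop(sprintf("MID scheme yields %d tag pairs but %d individuals need tags",
                 nrow(combos), length(ids)))
  }

  with_seed(derive_seed(config$seed, "reads"), {
    assignment <- data.frame(individual = ids,
                             fwd_mid = combos$fwd[seq_along(ids)],
                             rev_mid = combos$rev[seq_along(ids)],
                             stringsAsFactors = FALSE)

    depths <- stats::rnbinom(length(ids), mu = rm$mean_depth,
                             size = rm$depth_dispersion)
    total <- sum(depths)

    read_ind <- rep.int(seq_along(ids), depths)
    n_alleles <- lengths(sets)[read_ind]

    # per-read artifact class
    u <- stats::runif(total)
    is_noise <- u < rm$noise_variant_rate
    is_chim <- !is_noise &
      u < rm$noise_variant_rate + rm$chimera_rate &
      n_alleles >= 2

    # per-(individual, allele) amplification bias
    bias <- lapply(lengths(sets), function(k) {
      w <- exp(stats::rnorm(k, 0, rm$allele_amplification_bias_sd))
      w / sum(w)
    })

    src <- character(total)
    inserts <- character(total)
    bases <- c("A", "C", "G", "T")
    pos <- 1L
    for (i in seq_along(ids)) {
      d <- depths[i]
      if (d == 0) next
      idx <- pos:(pos + d - 1L)
      pos <- pos + d
      picked <- sample(sets[[i]], d, replace = TRUE, prob = bias[[i]])
      src[idx] <- picked
      inserts[idx] <- unname(pool[picked])

      ch <- idx[is_chim[idx]]
      if (length(ch)) {
        for (r in ch) {
          par <- sample(sets[[i]], 2, replace = FALSE)
          cut <- sample.int(len - 1L, 1L)
          inserts[r] <- paste0(substr(pool[[par[1]]], 1L, cut),
                               substr(pool[[par[2]]], cut + 1L, len))
          src[r] <- "chimera"
        }
      }
    }
    nz <- which(is_noise)
    if (length(nz)) {
      for (r in nz) {
        inserts[r] <- paste(sample(bases, len, replace = TRUE), collapse = "")
        src[r] <- "noise"
      }
    }

    # point substitution errors
    n_err <- stats::rbinom(total, len, rm$per_base_error_rate)
    err_reads <- which(n_err > 0)
    for (r in err_reads) {
      p <- sample.int(len, n_err[r])
      s <- strsplit(inserts[r], "", fixed = TRUE)[[1]]
      for (q in p) s[q] <- sample(setdiff(bases, s[q]), 1L)
      inserts[r] <- paste(s, collapse = "")
    }

    fwd <- paste0(assignment$fwd_mid, config$primers$forward)[read_ind]
    rev_tail <- paste0(revcomp(config$primers$reverse), "")[1]
    rc_rev_mid <- revcomp(assignment$rev_mid)
    tail <- paste0(rev_tail, rc_rev_mid)[read_ind]
    reads <- paste0(fwd, inserts, tail)
    names(reads) <- sprintf("read%07d", seq_len(total))

    provenance <- data.frame(
      read_id = names(reads),
      individual = ids[read_ind],
      source = src,
      n_errors = n_err,
      stringsAsFactors = FALSE
    )

    scheme <- tag_scheme(forward_mids = config$mid_scheme$forward,
                         reverse_mids = config$mid_scheme$reverse,
                         forward_primer = config$primers$forward,
                         reverse_primer = config$primers$reverse,
                         assignment = assignment)

    structure(list(reads = reads, provenance = provenance,
                   assignment = assignment, scheme = scheme),
              class = "read_set")
  })
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("Simulated read set: %d reads, %d individuals\n",
              length(x$reads), nrow(x$assignment)))
  src <- table(ifelse(x$provenance$source %in% c("chimera", "noise"),
                      x$provenance$source, "allele"))
  cat("  provenance:", paste(names(src), src, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}
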