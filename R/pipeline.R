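#' Validate and normalize a pipeline configuration
#'
#' The configuration is a single YAML (or already-parsed list) document with
#' per-stage blocks. Unknown keys are rejected with their path into the
#' document; missing keys are filled with defaults and echoed back.
#'
#' Recognised structure (all blocks optional):
#' \preformatted{
#' seed: 1
#' simulation:            # any sim_config() argument
#'   n_populations: 9
#'   samples_per_population: [26, 16, 35, 56, 41, 19, 13, 28, 35]
#' genotyper:
#'   min_depth: 150
#'   mpaf_true_threshold: 0.04
#'   mpaf_floor: 0.001
#' popgen:
#'   n_perm_amova: 1000
#'   n_perm_pairwise: 199
#' multivar:
#'   n_perm_rv: 999
#' ibd:
#'   n_perm: 999
#'   exclude: []          # populations dropped from IBD tests
#' selection:
#'   bootstrap_reps: 1000
#'   model_fits: [{label: M1a, lnL: -527.69, k: 2}, ...]
#'   lrt_pairs: ["M1a:M2a"]
#' }
#'
#' @param config path to a YAML file, or a list.
#' @return normalized list of class `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a list")

  defaults <- list(
    seed = 1L,
    simulation = list(),
    genotyper = list(min_depth = 150, mpaf_true_threshold = 0.04,
                     mpaf_floor = 0.001),
    popgen = list(n_perm_amova = 1000, n_perm_pairwise = 199),
    multivar = list(n_perm_rv = 999),
    ibd = list(n_perm = 999, exclude = character(0)),
    selection = list(bootstrap_reps = 1000, model_fits = list(),
                     lrt_pairs = list())
  )
  errs <- character(0)
  unknown_top <- setdiff(names(config), names(defaults))
  if (length(unknown_top)) {
    errs <- c(errs, paste0("unknown key: ", unknown_top))
  }
  for (blk in setdiff(names(defaults), c("seed", "simulation"))) {
    if (!is.null(config[[blk]])) {
      bad <- setdiff(names(config[[blk]]), names(defaults[[blk]]))
      if (length(bad)) errs <- c(errs, paste0("unknown key: ", blk, ".", bad))
    }
  }
  sim_args <- names(formals(sim_config))
  if (!is.null(config$simulation)) {
    bad <- setdiff(names(config$simulation), setdiff(sim_args, "seed"))
    if (length(bad)) errs <- c(errs, paste0("unknown key: simulation.", bad))
  }
  if (length(errs)) stop(paste(errs, collapse = "; "))

  out <- defaults
  for (nm in names(config)) {
    if (nm %in% c("seed", "simulation")) {
      out[[nm]] <- config[[nm]]
    } else {
      for (k in names(config[[nm]])) out[[nm]][[k]] <- config[[nm]][[k]]
    }
  }
  out$seed <- as.integer(out$seed %||% defaults$seed)
  # materialize the full simulation config so the echo is complete
  out$simulation <- do.call(sim_config, c(out$simulation, list(seed = out$seed)))
  structure(out, class = "pipeline_config")
}

#' Run the full comparative analysis pipeline
#'
#' Executes, in dependency order: synthetic-data generation (allele pool,
#' genotypes, reads), amplicon genotyping (demultiplex, tabulate, classify,
#' call, concordance bound), population statistics (diversity report, AMOVA
#' for both markers, pairwise differentiation), multivariate co-structure
#' (binary encoding, Jaccard, PCoA, between-class analysis, co-inertia with
#' RV test), isolation-by-distance Mantel tests and the NG86 dN/dS scan of
#' the allele pool, plus any configured LRTs. All artifacts are written
#' under `out_dir` and listed with content hashes in `MANIFEST.json`; the
#' headline marker contrast is written to `summary.json`.
#'
#' @param config a [validate_config()] result (or something coercible).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `summary` and `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  say <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
    cat(line, "\n", sep = "", file = logf, append = TRUE)
    message(line)
  }
  paths <- character(0)
  keep <- function(p) { paths[[length(paths) + 1]] <<- p; p }

  # --- stage 1: simulate ---
  say("simulating study data (seed %d)", config$seed)
  sc <- config$simulation
  pool <- build_allele_pool(sc)
  truth <- simulate_genotypes(pool, sc)
  reads <- simulate_reads(truth, sc)
  write_fasta(pool, keep(file.path(out_dir, "alleles.fasta")))
  write_fasta(reads$reads, keep(file.path(out_dir, "reads.fasta")))
  write_mhc_genotypes(truth$mhc, keep(file.path(out_dir, "truth_mhc.tsv")))
  write_msat_genotypes(truth$msat, keep(file.path(out_dir, "truth_msat.tsv")))
  write_coordinates(truth$coordinates, keep(file.path(out_dir, "coordinates.csv")))
  utils::write.table(reads$provenance, keep(file.path(out_dir, "provenance.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg_echo <- config
  cfg_echo$simulation <- unclass(cfg_echo$simulation)
  jsonlite::write_json(unclass(cfg_echo), keep(file.path(out_dir, "config.json")),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  # --- stage 2: genotype ---
  say("genotyping %d reads", length(reads$reads))
  gt <- config$genotyper
  dm <- demultiplex(reads$reads, reads$scheme, sc$amplicon_length)
  vt <- tabulate_variants(dm)
  cls <- classify_variants(vt, mpaf_true_threshold = gt$mpaf_true_threshold,
                           mpaf_floor = gt$mpaf_floor,
                           frame_offset = sc$frame_offset,
                           known_alleles = pool)
  pops_of <- stats::setNames(truth$mhc$population, truth$mhc$individual)
  calls <- call_genotypes(vt, cls, min_depth = gt$min_depth,
                          populations = pops_of)
  utils::write.table(cls, keep(file.path(out_dir, "classification.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(calls)[, setdiff(names(calls), "allele_set")],
                     keep(file.path(out_dir, "genotype_calls.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dm$discards, keep(file.path(out_dir, "discard_log.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  called <- calls[calls$status == "CALLED" & calls$n_alleles >= 2, ]
  mhc_called <- mhc_genotypes(called$individual, called$population,
                              called$allele_set)
  say("called %d/%d individuals (implied minimum loci: %d)",
      nrow(called), nrow(calls), implied_min_loci(calls))

  # --- stage 3: population statistics ---
  say("population diversity and differentiation")
  pg <- config$popgen
  seqs <- pool
  names(seqs) <- names(pool)
  div <- diversity_report(mhc_called, truth$msat, seqs)
  utils::write.table(div, keep(file.path(out_dir, "diversity_report.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  am_mhc <- amova(mhc_called, allele_seqs = seqs, n_perm = pg$n_perm_amova,
                  seed = derive_seed(config$seed, "amova_mhc"))
  am_msat <- amova(truth$msat, n_perm = pg$n_perm_amova,
                   seed = derive_seed(config$seed, "amova_msat"))
  pw_mhc <- pairwise_differentiation(mhc_called, "phist", allele_seqs = seqs,
                                     n_perm = pg$n_perm_pairwise,
                                     seed = derive_seed(config$seed, "pw_mhc"))
  pw_msat <- pairwise_differentiation(truth$msat, "fst",
                                      n_perm = pg$n_perm_pairwise,
                                      seed = derive_seed(config$seed, "pw_msat"))
  write_square_matrix(pw_mhc$stat, keep(file.path(out_dir, "pairwise_phist_mhc.csv")))
  write_square_matrix(pw_msat$stat, keep(file.path(out_dir, "pairwise_fst_msat.csv")))

  # --- stage 4: multivariate co-structure ---
  say("co-inertia analysis")
  be <- binary_encode(mhc_called, truth$msat)
  bca_x <- between_class_analysis(
    principal_coordinates(jaccard_s3_distance(be$mhc)), be$populations)
  bca_y <- between_class_analysis(
    principal_coordinates(jaccard_s3_distance(be$msat)), be$populations)
  coa <- coinertia(bca_x, bca_y, n_perm = config$multivar$n_perm_rv,
                   seed = derive_seed(config$seed, "rv"))
  jsonlite::write_json(
    list(rv = coa$rv, p = coa$p_value, n_perm = coa$n_perm,
         eig_fraction = coa$eig_fraction,
         vector_lengths = as.list(coa$vector_lengths)),
    keep(file.path(out_dir, "coinertia.json")), auto_unbox = TRUE, digits = NA)

  # --- stage 5: isolation by distance ---
  say("isolation-by-distance tests")
  excl <- config$ibd$exclude
  coords <- truth$coordinates
  keep_pops <- setdiff(coords$population, excl)
  geo <- geographic_log_distance(coords, exclude = excl)
  sub <- function(m) m[keep_pops, keep_pops]
  m_msat <- mantel(sub(pw_msat$stat), geo, n_perm = config$ibd$n_perm,
                   seed = derive_seed(config$seed, "mantel_msat"))
  m_mhc <- mantel(sub(pw_mhc$stat), geo, n_perm = config$ibd$n_perm,
                  seed = derive_seed(config$seed, "mantel_mhc"))
  pm_mhc <- partial_mantel(sub(pw_mhc$stat), geo, sub(pw_msat$stat),
                           n_perm = config$ibd$n_perm,
                           seed = derive_seed(config$seed, "pmantel_mhc"))
  ai <- allele_diversity_index(mhc_called)
  mean_alleles <- stats::aggregate(
    lengths(mhc_called$alleles), list(population = mhc_called$population), mean)
  ar <- rarefied_allelic_richness(truth$msat)
  common <- intersect(mean_alleles$population, ar$population)
  divcor <- diversity_correlation(
    ar$Ar[match(common, ar$population)],
    mean_alleles$x[match(common, mean_alleles$population)])

  # --- stage 6: selection ---
  say("selection statistics")
  dnds <- ng86_dnds(codon_alignment(pool, frame_offset = sc$frame_offset),
                    bootstrap_reps = config$selection$bootstrap_reps,
                    seed = derive_seed(config$seed, "dnds"))
  lrts <- list()
  fits <- config$selection$model_fits
  if (length(fits) && length(config$selection$lrt_pairs)) {
    by_label <- stats::setNames(
      lapply(fits, function(f) model_fit(f$label, f$lnL, f$k)),
      vapply(fits, `[[`, "", "label"))
    for (pair in config$selection$lrt_pairs) {
      lab <- strsplit(pair, ":", fixed = TRUE)[[1]]
      res <- lrt(by_label[[lab[1]]], by_label[[lab[2]]])
      lrts[[pair]] <- list(statistic = res$statistic, df = res$df, p = res$p)
    }
  }

  summary <- list(
    n_individuals = nrow(calls),
    n_called = nrow(called),
    implied_min_loci = implied_min_loci(calls),
    amova = list(
      mhc = list(phi_st = am_mhc$phi_st, pct_among = am_mhc$pct_among,
                 p = am_mhc$p_value),
      msat = list(fst = am_msat$phi_st, pct_among = am_msat$pct_among,
                  p = am_msat$p_value)
    ),
    pairwise_mean = list(mhc_phist = mean(upper_tri(pw_mhc$stat)),
                         msat_fst = mean(upper_tri(pw_msat$stat))),
    mantel = list(
      msat = list(r = m_msat$r, p = m_msat$p),
      mhc = list(r = m_mhc$r, p = m_mhc$p),
      mhc_partial_given_msat = list(r = pm_mhc$r, p = pm_mhc$p)
    ),
    rv = list(rv = coa$rv, p = coa$p_value),
    diversity_correlation = divcor,
    dnds = list(dN = dnds$dN, dS = dnds$dS, Z = dnds$Z, p = dnds$p),
    lrt = lrts
  )
  jsonlite::write_json(summary, keep(file.path(out_dir, "summary.json")),
                       auto_unbox = TRUE, digits = NA)

  manifest <- data.frame(
    file = basename(unlist(paths)),
    md5 = unname(tools::md5sum(unlist(paths))),
    bytes = file.size(unlist(paths)),
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(list(seed = config$seed, files = manifest),
                       file.path(out_dir, "MANIFEST.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done: %d artifacts", nrow(manifest))
  invisible(list(summary = summary, manifest = manifest))
}
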