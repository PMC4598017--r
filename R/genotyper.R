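#' MID tag scheme for demultiplexing pooled amplicon reads
#'
#' @param forward_mids,reverse_mids character vectors of tag sequences.
#' @param forward_primer,reverse_primer primer sequences (the read layout is
#'   forward MID + forward primer + insert + revcomp(reverse primer) +
#'   revcomp(reverse MID)).
#' @param assignment data frame with columns `individual`, `fwd_mid`,
#'   `rev_mid` mapping tag pairs to individuals; pairs must be distinct.
#' @return object of class `tag_scheme`. The minimum pairwise Hamming
#'   distance among equal-length tags is recorded in the `min_tag_distance`
#'   attribute (well-designed schemes keep this large enough that tag
#'   misassignment through sequencing error is essentially impossible).
#' @export
tag_scheme <- function(forward_mids, reverse_mids, forward_primer,
                       reverse_primer, assignment) {
  stopifnot(is.character(forward_mids), length(forward_mids) > 0,
            is.character(reverse_mids), length(reverse_mids) > 0)
  if (!all(c("individual", "fwd_mid", "rev_mid") %in% names(assignment))) {
    stop("assignment needs columns individual, fwd_mid, rev_mid")
  }
  key <- paste(assignment$fwd_mid, assignment$rev_mid)
  if (anyDuplicated(key)) stop("assignment contains duplicated tag pairs")
  if (!all(assignment$fwd_mid %in% forward_mids) ||
      !all(assignment$rev_mid %in% reverse_mids)) {
    stop("assignment uses tags absent from the MID lists")
  }
  min_dist <- function(tags) {
    tags <- tags[nchar(tags) == nchar(tags[1])]
    if (length(tags) < 2) return(NA_integer_)
    min(utils::combn(length(tags), 2, function(ij) hamming(tags[ij[1]], tags[ij[2]])))
  }
  structure(list(forward_mids = forward_mids, reverse_mids = reverse_mids,
                 forward_primer = toupper(forward_primer),
                 reverse_primer = toupper(reverse_primer),
                 assignment = assignment),
            min_tag_distance = min(min_dist(forward_mids), min_dist(reverse_mids),
                                   na.rm = TRUE),
            class = "tag_scheme")
}

#' Demultiplex and filter raw amplicon reads
#'
#' A read is retained iff (in this order of checks) a forward MID is found
#' exactly at its start, the full forward primer follows immediately, a
#' reverse MID (reverse-complemented) ends the read, the full reverse primer
#' (reverse-complemented) precedes it, the insert contains no ambiguity
#' codes, and the insert length equals `expected_length`. Matching is exact:
#' no mismatch tolerance in tags or primers. Each discarded read is logged
#' with the single (first-failing) reason; reads with a tag pair absent from
#' the assignment are logged as `unassigned`, not an error.
#'
#' @param reads named character vector (or `DNAStringSet`) of raw reads.
#' @param scheme a [tag_scheme()].
#' @param expected_length required insert length in bp.
#' @return list of class `demux_result`: `assignments` (read id, individual,
#'   insert), `discards` (read id, reason) and `n_input`. Retained plus
#'   discarded always equals the input count.
#' @export
demultiplex <- function(reads, scheme, expected_length) {
  stopifnot(inherits(scheme, "tag_scheme"), expected_length > 0)
  if (methods::is(reads, "XStringSet")) {
    nm <- names(reads)
    reads <- as.character(reads)
    names(reads) <- nm
  }
  if (is.null(names(reads))) names(reads) <- sprintf("read%07d", seq_along(reads))
  reads <- toupper(reads)
  n <- length(reads)
  ids <- names(reads)
  reason <- rep(NA_character_, n)

  # forward MID: exact prefix (longest tags first so no tag can shadow a
  # longer one it prefixes)
  fw <- scheme$forward_mids[order(-nchar(scheme$forward_mids))]
  f_tag <- rep(NA_character_, n)
  for (t in fw) {
    hit <- is.na(f_tag) & startsWith(reads, t)
    f_tag[hit] <- t
  }
  reason[is.na(f_tag)] <- "forward_tag"

  fp <- scheme$forward_primer
  ok <- !is.na(f_tag)
  has_fp <- rep(FALSE, n)
  has_fp[ok] <- substr(reads[ok], nchar(f_tag[ok]) + 1L,
                       nchar(f_tag[ok]) + nchar(fp)) == fp
  reason[ok & !has_fp] <- "forward_primer"

  rv <- scheme$reverse_mids[order(-nchar(scheme$reverse_mids))]
  rc_rv <- revcomp(rv)
  r_tag <- rep(NA_character_, n)
  for (k in seq_along(rv)) {
    hit <- is.na(r_tag) & endsWith(reads, rc_rv[k])
    r_tag[hit] <- rv[k]
  }
  ok <- ok & has_fp
  reason[ok & is.na(r_tag)] <- "reverse_tag"
  ok <- ok & !is.na(r_tag)

  rc_rp <- revcomp(scheme$reverse_primer)
  tail_len <- nchar(rc_rp) + nchar(r_tag)
  has_rp <- rep(FALSE, n)
  has_rp[ok] <- substr(reads[ok], nchar(reads[ok]) - tail_len[ok] + 1L,
                       nchar(reads[ok]) - nchar(r_tag[ok])) == rc_rp
  reason[ok & !has_rp] <- "reverse_primer"
  ok <- ok & has_rp

  head_len <- nchar(f_tag) + nchar(fp)
  insert <- rep(NA_character_, n)
  insert[ok] <- substr(reads[ok], head_len[ok] + 1L,
                       nchar(reads[ok]) - tail_len[ok])

  amb <- ok & grepl("[^ACGT]", insert)
  reason[amb] <- "ambiguous"
  ok <- ok & !amb

  bad_len <- ok & nchar(insert) != expected_length
  reason[bad_len] <- "length"
  ok <- ok & !bad_len

  key <- paste(f_tag, r_tag)
  akey <- paste(scheme$assignment$fwd_mid, scheme$assignment$rev_mid)
  ind <- scheme$assignment$individual[match(key, akey)]
  unas <- ok & is.na(ind)
  reason[unas] <- "unassigned"
  ok <- ok & !unas

  structure(list(
    assignments = data.frame(read_id = ids[ok], individual = ind[ok],
                             insert = insert[ok], stringsAsFactors = FALSE),
    discards = data.frame(read_id = ids[!ok], reason = reason[!ok],
                          stringsAsFactors = FALSE),
    n_input = n
  ), class = "demux_result")
}

#' @export
print.demux_result <- function(x, ...) {
  cat(sprintf("Demultiplexed %d reads: %d retained, %d discarded\n",
              x$n_input, nrow(x$assignments), nrow(x$discards)))
  if (nrow(x$discards)) {
    tb <- table(x$discards$reason)
    cat("  discard reasons:", paste(names(tb), tb, sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tabulate sequence variants and their maximum per-amplicon frequency
#'
#' Collapses retained inserts into one variant per distinct sequence, with
#' per-individual read counts. The MPAF of a variant is the maximum, over
#' all individuals carrying it, of the variant's share of that individual's
#' total retained reads; it is the primary criterion separating true alleles
#' from PCR/sequencing artifacts.
#'
#' @param x a [demultiplex()] result, or a data frame with columns
#'   `individual` and `insert`.
#' @return list of class `variant_table`: `variants` (variant id, sequence,
#'   mpaf, n_carriers, ordered by decreasing MPAF), `counts` (variants x
#'   individuals integer matrix) and `depths` (per-individual totals).
#' @export
tabulate_variants <- function(x) {
  a <- if (inherits(x, "demux_result")) x$assignments else x
  if (nrow(a) == 0) {
    return(structure(list(
      variants = data.frame(variant_id = character(0), sequence = character(0),
                            mpaf = numeric(0), n_carriers = integer(0)),
      counts = matrix(0L, 0, 0), depths = integer(0)), class = "variant_table"))
  }
  tab <- table(a$insert, a$individual)
  counts <- matrix(as.integer(tab), nrow(tab),
                   dimnames = list(rownames(tab), colnames(tab)))
  depths <- colSums(counts)
  props <- sweep(counts, 2, pmax(depths, 1L), "/")
  mpaf <- apply(props, 1, max)
  n_carriers <- as.integer(rowSums(counts > 0))

  ord <- order(-mpaf, rownames(counts))
  counts <- counts[ord, , drop = FALSE]
  variants <- data.frame(
    variant_id = sprintf("V%04d", seq_len(nrow(counts))),
    sequence = rownames(counts),
    mpaf = mpaf[ord],
    n_carriers = n_carriers[ord],
    row.names = NULL, stringsAsFactors = FALSE
  )
  rownames(counts) <- variants$variant_id
  structure(list(variants = variants, counts = counts, depths = depths),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("Variant table: %d variants across %d individuals\n",
              nrow(x$variants), length(x$depths)))
  if (nrow(x$variants)) {
    cat(sprintf("  MPAF range: %.4g - %.4g\n",
                min(x$variants$mpaf), max(x$variants$mpaf)))
  }
  invisible(x)
}

#' Classify amplicon variants as true alleles or artifact classes
#'
#' Deterministic decision ladder, applied per variant:
#' \enumerate{
#'   \item `mpaf < mpaf_floor`: discarded outright (`BELOW_FLOOR`).
#'   \item `mpaf >= mpaf_true_threshold`, no internal stop codon in the
#'     configured frame, and either at least two carriers or confirmation in
#'     a replicate pair: `TRUE_ALLELE`. Sequences matching `known_alleles`
#'     are whitelisted as `TRUE_ALLELE` regardless (previously characterized
#'     alleles serve as a validation baseline).
#'   \item remaining variants are triaged, most conservative rule first:
#'     within 1-2 substitutions of a `TRUE_ALLELE` that co-occurs in every
#'     carrier (`ONE_TWO_BP_ARTIFACT`); internal stop codon (`STOP_CODON`);
#'     trimmed length not a multiple of 3 (`FRAMESHIFT`); a single carrier
#'     (`SINGLETON`); present in no carrier's duplicate when replicate data
#'     exist (`UNVERIFIED`); otherwise `CANDIDATE` (reported for manual
#'     review, excluded from genotype calls).
#' }
#' "1-2 bp difference" is taken as Hamming distance of at most 2; reads with
#' indels never reach this stage because length filtering removes them.
#'
#' @param vt a [tabulate_variants()] result.
#' @param mpaf_true_threshold MPAF at or above which a clean variant is a
#'   true allele (default 0.04: characterized true alleles occur in carriers
#'   at 4 percent or more of the amplicon's reads).
#' @param mpaf_floor MPAF below which variants are discarded outright.
#' @param frame_offset reading-frame offset (0, 1, 2) for stop-codon checks.
#' @param replicate_pairs optional data frame with columns `id1`, `id2`
#'   listing duplicate sample pairs.
#' @param known_alleles optional named character vector of previously
#'   validated allele sequences.
#' @return data frame of class `variant_classification`: variant id,
#'   sequence, mpaf, n_carriers, `allele_name` (the known-allele name where
#'   matched, else the variant id), `label`, `evidence` (the rule that
#'   fired). Attributes record the parameters.
#' @export
classify_variants <- function(vt, mpaf_true_threshold = 0.04, mpaf_floor = 0.001,
                              frame_offset = 2, replicate_pairs = NULL,
                              known_alleles = NULL) {
  stopifnot(inherits(vt, "variant_table"))
  if (!(mpaf_true_threshold > 0 && mpaf_true_threshold < 1)) {
    stop("mpaf_true_threshold must be in (0, 1)")
  }
  if (!(mpaf_floor > 0 && mpaf_floor < mpaf_true_threshold)) {
    stop("mpaf_floor must be in (0, mpaf_true_threshold)")
  }
  if (!frame_offset %in% 0:2) stop("frame_offset must be 0, 1 or 2")

  v <- vt$variants
  n <- nrow(v)
  label <- rep(NA_character_, n)
  evidence <- rep(NA_character_, n)
  allele_name <- v$variant_id

  tr <- lapply(v$sequence, translate_and_flag, frame_offset = frame_offset)
  has_stop <- vapply(tr, `[[`, logical(1), "has_internal_stop")
  frame_ok <- vapply(tr, `[[`, logical(1), "frame_ok")

  carriers <- lapply(seq_len(n), function(i) {
    colnames(vt$counts)[vt$counts[i, ] > 0]
  })

  rep_confirmed <- rep(FALSE, n)
  if (!is.null(replicate_pairs) && nrow(replicate_pairs) > 0) {
    for (i in seq_len(n)) {
      cs <- carriers[[i]]
      rep_confirmed[i] <- any(replicate_pairs$id1 %in% cs &
                                replicate_pairs$id2 %in% cs)
    }
  }

  known_hit <- rep(FALSE, n)
  if (!is.null(known_alleles)) {
    m <- match(v$sequence, unname(known_alleles))
    known_hit <- !is.na(m)
    allele_name[known_hit] <- names(known_alleles)[m[known_hit]]
  }

  below <- v$mpaf < mpaf_floor & !known_hit
  label[below] <- "BELOW_FLOOR"
  evidence[below] <- sprintf("mpaf %.5f < floor %.5f", v$mpaf[below], mpaf_floor)

  promoted <- !below & (known_hit |
    (v$mpaf >= mpaf_true_threshold & !has_stop &
       (v$n_carriers >= 2 | rep_confirmed)))
  label[promoted] <- "TRUE_ALLELE"
  evidence[promoted] <- ifelse(known_hit[promoted],
    "matches a previously characterized allele",
    sprintf("mpaf %.4f >= %.4f, ORF clean, %d carriers%s",
            v$mpaf[promoted], mpaf_true_threshold, v$n_carriers[promoted],
            ifelse(rep_confirmed[promoted], " (replicate-confirmed)", "")))

  true_idx <- which(promoted)
  pending <- which(is.na(label))
  has_reps <- !is.null(replicate_pairs) && nrow(replicate_pairs) > 0
  dup_of <- if (has_reps) {
    stats::setNames(c(replicate_pairs$id2, replicate_pairs$id1),
                    c(replicate_pairs$id1, replicate_pairs$id2))
  } else character(0)

  for (i in pending) {
    cs <- carriers[[i]]
    # (a) 1-2 bp shadow of a co-occurring true allele
    parent <- NA_character_
    for (j in true_idx) {
      if (nchar(v$sequence[i]) == nchar(v$sequence[j]) &&
          hamming(v$sequence[i], v$sequence[j]) <= 2 &&
          all(vt$counts[j, cs] > 0)) {
        parent <- allele_name[j]
        break
      }
    }
    if (!is.na(parent)) {
      label[i] <- "ONE_TWO_BP_ARTIFACT"
      evidence[i] <- sprintf("<= 2 substitutions from parental true allele %s present in all %d carrier(s)",
                             parent, length(cs))
    } else if (has_stop[i]) {
      label[i] <- "STOP_CODON"
      evidence[i] <- "premature stop codon in frame"
    } else if (!frame_ok[i]) {
      label[i] <- "FRAMESHIFT"
      evidence[i] <- "trimmed length not a positive multiple of 3"
    } else if (v$n_carriers[i] == 1) {
      label[i] <- "SINGLETON"
      evidence[i] <- "present in a single individual"
    } else if (has_reps && any(cs %in% names(dup_of)) &&
               all(vt$counts[i, intersect(unname(dup_of[cs]), colnames(vt$counts))] == 0)) {
      label[i] <- "UNVERIFIED"
      evidence[i] <- "absent from every carrier's duplicate sample"
    } else {
      label[i] <- "CANDIDATE"
      evidence[i] <- "no artifact rule fired; flagged for manual review"
    }
  }

  out <- data.frame(variant_id = v$variant_id, sequence = v$sequence,
                    mpaf = v$mpaf, n_carriers = v$n_carriers,
                    allele_name = allele_name, label = label,
                    evidence = evidence, stringsAsFactors = FALSE)
  structure(out,
            mpaf_true_threshold = mpaf_true_threshold, mpaf_floor = mpaf_floor,
            frame_offset = frame_offset,
            class = c("variant_classification", "data.frame"))
}

#' Call per-individual MHC genotypes from classified variants
#'
#' Individuals whose total retained reads fall below `min_depth` are
#' discarded as unreliable; for the rest, the called allele set consists of
#' the `TRUE_ALLELE` variants present at or above `mpaf_true_threshold` of
#' that individual's reads. Individuals with fewer than 2 or more than 5
#' called alleles are flagged. The maximum called set size also implies a
#' lower bound on the number of co-amplifying diploid loci
#' (`ceiling(max/2)`, see [implied_min_loci()]).
#'
#' @param vt a [tabulate_variants()] result.
#' @param classification the matching [classify_variants()] result.
#' @param min_depth minimum retained reads per individual (default 150).
#' @param mpaf_true_threshold per-individual proportion required for an
#'   allele to be called; defaults to the classification's threshold.
#' @param populations optional named vector mapping individual to population.
#' @return data frame of class `mhc_calls`: individual, population, alleles
#'   (semicolon-joined), `allele_set` list column, n_alleles, depth, status
#'   (`CALLED`/`DISCARDED_LOW_DEPTH`), flag.
#' @export
call_genotypes <- function(vt, classification, min_depth = 150,
                           mpaf_true_threshold = NULL, populations = NULL) {
  stopifnot(inherits(vt, "variant_table"),
            inherits(classification, "variant_classification"))
  if (!all(classification$variant_id %in% rownames(vt$counts)) &&
      nrow(classification) > 0) {
    stop("classification does not cover this variant table")
  }
  thr <- mpaf_true_threshold %||% attr(classification, "mpaf_true_threshold")
  true_ids <- classification$variant_id[classification$label == "TRUE_ALLELE"]
  true_names <- classification$allele_name[classification$label == "TRUE_ALLELE"]

  inds <- names(vt$depths)
  sets <- vector("list", length(inds))
  status <- character(length(inds))
  flags <- character(length(inds))
  for (i in seq_along(inds)) {
    d <- vt$depths[[i]]
    if (d < min_depth) {
      status[i] <- "DISCARDED_LOW_DEPTH"
      sets[[i]] <- character(0)
      flags[i] <- sprintf("depth %d < %d", d, min_depth)
      next
    }
    status[i] <- "CALLED"
    prop <- vt$counts[true_ids, inds[i]] / d
    called <- sort(true_names[prop >= thr])
    sets[[i]] <- called
    flags[i] <- if (length(called) < 2) "fewer than 2 alleles"
                else if (length(called) > 5) "more than 5 alleles"
                else ""
  }

  pop <- if (is.null(populations)) rep(NA_character_, length(inds))
         else unname(populations[inds])
  out <- data.frame(individual = inds, population = pop,
                    alleles = vapply(sets, paste, "", collapse = ";"),
                    n_alleles = lengths(sets),
                    depth = unname(vt$depths), status = status, flag = flags,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$allele_set <- sets
  class(out) <- c("mhc_calls", "data.frame")
  out
}

#' @export
print.mhc_calls <- function(x, ...) {
  called <- x$status == "CALLED"
  cat(sprintf("MHC genotype calls: %d individuals (%d called, %d discarded for low depth)\n",
              nrow(x), sum(called), sum(!called)))
  if (any(called)) {
    cat(sprintf("  alleles per called individual: %d-%d (implied minimum loci: %d)\n",
                min(x$n_alleles[called]), max(x$n_alleles[called]),
                implied_min_loci(x)))
  }
  invisible(x)
}

#' Minimum number of diploid loci implied by a maximum allele count
#'
#' A diploid locus contributes at most two distinct alleles, so observing up
#' to `m` distinct alleles within one individual implies at least
#' `ceiling(m / 2)` co-amplifying loci.
#'
#' @param x an `mhc_calls` table (the maximum is taken over CALLED
#'   individuals), an `mhc_geno` table, or a plain integer maximum.
#' @return integer lower bound on the locus count.
#' @export
implied_min_loci <- function(x) {
  m <- if (inherits(x, "mhc_calls")) {
    max(x$n_alleles[x$status == "CALLED"], 0L)
  } else if (inherits(x, "mhc_geno")) {
    max(lengths(x$alleles))
  } else {
    as.integer(x)
  }
  as.integer(ceiling(m / 2))
}

#' Concordance between two replicate genotyping runs
#'
#' @param calls_run1,calls_run2 `mhc_calls` tables, or named lists of allele
#'   sets, covering the same individual ids.
#' @return list of class `concordance`: `n_pairs`, `complete_matches`
#'   (identical sets), `partial_matches` (overlapping but unequal),
#'   `zero_matches` (disjoint), `complete_pct` (rounded to integer percent,
#'   half away from zero).
#' @export
replicate_concordance <- function(calls_run1, calls_run2) {
  as_sets <- function(x) {
    if (inherits(x, "mhc_calls")) {
      stats::setNames(x$allele_set, x$individual)
    } else if (inherits(x, "mhc_geno")) {
      stats::setNames(x$alleles, x$individual)
    } else if (is.list(x)) {
      x
    } else stop("cannot interpret calls input")
  }
  s1 <- as_sets(calls_run1)
  s2 <- as_sets(calls_run2)
  only1 <- setdiff(names(s1), names(s2))
  only2 <- setdiff(names(s2), names(s1))
  if (length(only1) || length(only2)) {
    stop("runs cover different individuals: ",
         paste(c(only1, only2), collapse = ", "))
  }
  ids <- names(s1)
  complete <- partial <- zero <- 0L
  for (id in ids) {
    a <- sort(unique(s1[[id]]))
    b <- sort(unique(s2[[id]]))
    if (identical(a, b)) complete <- complete + 1L
    else if (length(intersect(a, b)) > 0) partial <- partial + 1L
    else zero <- zero + 1L
  }
  structure(list(n_pairs = length(ids), complete_matches = complete,
                 partial_matches = partial, zero_matches = zero,
                 complete_pct = as.integer(round_half_up(100 * complete / length(ids)))),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("Replicate concordance over %d pairs: %d complete (%d%%), %d partial, %d zero\n",
              x$n_pairs, x$complete_matches, x$complete_pct,
              x$partial_matches, x$zero_matches))
  invisible(x)
}

#' Translate an amplicon insert and flag stop codons and frame problems
#'
#' Trims `frame_offset` leading bases and any trailing remainder, translates
#' with the standard genetic code, and reports whether a stop codon occurs
#' before the final codon (`has_internal_stop`) and whether the trimmed
#' length is a positive multiple of 3 (`frame_ok`). A terminal stop is not
#' included in the returned protein.
#'
#' @param sequence a single ACGT string.
#' @param frame_offset 0, 1 or 2.
#' @return list with `protein`, `has_internal_stop`, `frame_ok`, `n_codons`.
#' @export
translate_and_flag <- function(sequence, frame_offset = 0) {
  if (length(sequence) != 1 || is.na(sequence) || !nzchar(sequence)) {
    stop("sequence must be a single non-empty string")
  }
  if (!frame_offset %in% 0:2) stop("frame_offset must be 0, 1 or 2")
  s <- toupper(sequence)
  if (grepl("[^ACGT]", s)) stop("sequence must contain only A, C, G, T")
  trimmed <- substr(s, frame_offset + 1L, nchar(s))
  n_cod <- nchar(trimmed) %/% 3L
  frame_ok <- n_cod > 0L && nchar(trimmed) %% 3L == 0L
  if (n_cod == 0L) {
    return(list(protein = "", has_internal_stop = FALSE, frame_ok = FALSE,
                n_codons = 0L))
  }
  aa <- unname(Biostrings::GENETIC_CODE[split_codons(trimmed)])
  has_internal_stop <- n_cod > 1L && any(aa[-n_cod] == "*")
  protein <- paste(if (aa[n_cod] == "*") aa[-n_cod] else aa, collapse = "")
  list(protein = protein, has_internal_stop = has_internal_stop,
       frame_ok = frame_ok, n_codons = n_cod)
}
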