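make_scheme <- function() {
  tag_scheme(
    forward_mids = c("ACGTACGTAA", "GGTTCCAAGG"),
    reverse_mids = c("TTGGCCAATT", "CCAATTGGCC"),
    forward_primer = "GTGACC",
    reverse_primer = "CCAGTT",
    assignment = data.frame(
      individual = c("i1", "i2"),
      fwd_mid = c("ACGTACGTAA", "GGTTCCAAGG"),
      rev_mid = c("TTGGCCAATT", "TTGGCCAATT"),
      stringsAsFactors = FALSE
    )
  )
}

wrap_read <- function(insert, fwd = "ACGTACGTAA", rev = "TTGGCCAATT",
                      scheme = make_scheme()) {
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  paste0(fwd, scheme$forward_primer, insert, rc(scheme$reverse_primer), rc(rev))
}

test_that("demultiplexing retains clean reads and logs one reason per discard", {
  scheme <- make_scheme()
  ins <- paste(rep("ACGT", 5), collapse = "")          # 20 bp clean insert
  reads <- c(
    good      = wrap_read(ins),
    ambig     = wrap_read(sub("A", "N", ins)),
    short     = wrap_read(substr(ins, 1, 19)),
    no_fwd    = paste0("TTTTTTTTTT", scheme$forward_primer, ins, "AACTGG",
                       "AATTGGCCAA"),
    bad_prim  = wrap_read(ins) |> sub(pattern = "GTGACC", replacement = "GTGACG"),
    unassign  = wrap_read(ins, fwd = "GGTTCCAAGG", rev = "CCAATTGGCC")
  )
  dm <- demultiplex(reads, scheme, expected_length = 20)

  expect_equal(nrow(dm$assignments) + nrow(dm$discards), length(reads))
  expect_equal(dm$assignments$individual, "i1")
  expect_equal(dm$assignments$insert, ins)

  reasons <- stats::setNames(dm$discards$reason, dm$discards$read_id)
  expect_equal(unname(reasons["ambig"]), "ambiguous")
  expect_equal(unname(reasons["short"]), "length")
  expect_equal(unname(reasons["no_fwd"]), "forward_tag")
  expect_equal(unname(reasons["bad_prim"]), "forward_primer")
  expect_equal(unname(reasons["unassign"]), "unassigned")
})

test_that("variant tabulation computes MPAF over per-individual read totals", {
  # one individual, identical reads: single variant at MPAF 1
  a <- data.frame(individual = rep("i1", 100),
                  insert = rep("AAAA", 100), stringsAsFactors = FALSE)
  vt <- tabulate_variants(a)
  expect_equal(nrow(vt$variants), 1)
  expect_equal(vt$variants$mpaf, 1)
  expect_equal(vt$variants$n_carriers, 1L)

  # hand arithmetic: 15/300 in i1, 60/400 in i2 -> mpaf = 0.15
  a2 <- data.frame(
    individual = c(rep("i1", 300), rep("i2", 400)),
    insert = c(rep("AAAA", 15), rep("CCCC", 285),
               rep("AAAA", 60), rep("CCCC", 340)),
    stringsAsFactors = FALSE
  )
  vt2 <- tabulate_variants(a2)
  v <- vt2$variants[vt2$variants$sequence == "AAAA", ]
  expect_equal(v$mpaf, 0.15)
  expect_equal(v$n_carriers, 2L)

  # order invariance and duplication invariance of MPAF
  vt2b <- tabulate_variants(a2[sample(nrow(a2)), ])
  expect_equal(vt2b$variants, vt2$variants)
  vt2c <- tabulate_variants(rbind(a2, a2))
  expect_equal(vt2c$variants$mpaf, vt2$variants$mpaf)
  expect_true(all(vt2$variants$mpaf <= 1))

  expect_equal(nrow(tabulate_variants(a2[0, ])$variants), 0)
})

test_that("the classification ladder fires the documented rules in order", {
  # Construct variants by hand: an in-frame 12-mer world (frame 0).
  true_seq  <- "ATGAAACCCGGG"          # clean ORF
  shadow    <- "ATGAAACCCGGT"          # 1 bp from true_seq
  stopv     <- "ATGTAATTTGGG"          # internal stop (TAA), 4 bp from true_seq
  lonely    <- "ATGAAACCCTTT"          # 3 bp from true, single carrier, clean ORF
  dust      <- "ATGAAATTTTTT"

  a <- data.frame(
    individual = c(rep("i1", 2000), rep("i2", 1000)),
    insert = c(rep(true_seq, 1879), rep(shadow, 60), rep(stopv, 60), rep(dust, 1),
               rep(true_seq, 950), rep(stopv, 30), rep(lonely, 20)),
    stringsAsFactors = FALSE
  )
  vt <- tabulate_variants(a)
  cls <- classify_variants(vt, mpaf_true_threshold = 0.04, mpaf_floor = 0.001,
                           frame_offset = 0)
  lab <- stats::setNames(cls$label, cls$sequence)
  expect_equal(unname(lab[true_seq]), "TRUE_ALLELE")
  expect_equal(unname(lab[shadow]), "ONE_TWO_BP_ARTIFACT")
  expect_equal(unname(lab[stopv]), "STOP_CODON")
  expect_equal(unname(lab[lonely]), "SINGLETON")
  expect_equal(unname(lab[dust]), "BELOW_FLOOR")

  # classification is deterministic
  expect_identical(cls, classify_variants(vt, 0.04, 0.001, 0))

  # replicate confirmation promotes a single-carrier-pair variant;
  # replicate absence demotes to UNVERIFIED
  reps <- data.frame(id1 = "i1", id2 = "i2", stringsAsFactors = FALSE)
  b <- data.frame(
    individual = c(rep("i1", 100), rep("i2", 100), rep("i3", 100)),
    insert = c(rep(true_seq, 95), rep("CCCAAACCCGGG", 5),
               rep(true_seq, 95), rep("CCCAAACCCGGG", 5),
               rep(true_seq, 97), rep("GGGTTTAAAGGG", 3)),
    stringsAsFactors = FALSE
  )
  vtb <- tabulate_variants(b)
  clsb <- classify_variants(vtb, 0.04, 0.001, 0,
                            replicate_pairs = data.frame(id1 = c("i1", "i3"),
                                                         id2 = c("i2", "i4")))
  labb <- stats::setNames(clsb$label, clsb$sequence)
  expect_equal(unname(labb["CCCAAACCCGGG"]), "TRUE_ALLELE")
  # i3's variant is >= 4 bp from any true allele, single carrier
  expect_equal(unname(labb["GGGTTTAAAGGG"]), "SINGLETON")

  expect_error(classify_variants(vt, frame_offset = 5), "frame_offset")
  expect_error(classify_variants(vt, mpaf_floor = 0.5), "mpaf_floor")
})

test_that("genotype calling applies the depth rule and MPAF-eligible alleles", {
  cfg <- small_config(seed = 21, read_model = list(
    mean_depth = 500, per_base_error_rate = 0, chimera_rate = 0,
    noise_variant_rate = 0, depth_dispersion = 5))
  pool <- build_allele_pool(cfg)
  truth <- simulate_genotypes(pool, cfg)
  rs <- simulate_reads(truth, cfg)
  dm <- demultiplex(rs$reads, rs$scheme, cfg$amplicon_length)
  vt <- tabulate_variants(dm)
  cls <- classify_variants(vt, frame_offset = cfg$frame_offset,
                           known_alleles = pool)
  calls <- call_genotypes(vt, cls, min_depth = 150)

  low <- calls[calls$depth < 150, ]
  expect_true(all(low$status == "DISCARDED_LOW_DEPTH"))
  called <- calls[calls$status == "CALLED", ]
  expect_true(all(called$depth >= 150))

  # noiseless recovery: called sets equal the simulation truth exactly
  sets <- stats::setNames(truth$mhc$alleles, truth$mhc$individual)
  for (r in seq_len(nrow(called))) {
    expect_identical(called$allele_set[[r]], sets[[called$individual[r]]])
  }

  # an explicit low-depth individual
  vt93 <- tabulate_variants(data.frame(
    individual = rep("lowguy", 93), insert = rep(pool[[1]], 93),
    stringsAsFactors = FALSE))
  cls93 <- classify_variants(vt93, frame_offset = cfg$frame_offset,
                             known_alleles = pool)
  c93 <- call_genotypes(vt93, cls93, min_depth = 150)
  expect_equal(c93$status, "DISCARDED_LOW_DEPTH")
})

test_that("a five-allele maximum implies at least three diploid loci", {
  expect_equal(implied_min_loci(5), 3L)
  expect_equal(implied_min_loci(4), 2L)
  expect_equal(implied_min_loci(toy_mhc()), 3L)  # one individual carries 5
})

test_that("replicate concordance counts complete, partial and zero matches", {
  # 42 pairs: 37 identical, 5 overlapping-unequal -> 88%, zero = 0
  ids <- sprintf("s%02d", 1:42)
  run1 <- sets_named(ids, c(replicate(37, c("A01", "A02"), simplify = FALSE),
                            replicate(5, c("A01", "A03"), simplify = FALSE)))
  run2 <- run1
  for (k in 38:42) run2[[k]] <- c("A01", "A04")
  cc <- replicate_concordance(run1, run2)
  expect_equal(cc$n_pairs, 42L)
  expect_equal(cc$complete_matches, 37L)
  expect_equal(cc$partial_matches, 5L)
  expect_equal(cc$zero_matches, 0L)
  expect_equal(cc$complete_pct, 88L)

  # identity and disjoint limits
  expect_equal(replicate_concordance(run1, run1)$complete_pct, 100L)
  run3 <- lapply(run1, function(s) c("Z01", "Z02"))
  cc3 <- replicate_concordance(run1, run3)
  expect_equal(cc3$zero_matches, 42L)
  expect_equal(cc3$complete_pct, 0L)

  expect_error(replicate_concordance(run1, run2[1:10]), "different individuals")
})

test_that("translation flags internal stops and frame problems", {
  t1 <- translate_and_flag("ATGAAATAG", 0)
  expect_equal(t1$protein, "MK")
  expect_false(t1$has_internal_stop)
  expect_true(t1$frame_ok)

  t2 <- translate_and_flag("ATGTAAAAA", 0)
  expect_true(t2$has_internal_stop)

  seq185 <- paste(rep("A", 2), collapse = "")
  seq185 <- paste0("GG", strrep("ATG", 61))   # 2 + 183 = 185 bp
  t3 <- translate_and_flag(seq185, 2)
  expect_equal(t3$n_codons, 61L)
  expect_true(t3$frame_ok)

  t4 <- translate_and_flag("GGATGAA", 2)      # trimmed length 5: not multiple of 3
  expect_false(t4$frame_ok)

  expect_error(translate_and_flag("", 0), "non-empty")
  expect_error(translate_and_flag("ATGN", 0), "only A, C, G, T")
})
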