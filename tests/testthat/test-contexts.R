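test_that("trinucleotide channels collapse purine-centred sites onto the pyrimidine strand", {
  ref <- ref_seq(c("1" = "ACGTA"))
  rec <- toy_catalog("S1", "1", 3, ref = "G", alt = "A")
  expect_equal(trinucleotide_context(rec, ref), "A[C>T]G")

  ref2 <- ref_seq(c("1" = "TCA"))
  rec2 <- toy_catalog("S1", "1", 2, ref = "C", alt = "T")
  expect_equal(trinucleotide_context(rec2, ref2), "T[C>T]A")

  # all four central bases map to a pyrimidine-centred label
  ref3 <- ref_seq(c("1" = "AAACCCGGGTTTA"))
  for (p in 2:12) {
    b <- substr(unclass(ref3)[["1"]], p, p)
    alt <- setdiff(c("A", "C", "G", "T"), b)[1]
    ch <- trinucleotide_context(toy_catalog("S1", "1", p, ref = b, alt = alt), ref3)
    expect_match(ch, "\\[(C|T)>", info = paste("pos", p))
  }
})

test_that("reference mismatch is a data error carrying the locus", {
  ref <- ref_seq(c("1" = "ACGTA"))
  rec <- toy_catalog("S9", "1", 3, ref = "T", alt = "A")
  expect_error(trinucleotide_context(rec, ref), "S9 1:3",
               class = "apobecscope_data_error")
})

test_that("N or edge contexts are skipped with a warning, or error under strict mode", {
  ref <- ref_seq(c("1" = "NCGTA"))
  rec <- toy_catalog("S1", "1", 2, ref = "C", alt = "T")
  expect_warning(ch <- mutation_channels(rec, ref), "skipped")
  expect_true(is.na(ch))
  expect_error(mutation_channels(rec, ref, strict_n = TRUE),
               class = "apobecscope_data_error")
  edge <- toy_catalog("S1", "1", 5, ref = "A", alt = "G")
  expect_warning(ch_edge <- mutation_channels(edge, ref), "skipped")
  expect_true(is.na(ch_edge))
})

test_that("strand involution: mirrored reverse-complement reference leaves channels unchanged", {
  set.seed(42)
  ref <- generate_reference(1, 3000, seed = 11)
  cat <- simulate_background(ref, synthetic_signatures(), c(SBS_FLAT = 1),
                             n_samples = 1, snvs_per_sample = 80, seed = 12)
  ch_fwd <- mutation_channels(cat, ref)
  L <- ref_lengths(ref)[[1]]
  ref_rc <- ref_seq(stats::setNames(revcomp(unclass(ref)[["1"]]), "1"))
  cat_rc <- data.table::copy(cat)
  cat_rc$pos <- L - cat$pos + 1L
  cat_rc$ref <- chartr("ACGT", "TGCA", cat$ref)
  cat_rc$alt <- chartr("ACGT", "TGCA", cat$alt)
  ch_rc <- mutation_channels(cat_rc, ref_rc)
  expect_equal(ch_fwd, ch_rc)
})

test_that("spectrum counts conserve totals and pool additively over samples", {
  ref <- ref_seq(c("1" = "ATCAGTCAA"))
  cat <- toy_catalog(c("S1", "S2"), "1", c(3, 7), ref = "C", alt = c("T", "G"))
  sp <- build_spectrum(cat, ref)
  expect_equal(sp$total, 2L)
  expect_equal(sum(sp$counts > 0), 2L)
  expect_equal(names(sp$counts), sbs_channels())

  mat <- per_sample_spectra(cat, ref)
  expect_equal(unname(rowSums(mat)), unname(as.numeric(sp$counts)))

  # point-mass catalog: all counts in one channel
  sig1 <- local({
    m <- matrix(0, 96, 1, dimnames = list(sbs_channels(), "PM"))
    m["A[C>T]G", 1] <- 1
    signature_catalog(m)
  })
  ref2 <- generate_reference(1, 20000, seed = 3)
  cat2 <- simulate_background(ref2, sig1, c(PM = 1), 1, 50, seed = 4)
  sp2 <- build_spectrum(cat2, ref2)
  expect_equal(unname(sp2$counts["A[C>T]G"]), 50L)
  expect_equal(sp2$total, 50L)
})

test_that("class summary proportions and degenerate cases", {
  cat <- toy_catalog("S1", "1", c(10, 20, 30, 40), ref = "C",
                     alt = c("T", "T", "T", "A"))
  cs <- class_summary(cat)
  ct <- cs$snv_class[cs$snv_class$snv_class == "C>T", ]
  expect_equal(ct$proportion, 0.75)
  expect_equal(sum(cs$snv_class$proportion), 1)

  ins_only <- toy_catalog("S1", "1", 10, ref = "-", alt = "ATT",
                          variant_type = "INS")
  cs2 <- class_summary(ins_only)
  expect_true(all(cs2$snv_class$empty))
  expect_true(all(is.na(cs2$snv_class$proportion)))
})

test_that("catalog subtraction keys on (chrom, pos, ref, alt) presence only", {
  control <- toy_catalog("control", "1", c(10, 20, 30), ref = "C", alt = "T")
  treated <- data.table::copy(control); treated$sample_id <- "treated"
  expect_equal(nrow(subtract_catalog(treated, control)), 0L)

  # same position, different alt -> retained
  t2 <- rbind(treated, toy_catalog("treated", "1", 20, ref = "C", alt = "G"))
  d <- subtract_catalog(t2, control)
  expect_equal(nrow(d), 1L)
  expect_equal(d$alt, "G")
  expect_equal(d$sample_id, "treated")

  multi <- rbind(treated, toy_catalog("treated2", "1", 99))
  expect_error(subtract_catalog(multi, control), class = "apobecscope_data_error")
})

test_that("subtraction recovers exactly the simulated additions", {
  ref <- generate_reference(2, 50000, seed = 21)
  sigs <- synthetic_signatures()
  pl <- simulate_paired_lines(ref, sigs, n_baseline = 300, n_added = 500, seed = 22)
  diff <- subtract_catalog(pl$treated, pl$control)
  expect_equal(nrow(diff), nrow(pl$truth))
  expect_identical(diff, pl$truth)
  expect_equal(nrow(pl$treated), nrow(pl$control) + nrow(pl$truth))

  pl0 <- simulate_paired_lines(ref, sigs, n_baseline = 100, n_added = 0, seed = 23)
  expect_equal(nrow(subtract_catalog(pl0$treated, pl0$control)), 0L)
})
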