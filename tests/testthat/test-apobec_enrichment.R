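test_that("enrichment score formula matches the hand-evaluated example", {
  expect_equal(enrichment_score(8, 10, 20, 100), 4.0)
  expect_true(is.na(enrichment_score(0, 0, 20, 100)))
  expect_identical(enrichment_score(3, 10, 0, 100), Inf)
})

test_that("per-sample counts agree with an independent string-scan oracle", {
  ref <- generate_reference(1, 4000, seed = 31)
  cat <- simulate_background(ref, synthetic_signatures(), c(SBS_FLAT = 1),
                             n_samples = 1, snvs_per_sample = 60, seed = 32)
  res <- motif_enrichment(cat, ref, motif = "TCW", flank = 20)
  s <- unclass(ref)[["1"]]; L <- nchar(s)
  rc <- revcomp(s)
  cx <- cat[cat$ref %in% c("C", "G"), ]
  mut_motif <- 0; ctx_motif <- 0; ctx_C <- 0
  for (i in seq_len(nrow(cx))) {
    p <- cx$pos[i]
    tri <- if (cx$ref[i] == "C") substr(s, p - 1, p + 1) else
      revcomp(substr(s, p - 1, p + 1))
    if (grepl("^TC[AT]$", tri)) mut_motif <- mut_motif + 1
    win_lo <- max(1, p - 20); win_hi <- min(L, p + 20)
    for (q in win_lo:win_hi) {
      if (abs(q - p) %in% c(1, 2)) next
      if (substr(s, q, q) %in% c("C", "G")) ctx_C <- ctx_C + 1
    }
    # motif availability: every cytosine centre inside the window whose
    # full trinucleotide (read off the reference) matches tCw on either
    # strand; positions within 2 bp of the mutated base are excluded from
    # both counts (their motif status is fixed by the mutated base)
    for (q in max(2, win_lo):min(L - 1, win_hi)) {
      if (abs(q - p) %in% c(1, 2)) next
      w3 <- substr(s, q - 1, q + 1)
      if (grepl("^TC[AT]$", w3) || grepl("^TC[AT]$", revcomp(w3))) {
        ctx_motif <- ctx_motif + 1
      }
    }
  }
  expect_equal(res$mut_C, nrow(cx))
  expect_equal(res$mut_motif, mut_motif)
  expect_equal(res$ctx_C, ctx_C)
  expect_equal(res$ctx_motif, ctx_motif)
  expect_equal(res$E, enrichment_score(mut_motif, nrow(cx), ctx_motif, ctx_C))
})

test_that("the trivial motif C scores exactly 1 and the CC motif reads the 5' neighbour", {
  ref <- generate_reference(1, 3000, seed = 33)
  cat <- simulate_background(ref, synthetic_signatures(), c(SBS_FLAT = 1),
                             n_samples = 2, snvs_per_sample = 40, seed = 34)
  res <- motif_enrichment(cat, ref, motif = "C", flank = 15)
  expect_equal(res$E, rep(1, nrow(res)))
  expect_equal(res$mut_motif, res$mut_C)
  expect_equal(res$ctx_motif, res$ctx_C)

  # CC: mutated C preceded by C on the pyrimidine strand
  ref2 <- ref_seq(c("1" = "AACCTAAGGA"))
  rec <- toy_catalog("S1", "1", c(4, 8), ref = c("C", "G"), alt = c("T", "A"))
  res2 <- motif_enrichment(rec, ref2, motif = "CC", flank = 2)
  # pos 4: CC context (C at 3); pos 8 is G with 3' G -> collapsed 5' C too
  expect_equal(res2$mut_motif, 2L)
})

test_that("E is near 1 when mutations land uniformly on cytosines", {
  ref <- generate_reference(1, 1e6, seed = 35)
  s <- unclass(ref)[["1"]]
  cpos <- which(strsplit(s, "")[[1]] %in% c("C", "G"))
  cpos <- cpos[cpos > 1 & cpos < nchar(s)]
  set.seed(36)
  pick <- sort(sample(cpos, 3000))
  b <- substring(s, pick, pick)
  alt <- ifelse(b == "C", sample(c("A", "G", "T"), length(pick), TRUE),
                sample(c("T", "C", "A"), length(pick), TRUE))
  cat <- toy_catalog("S1", "1", pick, ref = b, alt = alt)
  res <- motif_enrichment(cat, ref, motif = "TCW", flank = 20)
  p_exp <- res$ctx_motif / res$ctx_C
  p_obs <- res$mut_motif / res$mut_C
  se <- sqrt(p_exp * (1 - p_exp) / res$mut_C)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("E is invariant to reverse-complementing the reference", {
  ref <- generate_reference(1, 5000, seed = 37)
  cat <- simulate_background(ref, synthetic_signatures(), c(SBS_APOBEC = 1),
                             n_samples = 1, snvs_per_sample = 50, seed = 38)
  res <- motif_enrichment(cat, ref, motif = "TCW", flank = 20)
  L <- ref_lengths(ref)[[1]]
  ref_rc <- ref_seq(stats::setNames(revcomp(unclass(ref)[["1"]]), "1"))
  cat_rc <- data.table::copy(cat)
  cat_rc$pos <- L - cat$pos + 1L
  cat_rc$ref <- chartr("ACGT", "TGCA", cat$ref)
  cat_rc$alt <- chartr("ACGT", "TGCA", cat$alt)
  res_rc <- motif_enrichment(cat_rc, ref_rc, motif = "TCW", flank = 20)
  expect_equal(res$E, res_rc$E)
  expect_equal(res$mut_motif, res_rc$mut_motif)
})

test_that("samples without C>X mutations are flagged not-evaluable", {
  ref <- ref_seq(c("1" = "ATATATATAT"))
  cat <- toy_catalog("S1", "1", c(3, 5), ref = "A", alt = "G")
  res <- motif_enrichment(cat, ref)
  expect_false(res$evaluable)
  expect_true(is.na(res$E))
  expect_warning(classify_enriched(res), "evaluable")
  part <- suppressWarnings(classify_enriched(res))
  expect_length(part$enriched, 0)
  expect_equal(part$not_evaluable, "S1")
})

test_that("classification uses a strict threshold", {
  res <- data.table::data.table(sample_id = c("A", "B", "C"),
                                E = c(1.0, 2.0, 2.5), evaluable = TRUE)
  part <- classify_enriched(res, threshold = 2)
  expect_equal(part$enriched, "C")
  expect_setequal(part$non_enriched, c("A", "B"))
})

test_that("per-gene Fisher test matches the hypergeometric hand computation", {
  cat <- toy_catalog(sprintf("E%d", 1:5), "1", 101:105, gene = "PCSK5")
  cat <- rbind(cat, toy_catalog(sprintf("N%d", 1:5), "1", 201:205, gene = "OTHER"))
  part <- list(enriched = sprintf("E%d", 1:5), non_enriched = sprintf("N%d", 1:5))
  gd <- compare_groups(cat, part)
  row <- gd$genes[gd$genes$gene == "PCSK5", ]
  expect_identical(row$odds_ratio, Inf)
  expect_equal(row$p, 2 / 252, tolerance = 1e-12)  # two-sided Fisher on [[5,0],[0,5]]

  # identical groups: mutation pattern independent of the grouping -> q = 1
  cat2 <- rbind(toy_catalog(sprintf("E%d", 1:4), "1", 101:104, gene = "G1"),
                toy_catalog(sprintf("N%d", 1:4), "1", 101:104, gene = "G1"))
  gd2 <- compare_groups(cat2, list(enriched = sprintf("E%d", 1:4),
                                   non_enriched = sprintf("N%d", 1:4)))
  expect_true(all(gd2$genes$q > 0.999))
})

test_that("a doubled mutation burden is detected by the rank-sum comparison", {
  set.seed(40)
  reject <- 0L
  for (rep in 1:100) {
    ne <- rpois(30, 60); nn <- rpois(30, 30)
    cat <- data.table::rbindlist(c(
      lapply(1:30, function(i) toy_catalog(sprintf("E%02d", i), "1",
                                           sample.int(1e6, ne[i]))),
      lapply(1:30, function(i) toy_catalog(sprintf("N%02d", i), "1",
                                           sample.int(1e6, nn[i])))))
    gd <- suppressWarnings(
      compare_groups(cat, list(enriched = sprintf("E%02d", 1:30),
                               non_enriched = sprintf("N%02d", 1:30))))
    if (gd$burden$p < 0.01) reject <- reject + 1L
  }
  expect_gte(reject, 90L)
})
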