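test_that("reference generation is deterministic, honours GC and rejects bad lengths", {
  r1 <- generate_reference(1, 1000, seed = 1)
  r2 <- generate_reference(1, 1000, seed = 1)
  expect_identical(unclass(r1), unclass(r2))
  r3 <- generate_reference(1, 1000, seed = 2)
  expect_false(identical(unclass(r1), unclass(r3)))

  gc1 <- generate_reference(1, 500, gc = 1, seed = 3)
  expect_false(grepl("[AT]", unclass(gc1)[["1"]]))
  gc0 <- generate_reference(1, 500, gc = 0, seed = 3)
  expect_false(grepl("[GC]", unclass(gc0)[["1"]]))

  expect_error(generate_reference(1, 0, seed = 1), class = "apobecscope_data_error")
})

test_that("a degenerate mixture produces only its channel, deterministically", {
  sig1 <- local({
    m <- matrix(0, 96, 1, dimnames = list(sbs_channels(), "PM"))
    m["A[C>T]G", 1] <- 1
    signature_catalog(m)
  })
  ref <- generate_reference(1, 30000, seed = 5)
  c1 <- simulate_background(ref, sig1, c(PM = 1), 1, 100, seed = 6)
  c2 <- simulate_background(ref, sig1, c(PM = 1), 1, 100, seed = 6)
  expect_identical(c1, c2)
  expect_equal(unique(mutation_channels(c1, ref)), "A[C>T]G")
  expect_false(any(duplicated(c1$pos)))  # placement without replacement
})

test_that("a channel without eligible sites errors by name", {
  sig1 <- local({
    m <- matrix(0, 96, 1, dimnames = list(sbs_channels(), "PM"))
    m["A[C>T]G", 1] <- 1
    signature_catalog(m)
  })
  ref <- ref_seq(c("1" = "TTTTTTTTTT"))
  expect_error(simulate_background(ref, sig1, c(PM = 1), 1, 5, seed = 1),
               "A\\[C>T\\]G", class = "apobecscope_data_error")
})

test_that("empirical channel frequencies converge to the mixture", {
  sigs <- synthetic_signatures(c("SBS_APOBEC", "SBS_FLAT"))
  ref <- generate_reference(2, 2e5, seed = 7)
  n <- 10000
  cat <- simulate_background(ref, sigs, c(SBS_APOBEC = 0.5, SBS_FLAT = 0.5),
                             n_samples = 1, snvs_per_sample = n, seed = 8)
  counts <- build_spectrum(cat, ref)$counts
  p <- as.numeric(sigs$matrix %*% c(0.5, 0.5))
  se <- sqrt(n * p * (1 - p))
  dev <- abs(as.numeric(counts) - n * p)
  expect_true(all(dev[p > 0] <= 3 * se[p > 0] + 1e-9))
  expect_true(all(counts[p == 0] == 0))

  # chi-square goodness of fit is not rejected at alpha = 0.01
  gof <- suppressWarnings(chisq.test(as.numeric(counts[p > 0]), p = p[p > 0],
                                     rescale.p = TRUE))
  expect_gt(gof$p.value, 0.01)
})

test_that("injected clusters conserve counts and record their truth spans", {
  ref <- generate_reference(1, 2e5, seed = 9)
  base <- simulate_background(ref, synthetic_signatures(), c(SBS_FLAT = 1),
                              n_samples = 1, snvs_per_sample = 20, seed = 10)
  spec <- list(list(n_clusters = 3L, cluster_size = 6L, imd_mean = 200,
                    tpc_fraction = 0.5, c_to_t_fraction = 0.5))
  inj <- inject_kataegis(base, ref, spec, seed = 11)
  expect_equal(nrow(inj$truth), 3L)
  expect_equal(nrow(inj$records), 18L)
  expect_equal(nrow(inj$catalog), nrow(base) + 18L)
  for (i in 1:3) {
    members <- inj$records[inj$records$chrom == inj$truth$chrom[i] &
                             inj$records$pos >= inj$truth$start[i] &
                             inj$records$pos <= inj$truth$end[i] &
                             inj$records$sample_id == inj$truth$sample_id[i], ]
    expect_gte(nrow(members), 6L)
  }
  # truth spans lie within the reference
  expect_true(all(inj$truth$end <= ref_lengths(ref)[inj$truth$chrom]))
})

test_that("a pure TpC->TpT spec injects only T[C>T]N mutations", {
  ref <- generate_reference(1, 2e5, seed = 12)
  base <- simulate_background(ref, synthetic_signatures(), c(SBS_FLAT = 1),
                              n_samples = 1, snvs_per_sample = 10, seed = 13)
  spec <- list(list(n_clusters = 2L, cluster_size = 8L, imd_mean = 150,
                    tpc_fraction = 1, c_to_t_fraction = 1))
  inj <- inject_kataegis(base, ref, spec, seed = 14)
  ch <- mutation_channels(inj$records, ref)
  expect_true(all(grepl("^T\\[C>T\\]", ch)))
  expect_equal(inj$truth$class, rep("tpc_to_tpt", 2))
})

test_that("clusters that cannot fit a contig are an error", {
  ref <- ref_seq(c("1" = paste(rep("ACGT", 25), collapse = "")))  # 100 bp
  base <- toy_catalog("S1", "1", 10)
  spec <- list(list(n_clusters = 1L, cluster_size = 10L, imd_mean = 500,
                    tpc_fraction = 0, c_to_t_fraction = 0))
  expect_error(inject_kataegis(base, ref, spec, seed = 1),
               class = "apobecscope_data_error")
})

test_that("the detector recovers injected showers on a sparse background", {
  recalls <- numeric(3)
  for (i in 1:3) {
    ref <- generate_reference(1, 1e6, seed = 100 + i)
    base <- simulate_background(ref, synthetic_signatures(), c(SBS_FLAT = 1),
                                n_samples = 1, snvs_per_sample = 100,
                                seed = 200 + i)
    spec <- list(list(n_clusters = 5L, cluster_size = 8L, imd_mean = 200,
                      tpc_fraction = 0.9, c_to_t_fraction = 0.8))
    inj <- inject_kataegis(base, ref, spec, seed = 300 + i)
    reg <- detect_kataegis(inj$catalog)
    hit <- vapply(seq_len(nrow(inj$truth)), function(k) {
      any(reg$chrom == inj$truth$chrom[k] &
            reg$start <= inj$truth$end[k] & reg$end >= inj$truth$start[k])
    }, logical(1))
    recalls[i] <- mean(hit)
  }
  expect_true(all(recalls >= 0.95))
})

test_that("paired-line generation shares the baseline and skews additions to tCw", {
  ref <- generate_reference(2, 1e5, seed = 15)
  sigs <- synthetic_signatures()
  pl <- simulate_paired_lines(ref, sigs, n_baseline = 200, n_added = 2000, seed = 16)
  expect_equal(nrow(pl$treated), nrow(pl$control) + nrow(pl$truth))
  added <- subtract_catalog(pl$treated, pl$control)
  fit <- fit_exposures(build_spectrum(added, ref), sigs)
  expect_gte(unname(fit$weights["SBS_APOBEC"]), 0.9)
})

test_that("cohort tables honour the censoring-rate extremes and record truth", {
  s0 <- simulate_cohort_tables(n_samples = 50, censoring_rate = 0, seed = 17)
  expect_true(all(s0$survival$event == 1L))
  s1 <- simulate_cohort_tables(n_samples = 50, censoring_rate = 1, seed = 17)
  expect_true(all(s1$survival$event == 0L))
  expect_error(logrank_test(s1$survival[1:25, ], s1$survival[26:50, ]),
               class = "apobecscope_data_error")
  expect_true(all(s0$survival$time > 0))
  expect_equal(s0$truth$true_hr, 3)
  expect_equal(nrow(s0$truth$group), 50)
})

test_that("the full cohort generator is deterministic and internally consistent", {
  cfg <- sim_config(seed = 42, n_samples = 6, background_snvs_per_sample = 50,
                    ref_length_per_contig = 1e5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$catalog, b$catalog)
  expect_identical(a$expression, b$expression)
  expect_setequal(unique(a$catalog$sample_id), a$expression$sample_id)
  expect_true(all(a$cluster_truth$sample_id %in% a$expression$sample_id))
  # high group receives more clusters than the low group
  high <- a$group_truth$sample_id[a$group_truth$high]
  n_high <- sum(a$cluster_truth$sample_id %in% high)
  n_low <- nrow(a$cluster_truth) - n_high
  if (length(high) > 0 && length(high) < 6) expect_gte(n_high, n_low)
})
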