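test_that("rainfall distances are per-chromosome, per-sample chains", {
  cat <- toy_catalog("S1", "1", c(100, 300, 1300))
  rf <- rainfall(cat, "S1")
  expect_equal(rf$imd, c(NA, 200, 1000))

  cat2 <- rbind(toy_catalog("S1", "1", c(100, 250)),
                toy_catalog("S1", "2", 500),
                toy_catalog("S2", "1", 180))
  rf2 <- rainfall(cat2, "S1")
  expect_equal(rf2$imd, c(NA, 150, NA))  # chain resets at chromosome 2
  rf3 <- rainfall(cat2, "S2")
  expect_equal(rf3$imd, NA_integer_)     # never crosses samples
})

test_that("detection respects the k_min and mean-IMD boundaries", {
  # 5 mutations 100 bp apart: k_min unmet
  c5 <- toy_catalog("S1", "1", seq(100, 500, by = 100))
  expect_equal(nrow(detect_kataegis(c5)), 0L)

  # 6 mutations with mean gap 500
  c6 <- toy_catalog("S1", "1", seq(1000, 3500, by = 500))
  r <- detect_kataegis(c6)
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, 1000L); expect_equal(r$end, 3500L)
  expect_equal(r$n_mut, 6L); expect_equal(r$mean_imd, 500)

  # mean gap exactly 1000 qualifies ("less than or equal to")
  cb <- toy_catalog("S1", "1", seq(1000, 6000, by = 1000))
  rb <- detect_kataegis(cb)
  expect_equal(nrow(rb), 1L)
  expect_equal(rb$mean_imd, 1000)

  # mean gap just over the bound does not
  co <- toy_catalog("S1", "1", c(seq(1000, 5000, by = 1000), 6010))
  expect_equal(nrow(detect_kataegis(co)), 0L)
})

test_that("regions never span chromosomes or samples", {
  cat <- rbind(toy_catalog("S1", "1", seq(100, 600, by = 100)),
               toy_catalog("S1", "2", seq(100, 600, by = 100)),
               toy_catalog("S2", "1", seq(1100, 1600, by = 100)))
  r <- detect_kataegis(cat)
  expect_equal(nrow(r), 3L)
  expect_equal(sort(paste(r$sample_id, r$chrom)), c("S1 1", "S1 2", "S2 1"))
})

test_that("detector equals the exhaustive enumeration oracle on random catalogs", {
  for (seed in 1:8) {
    set.seed(seed)
    pos <- random_positions(n_uniform = 350, n_clusters = 4, cluster_size = 9)
    got <- detect_kataegis(toy_catalog("S1", "1", pos))
    want <- oracle_kataegis(pos, 6, 1000)
    expect_equal(nrow(got), length(want), info = paste("seed", seed))
    if (length(want)) {
      expect_equal(got$start, vapply(want, `[`, numeric(1), 1))
      expect_equal(got$end, vapply(want, `[`, numeric(1), 2))
      expect_equal(got$n_mut, as.integer(vapply(want, `[`, numeric(1), 3)))
      expect_true(all(got$mean_imd <= 1000))
    }
  }
})

test_that("relaxing d_max or k_min never loses regions", {
  set.seed(77)
  for (rep in 1:5) {
    pos <- random_positions(n_uniform = 300, n_clusters = 3)
    cat <- toy_catalog("S1", "1", pos)
    n_base <- nrow(detect_kataegis(cat, config = kataegis_config(6, 1000)))
    expect_gte(nrow(detect_kataegis(cat, config = kataegis_config(6, 2000))), n_base)
    expect_gte(nrow(detect_kataegis(cat, config = kataegis_config(5, 1000))), n_base)
  }
})

test_that("C>X density classification applies the strict > 5 per kb rule", {
  regions <- data.table::data.table(sample_id = "S1", chrom = "1",
                                    start = c(1001L, 5001L), end = c(2000L, 7000L),
                                    n_mut = c(7L, 8L), mean_imd = c(166, 285))
  ref <- generate_reference(1, 10000, seed = 50)
  s <- unclass(ref)[["1"]]
  mk <- function(lo, hi, n) {
    cand <- which(strsplit(substr(s, lo, hi), "")[[1]] %in% c("C", "G")) + lo - 1
    p <- cand[seq(1, length(cand), length.out = n)]
    b <- substring(s, p, p)
    toy_catalog("S1", "1", p, ref = b, alt = ifelse(b == "C", "T", "A"))
  }
  cat <- rbind(mk(1001, 2000, 7), mk(5001, 7000, 8))
  cls <- classify_regions(regions, cat, ref)
  expect_equal(cls$n_ctox, c(7L, 8L))
  expect_equal(cls$ctox_density, c(7.0, 4.0))
  expect_equal(cls$is_ctox_enriched, c(TRUE, FALSE))
})

test_that("strict TpC class requires every member to be TpC->TpX", {
  ref <- ref_seq(c("1" = paste(rep("ATCG", 50), collapse = "")))
  # C at positions 3,7,11,...: always preceded by T
  p <- seq(3, 23, by = 4)
  cat <- toy_catalog("S1", "1", p, ref = "C", alt = "T")
  reg <- detect_kataegis(cat)
  expect_equal(nrow(reg), 1L)
  cls <- classify_regions(reg, cat, ref)
  expect_true(cls$is_strict_tpc)
  expect_equal(cls$n_ctox, cls$n_mut)  # class partition invariant

  # break one member: a T>G at position 6 is not a C>X
  cat2 <- rbind(cat, toy_catalog("S1", "1", 6, ref = "T", alt = "G"))
  reg2 <- detect_kataegis(cat2)
  cls2 <- classify_regions(reg2, cat2, ref)
  expect_false(any(cls2$is_strict_tpc))
})

test_that("gene annotation is inclusive-overlap with stable ordering", {
  genes <- data.table::data.table(chrom = "1", start = c(150L, 190L, 201L),
                                  end = c(300L, 195L, 300L),
                                  gene = c("A", "B", "C"), strand = "*")
  regions <- data.table::data.table(sample_id = "S1", chrom = "1",
                                    start = 100L, end = 200L)
  ann <- annotate_genes(regions, genes)
  expect_equal(ann$genes, "A,B")  # C starts at 201: no overlap with 100-200
  none <- annotate_genes(data.table::data.table(sample_id = "S1", chrom = "1",
                                                start = 500L, end = 600L), genes)
  expect_equal(none$genes, "")
})

test_that("per-sample counts and proportions are conserved", {
  regions <- data.table::data.table(
    sample_id = c("S1", "S1", "S1", "S2"), chrom = "1",
    start = c(1L, 100L, 200L, 1L), end = c(50L, 150L, 250L, 50L),
    n_mut = 6L, mean_imd = 100,
    is_ctox_enriched = c(TRUE, FALSE, FALSE, TRUE),
    is_strict_tpc = c(FALSE, FALSE, FALSE, TRUE))
  pc <- per_sample_counts(regions)
  s1 <- pc[pc$sample_id == "S1", ]
  expect_equal(s1$total, 3L)
  expect_equal(s1$ctox_enriched, 1L)
  expect_equal(s1$prop_enriched, 1 / 3)
  empty <- per_sample_counts(regions, samples = c("S1", "S2", "S3"))
  expect_equal(empty$total[empty$sample_id == "S3"], 0L)
  expect_true(is.na(empty$prop_enriched[empty$sample_id == "S3"]))
})

test_that("count-expression correlation handles exact ranks and degenerate input", {
  counts <- data.table::data.table(sample_id = sprintf("P%d", 1:6),
                                   ctox_enriched = 1:6)
  expr <- data.table::data.table(sample_id = sprintf("P%d", 1:6),
                                 expression = c(10, 20, 30, 40, 50, 60))
  res <- correlate_counts_with_expression(counts, expr)
  expect_equal(res$r, 1.0)
  expect_equal(res$method, "spearman")

  const <- data.table::copy(counts); const$ctox_enriched <- 3L
  res2 <- correlate_counts_with_expression(const, expr)
  expect_true(res2$degenerate)
  expect_true(is.na(res2$r))
})

test_that("expression-extreme subgroup comparison checks sizes and localises effects", {
  expr <- data.table::data.table(sample_id = sprintf("P%02d", 1:10),
                                 expression = 1:10)
  regions <- data.table::data.table(
    sample_id = rep(sprintf("P%02d", 7:10), each = 2), chrom = "1",
    start = 100L, end = 200L, n_mut = 6L, mean_imd = 50,
    is_ctox_enriched = TRUE, is_strict_tpc = FALSE, genes = "NES")
  sg <- compare_subgroups(regions, expr, top_n = 4, bottom_n = 4)
  expect_setequal(sg$subgroups$high, sprintf("P%02d", 7:10))
  tab <- sg$totals$table
  expect_true(all(tab$total[tab$subgroup == "low"] == 0))
  expect_equal(sg$genes$n_high[sg$genes$gene == "NES"], 8L)
  expect_equal(sg$genes$n_low[sg$genes$gene == "NES"], 0L)

  expect_error(compare_subgroups(regions, expr, top_n = 6, bottom_n = 6),
               class = "apobecscope_data_error")
})
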