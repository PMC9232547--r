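#' Kataegis detection parameters
#'
#' Defaults follow the standard working definition of putative kataegis:
#' six or more consecutive mutations with mean intermutational distance at
#' or below 1000 bp; C>X-enriched regions carry more than 5 C>X
#' conversions per 1000 bp of span.
#'
#' @param k_min minimum mutations per region (>= 2).
#' @param d_max maximum mean intermutational distance in bp.
#' @param ctox_density_min strict lower bound (exclusive) on C>X conversions
#'   per 1000 bp for the enriched class.
#' @return list of class `kataegis_config`.
#' @export
kataegis_config <- function(k_min = 6L, d_max = 1000, ctox_density_min = 5) {
  if (k_min < 2L) stop_data("k_min must be >= 2")
  if (d_max <= 0) stop_data("d_max must be > 0")
  if (ctox_density_min < 0) stop_data("ctox_density_min must be >= 0")
  structure(list(k_min = as.integer(k_min), d_max = d_max,
                 ctox_density_min = ctox_density_min),
            class = "kataegis_config")
}

#' Rainfall table of intermutational distances
#'
#' For one sample, orders SNVs per chromosome and computes each mutation's
#' distance to the previous mutation on the same chromosome (undefined,
#' `NA`, for the first per chromosome). Distances never chain across
#' samples or chromosomes.
#'
#' @param catalog a mutation catalog.
#' @param sample sample id.
#' @return `data.table` with `sample_id`, `chrom`, `pos`, `imd`,
#'   `snv_class` (6-class pyrimidine-collapsed label).
#' @export
rainfall <- function(catalog, sample) {
  validate_catalog(catalog)
  if (!sample %in% catalog$sample_id) stop_data("sample not in catalog: ", sample)
  snv <- catalog[catalog$sample_id == sample & catalog$variant_type == "SNP", ]
  data.table::setorderv(snv, c("chrom", "pos"))
  imd <- unlist(lapply(split(snv$pos, snv$chrom), function(p) c(NA, diff(p))),
                use.names = FALSE)
  # split() orders groups by chrom name, matching the sort above
  data.table::data.table(sample_id = sample, chrom = snv$chrom, pos = snv$pos,
                         imd = imd, snv_class = snv_class6(snv$ref, snv$alt))
}

# Core single-chromosome detector: returns list of index ranges (start, end)
# into the sorted position vector. A region is a maximal merge of windows of
# >= k_min consecutive mutations whose mean gap is <= d_max; merged regions
# violating the mean-gap bound themselves are split at their largest gap and
# re-detected, so every reported region satisfies mean_imd <= d_max.
detect_runs <- function(pos, k_min, d_max) {
  n <- length(pos)
  if (n < k_min) return(list())
  # per start index, the longest qualifying window (union of nested windows)
  max_len <- integer(n)
  for (L in k_min:n) {
    i <- seq_len(n - L + 1L)
    ok <- (pos[i + L - 1L] - pos[i]) <= d_max * (L - 1L)
    max_len[i[ok]] <- L
  }
  starts <- which(max_len > 0L)
  if (!length(starts)) return(list())
  ends <- starts + max_len[starts] - 1L
  # merge windows sharing at least one mutation
  merged <- list()
  cs <- starts[1]; ce <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= ce) ce <- max(ce, ends[i])
    else { merged[[length(merged) + 1L]] <- c(cs, ce); cs <- starts[i]; ce <- ends[i] }
  }
  merged[[length(merged) + 1L]] <- c(cs, ce)
  # re-check merged regions; split at the largest gap and recurse when the
  # merged mean gap exceeds d_max
  out <- list()
  for (r in merged) {
    s <- r[1]; e <- r[2]
    if ((pos[e] - pos[s]) <= d_max * (e - s)) {
      out[[length(out) + 1L]] <- c(s, e)
    } else {
      gaps <- diff(pos[s:e])
      cut <- which.max(gaps)  # first largest gap
      left <- detect_runs(pos[s:(s + cut - 1L)], k_min, d_max)
      right <- detect_runs(pos[(s + cut):e], k_min, d_max)
      for (x in left) out[[length(out) + 1L]] <- x + s - 1L
      for (x in right) out[[length(out) + 1L]] <- x + s + cut - 1L
    }
  }
  out
}

#' Detect kataegis regions
#'
#' Scans each chromosome of each requested sample for maximal runs of
#' consecutive mutations containing a window of at least `k_min` mutations
#' whose mean intermutational gap is at most `d_max`. Overlapping
#' qualifying windows are merged; a merged region whose own mean gap
#' exceeds `d_max` is split at its largest gap until every reported region
#' satisfies the bound. Regions never span chromosomes or samples.
#'
#' @param catalog a mutation catalog (SNVs are used).
#' @param sample sample id, or `NULL` for every sample.
#' @param config a [kataegis_config()].
#' @return `data.table` of regions: `sample_id`, `chrom`, `start`, `end`
#'   (positions of the first and last member mutation, 1-based inclusive),
#'   `n_mut`, `mean_imd`.
#' @export
detect_kataegis <- function(catalog, sample = NULL, config = kataegis_config()) {
  validate_catalog(catalog)
  snv <- catalog[catalog$variant_type == "SNP", ]
  if (!is.null(sample)) snv <- snv[snv$sample_id %in% sample, ]
  if (nrow(snv) == 0L) {
    return(data.table::data.table(sample_id = character(), chrom = character(),
                                  start = integer(), end = integer(),
                                  n_mut = integer(), mean_imd = numeric()))
  }
  data.table::setorderv(snv, c("sample_id", "chrom", "pos"))
  groups <- split(snv, paste(snv$sample_id, snv$chrom, sep = "\r"))
  out <- data.table::rbindlist(lapply(groups, function(g) {
    pos <- unique(g$pos)
    runs <- detect_runs(pos, config$k_min, config$d_max)
    if (!length(runs)) return(NULL)
    data.table::rbindlist(lapply(runs, function(r) {
      p <- pos[r[1]:r[2]]
      data.table::data.table(sample_id = g$sample_id[1], chrom = g$chrom[1],
                             start = p[1], end = p[length(p)],
                             n_mut = length(p),
                             mean_imd = (p[length(p)] - p[1]) / (length(p) - 1L))
    }))
  }))
  if (nrow(out) == 0L) {
    return(data.table::data.table(sample_id = character(), chrom = character(),
                                  start = integer(), end = integer(),
                                  n_mut = integer(), mean_imd = numeric()))
  }
  data.table::setorderv(out, c("sample_id", "chrom", "start"))
  out[]
}

#' Classify kataegis regions by C>X content
#'
#' Fills the C>X statistics of detected regions from their member records:
#' `n_ctox` counts pyrimidine-collapsed C>X members (a G-centred mutation
#' counts through its reverse complement), `ctox_density` is C>X mutations
#' per 1000 bp of span (first-to-last member position inclusive; a
#' single-position span counts as 1 bp), `is_ctox_enriched` applies the
#' strict `> ctox_density_min` rule, and `is_strict_tpc` is true when every
#' member is a C>X whose collapsed 5' neighbour is T (TpC->TpX).
#'
#' @param regions output of [detect_kataegis()].
#' @param catalog the catalog the regions were detected in.
#' @param ref a [ref_seq] reference (for the TpC check).
#' @param config a [kataegis_config()].
#' @return the regions table with columns `n_ctox`, `ctox_density`,
#'   `is_ctox_enriched`, `is_strict_tpc` added.
#' @export
classify_regions <- function(regions, catalog, ref, config = kataegis_config()) {
  validate_catalog(catalog)
  snv <- catalog[catalog$variant_type == "SNP", ]
  regions <- data.table::copy(regions)
  n <- nrow(regions)
  regions$n_ctox <- integer(n)
  regions$ctox_density <- numeric(n)
  regions$is_ctox_enriched <- logical(n)
  regions$is_strict_tpc <- logical(n)
  if (n == 0L) return(regions)
  contigs <- unclass(ref)
  for (i in seq_len(n)) {
    mem <- snv[snv$sample_id == regions$sample_id[i] &
                 snv$chrom == regions$chrom[i] &
                 snv$pos >= regions$start[i] & snv$pos <= regions$end[i], ]
    is_ctox <- mem$ref %in% c("C", "G")
    span <- max(1L, regions$end[i] - regions$start[i] + 1L)
    regions$n_ctox[i] <- sum(is_ctox)
    regions$ctox_density[i] <- sum(is_ctox) * 1000 / span
    regions$is_ctox_enriched[i] <- regions$ctox_density[i] > config$ctox_density_min
    strict <- all(is_ctox) && nrow(mem) > 0L
    if (strict) {
      s <- contigs[[regions$chrom[i]]]
      # collapsed 5' neighbour: base before a C, complement of base after a G
      prev5 <- ifelse(mem$ref == "C",
                      contig_bases(s, mem$pos - 1L),
                      chartr("ACGT", "TGCA", contig_bases(s, mem$pos + 1L)))
      strict <- all(!is.na(prev5) & prev5 == "T")
    }
    regions$is_strict_tpc[i] <- strict
  }
  regions
}

#' Annotate kataegis regions with overlapping genes
#'
#' A gene is attached when its interval overlaps the region span by at
#' least 1 bp; names are listed comma-separated in (chrom, start) order.
#'
#' @param regions a region table (needs `chrom`, `start`, `end`).
#' @param genes gene intervals from [read_bed_genes()].
#' @return regions with a `genes` column (empty string when none overlap).
#' @export
annotate_genes <- function(regions, genes) {
  regions <- data.table::copy(regions)
  if (nrow(regions) == 0L) { regions$genes <- character(0); return(regions) }
  q <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(regions$start, regions$end))
  s <- GenomicRanges::GRanges(genes$chrom,
                              IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(q, s)
  gl <- rep("", nrow(regions))
  if (length(hits)) {
    byq <- split(genes$gene[S4Vectors::subjectHits(hits)],
                 S4Vectors::queryHits(hits))
    for (k in names(byq)) gl[as.integer(k)] <- paste(unique(byq[[k]]), collapse = ",")
  }
  regions$genes <- gl
  regions
}

#' Per-sample kataegis counts
#'
#' @param regions classified region table (see [classify_regions()]).
#' @param samples optional sample-id vector to force zero rows for samples
#'   without regions.
#' @return `data.table` per sample: `total`, `ctox_enriched`, `strict_tpc`,
#'   `prop_enriched` (`NA` when total is 0).
#' @export
per_sample_counts <- function(regions, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(regions$sample_id))
  data.table::rbindlist(lapply(samples, function(s) {
    r <- regions[regions$sample_id == s, ]
    tot <- nrow(r)
    data.table::data.table(
      sample_id = s, total = tot,
      ctox_enriched = if ("is_ctox_enriched" %in% names(r)) sum(r$is_ctox_enriched) else NA_integer_,
      strict_tpc = if ("is_strict_tpc" %in% names(r)) sum(r$is_strict_tpc) else NA_integer_,
      prop_enriched = if (tot > 0 && "is_ctox_enriched" %in% names(r)) {
        sum(r$is_ctox_enriched) / tot
      } else NA_real_)
  }))
}

#' Correlate per-sample kataegis counts with expression
#'
#' @param counts output of [per_sample_counts()].
#' @param expression expression table ([read_expression_table()]).
#' @param which counts column to correlate (default `"ctox_enriched"`).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return list with `r`, `p`, `n`, `method`, and `degenerate = TRUE` with
#'   `NA` statistics when either variable is constant.
#' @export
correlate_counts_with_expression <- function(counts, expression,
                                             which = "ctox_enriched",
                                             method = c("spearman", "pearson")) {
  method <- match.arg(method)
  merged <- merge(counts, expression, by = "sample_id")
  if (nrow(merged) < 3L) stop_data("need >= 3 paired samples for a correlation")
  x <- as.numeric(merged[[which]]); y <- merged$expression
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(r = NA_real_, p = NA_real_, n = nrow(merged), method = method,
                degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(merged),
       method = method, degenerate = FALSE)
}

#' Compare kataegis distribution between expression extremes
#'
#' Contrasts the `top_n` samples with the highest expression against the
#' `bottom_n` with the lowest: per-sample totals (total regions,
#' C>X-enriched regions, enriched proportion) with rank-sum p-values, and —
#' when regions are gene-annotated — per-gene, per-class region counts and
#' per-sample means in each subgroup.
#'
#' @param regions classified (optionally gene-annotated) region table.
#' @param expression expression table covering the cohort.
#' @param top_n,bottom_n subgroup sizes (default 25 each).
#' @return list with `subgroups` (sample membership), `totals` (per-sample
#'   counts with subgroup label and p-values) and `genes` (per-gene
#'   subgroup table, `NULL` if regions lack a `genes` column).
#' @export
compare_subgroups <- function(regions, expression, top_n = 25L, bottom_n = 25L) {
  n <- nrow(expression)
  if (top_n + bottom_n > n) {
    stop_data("top_n + bottom_n (", top_n + bottom_n,
              ") exceeds cohort size (", n, ")")
  }
  ord <- order(expression$expression, decreasing = TRUE)
  high <- expression$sample_id[ord[seq_len(top_n)]]
  low <- expression$sample_id[rev(ord)[seq_len(bottom_n)]]
  counts <- per_sample_counts(regions, samples = c(high, low))
  counts$subgroup <- ifelse(counts$sample_id %in% high, "high", "low")
  pvals <- vapply(c("total", "ctox_enriched", "prop_enriched"), function(col) {
    x <- counts[[col]][counts$subgroup == "high"]
    y <- counts[[col]][counts$subgroup == "low"]
    if (all(is.na(x)) || all(is.na(y))) return(NA_real_)
    suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
  }, numeric(1))

  gene_tab <- NULL
  if ("genes" %in% names(regions)) {
    reg <- regions[regions$sample_id %in% c(high, low) & regions$genes != "", ]
    if (nrow(reg)) {
      long <- reg[, .(gene = unlist(strsplit(genes, ",", fixed = TRUE))),
                  by = .(sample_id, is_ctox_enriched)]
      long$subgroup <- ifelse(long$sample_id %in% high, "high", "low")
      gene_tab <- long[, .(
        n_high = sum(subgroup == "high"),
        n_low = sum(subgroup == "low"),
        n_high_enriched = sum(subgroup == "high" & is_ctox_enriched),
        n_low_enriched = sum(subgroup == "low" & is_ctox_enriched)),
        by = gene]
      gene_tab$mean_high <- gene_tab$n_high / top_n
      gene_tab$mean_low <- gene_tab$n_low / bottom_n
      data.table::setorderv(gene_tab, "n_high", order = -1L)
    }
  }
  list(subgroups = list(high = high, low = low),
       totals = list(table = counts, p = pvals),
       genes = gene_tab)
}
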