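IUPAC_CLASS <- c(A = "A", C = "C", G = "G", T = "T", W = "[AT]", S = "[CG]",
                 R = "[AG]", Y = "[CT]", K = "[GT]", M = "[AC]", B = "[CGT]",
                 D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")

motif_regex <- function(motif) {
  ch <- strsplit(toupper(motif), "", fixed = TRUE)[[1]]
  if (!all(ch %in% names(IUPAC_CLASS))) {
    stop_data("motif contains non-IUPAC characters: ", motif)
  }
  paste(IUPAC_CLASS[ch], collapse = "")
}

count_matches <- function(s, regex) {
  # overlapping matches via lookahead
  m <- gregexpr(paste0("(?=", regex, ")"), s, perl = TRUE)[[1]]
  if (length(m) == 1L && m[1] == -1L) 0L else length(m)
}

# Start positions (1-based, within s) of overlapping regex matches.
match_starts <- function(s, regex) {
  m <- gregexpr(paste0("(?=", regex, ")"), s, perl = TRUE)[[1]]
  if (length(m) == 1L && m[1] == -1L) integer(0) else as.integer(m)
}

#' Fold-enrichment score from motif and cytosine counts
#'
#' The enrichment-score formula on already-assembled counts:
#' `E = (mut_motif * ctx_C) / (mut_C * ctx_motif)`.
#'
#' @param mut_motif C>X mutations whose neighbourhood matches the motif.
#' @param mut_C all C>X mutations.
#' @param ctx_motif motif occurrences in the context windows.
#' @param ctx_C cytosines in the context windows.
#' @return the score E (`NA` when `mut_C` is 0, `Inf` when `ctx_motif` is 0
#'   with `mut_motif > 0`).
#' @export
enrichment_score <- function(mut_motif, mut_C, ctx_motif, ctx_C) {
  if (mut_C == 0) return(NA_real_)
  if (ctx_motif == 0) return(if (mut_motif > 0) Inf else NA_real_)
  (mut_motif * ctx_C) / (mut_C * ctx_motif)
}

#' APOBEC motif enrichment score per sample
#'
#' For each sample, computes the fold enrichment of motif-context C>X
#' mutations relative to the motif's availability in the sequence
#' surrounding the mutations:
#'
#' \deqn{E = \frac{mut_{motif} \times ctx_C}{mut_C \times ctx_{motif}}}
#'
#' where `mut_C` counts all C>X mutations of the sample (pyrimidine-
#' collapsed, so G-centred sites count via their reverse complement),
#' `mut_motif` those whose immediate neighbourhood matches the motif on the
#' pyrimidine strand, `ctx_C` the cytosines (both strands) within `flank` bp
#' of each mutated site, and `ctx_motif` the motif occurrences (both
#' strands) in the same windows. Windows are clipped at contig ends and are
#' not deduplicated when they overlap — each mutation contributes its own
#' window. Window positions closer than the motif length to the mutated
#' base (the mutated site itself excepted) are left out of both context
#' counts: their motif status is constrained by the mutated base, and
#' counting them biases E upward under uniform mutation placement.
#'
#' The motif is an IUPAC string containing the mutated cytosine; when the
#' motif has several `C`s the mutated position is the last one (so `"CC"`
#' reads "C preceded by C", `"TCW"` is the canonical APOBEC3 target). With
#' the trivial motif `"C"`, E is identically 1.
#'
#' @param catalog a mutation catalog; only SNP records are used.
#' @param ref a [ref_seq] reference.
#' @param motif IUPAC motif containing the mutated C (default `"TCW"`).
#' @param flank half-width of the context window in bp (default 20).
#' @return `data.table` with one row per sample: `sample_id`, `motif`,
#'   `mut_motif`, `mut_C`, `ctx_motif`, `ctx_C`, `E`, `evaluable`, `flank`.
#'   Samples with no C>X mutations have `evaluable = FALSE` and `E = NA`;
#'   `ctx_motif = 0` with `mut_motif > 0` yields `E = Inf`.
#' @export
motif_enrichment <- function(catalog, ref, motif = "TCW", flank = 20L) {
  validate_catalog(catalog)
  if (flank < 1L) stop_data("flank must be >= 1")
  motif <- toupper(motif)
  m <- nchar(motif)
  j <- max(gregexpr("C", motif, fixed = TRUE)[[1]])
  if (j < 1L) stop_data("motif must contain the mutated C: ", motif)
  fwd_re <- motif_regex(motif)
  rev_re <- motif_regex(revcomp(motif))
  snv <- catalog[catalog$variant_type == "SNP", ]
  contigs <- unclass(ref)
  samples <- sort(unique(catalog$sample_id))
  out <- data.table::rbindlist(lapply(samples, function(sid) {
    rec <- snv[snv$sample_id == sid & snv$ref %in% c("C", "G"), ]
    mut_C <- nrow(rec)
    if (mut_C == 0L) {
      return(data.table::data.table(sample_id = sid, motif = motif,
                                    mut_motif = 0L, mut_C = 0L,
                                    ctx_motif = 0L, ctx_C = 0L, E = NA_real_,
                                    evaluable = FALSE, flank = as.integer(flank)))
    }
    mut_motif <- 0L; ctx_motif <- 0L; ctx_C <- 0L
    for (i in seq_len(mut_C)) {
      s <- contigs[[rec$chrom[i]]]
      if (is.null(s)) stop_data("contig ", rec$chrom[i], " not in reference")
      p <- rec$pos[i]; L <- nchar(s)
      # pyrimidine-strand neighbourhood of the mutated base
      if (rec$ref[i] == "C") {
        lo <- p - (j - 1L); hi <- p + (m - j)
        nb <- if (lo >= 1L && hi <= L) substr(s, lo, hi) else ""
      } else {
        lo <- p - (m - j); hi <- p + (j - 1L)
        nb <- if (lo >= 1L && hi <= L) revcomp(substr(s, lo, hi)) else ""
      }
      if (nchar(nb) == m && grepl(paste0("^", fwd_re, "$"), nb)) {
        mut_motif <- mut_motif + 1L
      }
      win_lo <- max(1L, p - flank); win_hi <- min(L, p + flank)
      win <- substr(s, win_lo, win_hi)
      # positions within m-1 bp of the mutated base cannot be motif centres
      # (their motif span covers the mutated site, whose base is fixed), so
      # they are excluded from both availability counts to keep E calibrated
      keep <- function(q) q == p | abs(q - p) >= m
      cg_centres <- win_lo + c(match_starts(win, "C"), match_starts(win, "G")) - 1L
      ctx_C <- ctx_C + sum(keep(cg_centres))
      # motifs are matched against an extended slice so occurrences
      # straddling the window edge are not lost
      ext_lo <- max(1L, win_lo - (m - 1L)); ext_hi <- min(L, win_hi + (m - 1L))
      ext <- substr(s, ext_lo, ext_hi)
      fwd_centres <- ext_lo + match_starts(ext, fwd_re) - 1L + (j - 1L)
      rev_centres <- ext_lo + match_starts(ext, rev_re) - 1L + (m - j)
      in_win <- function(q) q >= win_lo & q <= win_hi & keep(q)
      ctx_motif <- ctx_motif + sum(in_win(fwd_centres)) + sum(in_win(rev_centres))
    }
    E <- enrichment_score(mut_motif, mut_C, ctx_motif, ctx_C)
    data.table::data.table(sample_id = sid, motif = motif,
                           mut_motif = mut_motif, mut_C = mut_C,
                           ctx_motif = ctx_motif, ctx_C = ctx_C, E = E,
                           evaluable = TRUE, flank = as.integer(flank))
  }))
  out
}

#' Classify samples as APOBEC-enriched
#'
#' Splits samples on a strict threshold on the enrichment score: enriched
#' means `E > threshold`. Samples whose score could not be evaluated (no
#' C>X mutations) are reported separately.
#'
#' @param results output of [motif_enrichment()].
#' @param threshold enrichment-score cutoff (default 2).
#' @return list with character vectors `enriched`, `non_enriched`,
#'   `not_evaluable`, the `threshold`, and the annotated `results` table
#'   (column `enriched` added).
#' @export
classify_enriched <- function(results, threshold = 2) {
  if (threshold <= 0) stop_data("threshold must be > 0")
  res <- data.table::copy(results)
  res$enriched <- res$evaluable & !is.na(res$E) & res$E > threshold
  ev <- res$evaluable & !is.na(res$E)
  if (!any(ev)) warning("no sample has an evaluable enrichment score", call. = FALSE)
  list(enriched = res$sample_id[res$enriched],
       non_enriched = res$sample_id[ev & !res$enriched],
       not_evaluable = res$sample_id[!ev],
       threshold = threshold,
       results = res)
}

#' Compare APOBEC-enriched and non-enriched sample groups
#'
#' Per-gene differential alteration (two-sided Fisher exact test on the
#' 2x2 mutated-by-group table, Benjamini-Hochberg corrected across genes)
#' and group comparisons of mutation burden and motif-context ("tCw")
#' burden by two-sided Wilcoxon rank-sum tests.
#'
#' Gene attribution uses the catalog's `gene` column (MAF `Hugo_Symbol`)
#' when present; otherwise records are assigned by positional overlap with
#' `genes` intervals.
#'
#' @param catalog a mutation catalog.
#' @param partition output of [classify_enriched()] (or a list with
#'   `enriched` / `non_enriched` sample-id vectors).
#' @param ref optional [ref_seq]; needed for the motif-burden comparison.
#' @param genes optional gene intervals from [read_bed_genes()].
#' @param motif,flank passed to [motif_enrichment()] for the motif burden.
#' @return list with `genes` (per-gene table: counts, odds ratio, p, q),
#'   `burden` (per-sample totals plus rank-sum p) and `motif_burden`
#'   (per-sample motif-mutation counts plus rank-sum p, `NULL` without
#'   `ref`).
#' @export
compare_groups <- function(catalog, partition, ref = NULL, genes = NULL,
                           motif = "TCW", flank = 20L) {
  validate_catalog(catalog)
  grp_e <- partition$enriched
  grp_n <- partition$non_enriched
  burden_tab <- data.table::as.data.table(table(sample_id = catalog$sample_id))
  data.table::setnames(burden_tab, "N", "n_mutations")
  burden_tab$group <- ifelse(burden_tab$sample_id %in% grp_e, "enriched",
                      ifelse(burden_tab$sample_id %in% grp_n, "non_enriched", NA))
  burden_p <- NA_real_
  if (length(grp_e) == 0L || length(grp_n) == 0L) {
    warning("one group is empty; burden comparison skipped", call. = FALSE)
  } else {
    burden_p <- stats::wilcox.test(
      burden_tab$n_mutations[burden_tab$group == "enriched"],
      burden_tab$n_mutations[burden_tab$group == "non_enriched"],
      exact = FALSE)$p.value
  }

  motif_burden <- NULL
  if (!is.null(ref) && length(grp_e) > 0L && length(grp_n) > 0L) {
    enr <- motif_enrichment(catalog, ref, motif = motif, flank = flank)
    enr$group <- ifelse(enr$sample_id %in% grp_e, "enriched",
                 ifelse(enr$sample_id %in% grp_n, "non_enriched", NA))
    p <- stats::wilcox.test(enr$mut_motif[enr$group == "enriched"],
                            enr$mut_motif[enr$group == "non_enriched"],
                            exact = FALSE)$p.value
    motif_burden <- list(table = enr, p = p)
  }

  gene_tab <- NULL
  if (length(grp_e) > 0L && length(grp_n) > 0L) {
    cat2 <- data.table::copy(catalog)
    if (all(is.na(cat2$gene)) && !is.null(genes)) {
      cat2$gene <- assign_genes(cat2, genes)
    }
    cat2 <- cat2[!is.na(cat2$gene) & cat2$gene != "Unknown", ]
    all_genes <- sort(unique(cat2$gene))
    ne <- length(grp_e); nn <- length(grp_n)
    gene_tab <- data.table::rbindlist(lapply(all_genes, function(g) {
      mut_samples <- unique(cat2$sample_id[cat2$gene == g])
      a <- sum(grp_e %in% mut_samples); b <- ne - a
      c_ <- sum(grp_n %in% mut_samples); d <- nn - c_
      or <- if (b * c_ == 0) {
        if (a * d == 0) NA_real_ else Inf
      } else (a * d) / (b * c_)
      p <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2))$p.value
      data.table::data.table(gene = g, mut_enriched = a, wt_enriched = b,
                             mut_non_enriched = c_, wt_non_enriched = d,
                             odds_ratio = or, p = p)
    }))
    if (nrow(gene_tab)) {
      gene_tab$q <- stats::p.adjust(gene_tab$p, method = "BH")
      data.table::setorderv(gene_tab, "p")
    }
  } else {
    warning("gene comparison needs both groups non-empty", call. = FALSE)
  }

  list(genes = gene_tab,
       burden = list(table = burden_tab, p = burden_p),
       motif_burden = motif_burden)
}

# Positional gene assignment: first overlapping interval's name (NA if none).
assign_genes <- function(catalog, genes) {
  q <- GenomicRanges::GRanges(catalog$chrom,
                              IRanges::IRanges(catalog$pos, catalog$pos))
  s <- GenomicRanges::GRanges(genes$chrom,
                              IRanges::IRanges(genes$start, genes$end))
  hit <- GenomicRanges::findOverlaps(q, s, select = "first")
  ifelse(is.na(hit), NA_character_, genes$gene[hit])
}
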