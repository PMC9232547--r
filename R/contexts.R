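#' Pyrimidine-collapsed channel of each SNV in a catalog
#'
#' Looks up the reference trinucleotide around every SNP record and returns
#' its 96-channel label under the pyrimidine convention: purine-centred
#' mutations are reverse-complemented so the mutated base is C or T.
#'
#' A record whose reference allele disagrees with the reference sequence is a
#' data error (reported with sample, chromosome and position). Records whose
#' flank contains N or falls off a contig end are skipped with a warning by
#' default; `strict_n = TRUE` upgrades the skip to an error.
#'
#' @param catalog a mutation catalog (see [read_maf()]); non-SNP records are
#'   an error.
#' @param ref a [ref_seq] reference.
#' @param strict_n error instead of skipping N/edge contexts.
#' @return character vector of channel labels, `NA` for skipped records.
#' @export
mutation_channels <- function(catalog, ref, strict_n = FALSE) {
  validate_catalog(catalog)
  if (any(catalog$variant_type != "SNP")) {
    stop_data("mutation_channels expects an SNV-only catalog; filter with keep_types")
  }
  n <- nrow(catalog)
  out <- rep(NA_character_, n)
  if (n == 0L) return(out)
  contigs <- unclass(ref)
  for (chrom in unique(catalog$chrom)) {
    s <- contigs[[chrom]]
    if (is.null(s)) stop_data("contig ", chrom, " not in reference")
    idx <- which(catalog$chrom == chrom)
    pos <- catalog$pos[idx]
    L <- nchar(s)
    if (any(pos > L)) {
      bad <- idx[which(pos > L)[1]]
      stop_data("position beyond contig end at ", catalog$sample_id[bad], " ",
                chrom, ":", catalog$pos[bad])
    }
    cen <- substring(s, pos, pos)
    mism <- cen != catalog$ref[idx]
    if (any(mism)) {
      bad <- idx[which(mism)[1]]
      stop_data("reference allele mismatch at ", catalog$sample_id[bad], " ",
                chrom, ":", catalog$pos[bad], " (MAF ", catalog$ref[bad],
                ", reference ", cen[which(mism)[1]], ")")
    }
    five <- ifelse(pos > 1L, substring(s, pos - 1L, pos - 1L), "N")
    three <- ifelse(pos < L, substring(s, pos + 1L, pos + 1L), "N")
    fi <- base_int1(five); ci <- base_int1(cen); ti <- base_int1(three)
    ai <- base_int1(catalog$alt[idx])
    pur <- !is.na(ci) & (ci == 0L | ci == 2L)
    f2 <- ifelse(pur, 3L - ti, fi)
    t2 <- ifelse(pur, 3L - fi, ti)
    c2 <- ifelse(pur, 3L - ci, ci)
    a2 <- ifelse(pur, 3L - ai, ai)
    ctx <- 16L * (c2 == 3L) + 4L * f2 + t2
    out[idx] <- sbs_channels()[channel_index(ctx, a2)]
  }
  if (anyNA(out)) {
    msg <- paste0(sum(is.na(out)), " SNV record(s) skipped: flank contains N ",
                  "or lies at a contig edge")
    if (strict_n) stop_data(msg) else warning(msg, call. = FALSE)
  }
  out
}

#' Trinucleotide-context channel of a single mutation record
#'
#' @param record one-row catalog (see [read_maf()] columns).
#' @inheritParams mutation_channels
#' @return one channel label, e.g. `"A[C>T]G"`.
#' @export
trinucleotide_context <- function(record, ref, strict_n = TRUE) {
  mutation_channels(record, ref, strict_n = strict_n)
}

#' Build a 96-channel mutation spectrum
#'
#' Counts the SNVs of one sample (or of the pooled catalog) over the 96
#' canonical channels.
#'
#' @param catalog an SNV catalog.
#' @param ref a [ref_seq] reference.
#' @param sample sample id, or `NULL` to pool all samples.
#' @param strict_n see [mutation_channels()].
#' @return an object of class `spectrum`: list with `sample_id`, `counts`
#'   (named integer vector of length 96) and `total`.
#' @export
build_spectrum <- function(catalog, ref, sample = NULL, strict_n = FALSE) {
  validate_catalog(catalog)
  catalog <- catalog[catalog$variant_type == "SNP", ]
  if (!is.null(sample)) {
    if (!sample %in% catalog$sample_id) stop_data("sample not in catalog: ", sample)
    catalog <- catalog[catalog$sample_id == sample, ]
  }
  ch <- mutation_channels(catalog, ref, strict_n = strict_n)
  counts <- table(factor(ch, levels = sbs_channels()))
  counts <- stats::setNames(as.integer(counts), sbs_channels())
  structure(list(sample_id = if (is.null(sample)) "pooled" else sample,
                 counts = counts, total = sum(counts)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat("spectrum for", x$sample_id, "-", x$total, "SNVs over 96 channels\n")
  cls <- rep(sbs_classes(), each = 16)
  by_class <- tapply(x$counts, cls, sum)[sbs_classes()]
  print(by_class)
  invisible(x)
}

#' Per-sample spectrum matrix
#'
#' @inheritParams build_spectrum
#' @return integer matrix 96 x n_samples (channels in canonical order).
#' @export
per_sample_spectra <- function(catalog, ref, strict_n = FALSE) {
  validate_catalog(catalog)
  catalog <- catalog[catalog$variant_type == "SNP", ]
  ch <- mutation_channels(catalog, ref, strict_n = strict_n)
  samples <- sort(unique(catalog$sample_id))
  m <- vapply(samples, function(s) {
    as.integer(table(factor(ch[catalog$sample_id == s], levels = sbs_channels())))
  }, integer(96))
  m <- matrix(m, nrow = 96, dimnames = list(sbs_channels(), samples))
  m
}

# 6-class label from ref/alt alone (pyrimidine-collapsed; no flank needed).
snv_class6 <- function(ref, alt) {
  ri <- base_int1(ref); ai <- base_int1(alt)
  pur <- !is.na(ri) & (ri == 0L | ri == 2L)
  r2 <- ifelse(pur, 3L - ri, ri)
  a2 <- ifelse(pur, 3L - ai, ai)
  cls <- rep(NA_integer_, length(ref))
  isC <- r2 == 1L
  cls[isC] <- match(a2[isC], c(0L, 2L, 3L))
  isT <- r2 == 3L
  cls[isT] <- match(a2[isT], c(0L, 1L, 2L)) + 3L
  sbs_classes()[cls]
}

#' Per-sample variant-class summary
#'
#' Summarises a catalog three ways: counts of `Variant_Classification`
#' (missense, nonsense, ...), counts of variant type (SNP / INS / DEL /
#' other), and the 6-class pyrimidine-collapsed SNV spectrum with
#' proportions. Samples without SNVs are flagged (`empty = TRUE`) and carry
#' `NA` proportions.
#'
#' @param catalog a mutation catalog.
#' @return list of three `data.table`s: `classification`, `type`,
#'   `snv_class`.
#' @export
class_summary <- function(catalog) {
  validate_catalog(catalog)
  cls_tab <- data.table::as.data.table(
    table(sample_id = catalog$sample_id,
          classification = ifelse(is.na(catalog$variant_classification),
                                  "Unknown", catalog$variant_classification)))
  data.table::setnames(cls_tab, "N", "count")
  type_tab <- data.table::as.data.table(
    table(sample_id = catalog$sample_id, variant_type = catalog$variant_type))
  data.table::setnames(type_tab, "N", "count")
  snv <- catalog[catalog$variant_type == "SNP", ]
  samples <- sort(unique(catalog$sample_id))
  cls6 <- snv_class6(snv$ref, snv$alt)
  snv_tab <- data.table::rbindlist(lapply(samples, function(s) {
    counts <- table(factor(cls6[snv$sample_id == s], levels = sbs_classes()))
    tot <- sum(counts)
    data.table::data.table(sample_id = s, snv_class = sbs_classes(),
                           count = as.integer(counts),
                           proportion = if (tot > 0) as.numeric(counts) / tot
                                        else NA_real_,
                           empty = tot == 0L)
  }))
  data.table::setorderv(cls_tab, c("sample_id", "classification"))
  data.table::setorderv(type_tab, c("sample_id", "variant_type"))
  list(classification = cls_tab[], type = type_tab[], snv_class = snv_tab)
}

#' Subtract a control catalog from a treated catalog
#'
#' Returns the records of `treated` whose (chrom, pos, ref, alt) key is
#' absent from `control` — the "newly occurring" variants of a paired
#' control / overexpression design. Subtraction is on variant presence
#' only; a position present in both catalogs but with a different alternate
#' allele is retained.
#'
#' @param treated,control mutation catalogs. Each must contain a single
#'   sample unless `pairing` maps treated sample ids to control sample ids.
#' @param pairing named character vector: `names()` are treated samples,
#'   values the matching control samples.
#' @return catalog of new records, labelled with the treated sample ids.
#' @export
subtract_catalog <- function(treated, control, pairing = NULL) {
  validate_catalog(treated); validate_catalog(control)
  t_samples <- unique(treated$sample_id)
  c_samples <- unique(control$sample_id)
  if (is.null(pairing)) {
    if (length(t_samples) > 1L || length(c_samples) > 1L) {
      stop_data("multi-sample catalogs need an explicit treated->control pairing map")
    }
    pairing <- stats::setNames(c_samples, t_samples)
  }
  if (is.null(names(pairing)) || !all(t_samples %in% names(pairing))) {
    stop_data("pairing map must name every treated sample")
  }
  key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
  out <- lapply(t_samples, function(ts) {
    tt <- treated[treated$sample_id == ts, ]
    cc <- control[control$sample_id == pairing[[ts]], ]
    tt[!key(tt) %in% key(cc), ]
  })
  sort_catalog(data.table::rbindlist(out))
}
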