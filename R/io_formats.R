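#' Read a somatic mutation catalog from a MAF file
#'
#' Reads a tab-separated MAF (GDC column names), normalises it into the
#' package's catalog layout and applies the loading invariants: records are
#' sorted by (sample, chromosome, position) and exact duplicates on the
#' (sample, chrom, pos, ref, alt) 5-tuple are removed. Multi-allelic sites
#' remain separate records. Comment lines starting with `#` are skipped and
#' gzip-compressed input is accepted.
#'
#' The alternate allele is taken from `Tumor_Seq_Allele2`; when it equals the
#' reference allele the reader falls back to `Tumor_Seq_Allele1` (GDC
#' convention). Chromosome names are normalised to the prefix-less dialect.
#'
#' @param path path to a MAF file (optionally gzipped).
#' @param keep_types restrict to these `Variant_Type` values
#'   (e.g. `"SNP"`); `NULL` keeps every record.
#' @param keep_classifications optional filter on `Variant_Classification`
#'   (e.g. drop `"Silent"`); `NULL` keeps all.
#' @return a `data.table` with columns `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `variant_type`, `variant_classification`, `gene`.
#' @export
read_maf <- function(path, keep_types = NULL, keep_classifications = NULL) {
  if (!file.exists(path)) stop_format("MAF file not found: ", path)
  if (file.size(path) == 0L) stop_format("empty MAF file: ", path)
  dt <- suppressWarnings(tryCatch(
    data.table::fread(path, sep = "\t", header = TRUE, skip = "Tumor_Sample_Barcode",
                      colClasses = list(character = "Chromosome")),
    error = function(e) {
      data.table::fread(path, sep = "\t", header = TRUE)
    }))
  if (nrow(dt) == 0L && ncol(dt) == 0L) stop_format("empty MAF file: ", path)
  required <- c("Tumor_Sample_Barcode", "Chromosome", "Start_Position",
                "Reference_Allele", "Tumor_Seq_Allele2", "Variant_Type")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols)) {
    stop_format("MAF is missing mandatory column(s): ",
                paste(missing_cols, collapse = ", "))
  }
  alt <- toupper(as.character(dt[["Tumor_Seq_Allele2"]]))
  ref <- toupper(as.character(dt[["Reference_Allele"]]))
  if ("Tumor_Seq_Allele1" %in% names(dt)) {
    a1 <- toupper(as.character(dt[["Tumor_Seq_Allele1"]]))
    same <- !is.na(alt) & alt == ref & !is.na(a1) & a1 != ref
    alt[same] <- a1[same]
  }
  vt <- as.character(dt[["Variant_Type"]])
  vt[!vt %in% c("SNP", "INS", "DEL")] <- "other"
  cat_dt <- data.table::data.table(
    sample_id = as.character(dt[["Tumor_Sample_Barcode"]]),
    chrom = normalize_chrom(dt[["Chromosome"]]),
    pos = as.integer(dt[["Start_Position"]]),
    ref = ref,
    alt = alt,
    variant_type = vt,
    variant_classification = if ("Variant_Classification" %in% names(dt)) {
      as.character(dt[["Variant_Classification"]])
    } else NA_character_,
    gene = if ("Hugo_Symbol" %in% names(dt)) {
      as.character(dt[["Hugo_Symbol"]])
    } else NA_character_)
  if (anyNA(cat_dt$pos) || any(cat_dt$pos < 1L)) {
    stop_format("MAF contains missing or non-positive Start_Position values")
  }
  if (!is.null(keep_types)) cat_dt <- cat_dt[cat_dt$variant_type %in% keep_types, ]
  if (!is.null(keep_classifications)) {
    cat_dt <- cat_dt[cat_dt$variant_classification %in% keep_classifications, ]
  }
  snv <- cat_dt$variant_type == "SNP"
  bad_snv <- snv & (nchar(cat_dt$ref) != 1L | nchar(cat_dt$alt) != 1L |
                      cat_dt$ref == cat_dt$alt)
  if (any(bad_snv)) {
    stop_format(sum(bad_snv), " SNP record(s) with invalid ref/alt alleles ",
                "(first at ", cat_dt$chrom[bad_snv][1], ":",
                cat_dt$pos[bad_snv][1], ")")
  }
  sort_catalog(unique(cat_dt, by = c("sample_id", "chrom", "pos", "ref", "alt")))
}

sort_catalog <- function(catalog) {
  data.table::setorderv(catalog, c("sample_id", "chrom", "pos", "ref", "alt"))
  catalog[]
}

# Minimal catalog validation used at module boundaries.
validate_catalog <- function(catalog) {
  need <- c("sample_id", "chrom", "pos", "ref", "alt", "variant_type")
  missing_cols <- setdiff(need, names(catalog))
  if (length(missing_cols)) {
    stop_data("catalog is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  invisible(catalog)
}

#' Write a mutation catalog as a MAF file
#'
#' Emits the GDC column subset that [read_maf()] consumes, so a written
#' catalog round-trips field-by-field.
#'
#' @param catalog a catalog `data.table` (see [read_maf()]).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_maf <- function(catalog, path) {
  validate_catalog(catalog)
  end_pos <- catalog$pos + ifelse(catalog$variant_type == "DEL",
                                  pmax(nchar(catalog$ref) - 1L, 0L), 0L)
  out <- data.table::data.table(
    Hugo_Symbol = ifelse(is.na(catalog$gene), "Unknown", catalog$gene),
    Chromosome = catalog$chrom,
    Start_Position = catalog$pos,
    End_Position = end_pos,
    Variant_Classification = ifelse(is.na(catalog$variant_classification),
                                    "Missense_Mutation",
                                    catalog$variant_classification),
    Variant_Type = catalog$variant_type,
    Reference_Allele = catalog$ref,
    Tumor_Seq_Allele1 = catalog$ref,
    Tumor_Seq_Allele2 = catalog$alt,
    Tumor_Sample_Barcode = catalog$sample_id)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a FASTA reference into memory
#'
#' @param path FASTA path (optionally gzipped). Contigs are keyed by the
#'   first whitespace-delimited token of each header; bases are uppercased.
#' @return a [ref_seq] object.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_format("FASTA file not found: ", path)
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) stop_format("malformed FASTA: ", conditionMessage(e)))
  if (length(ss) == 0L) stop_format("FASTA file has no sequences: ", path)
  contigs <- as.character(ss)
  names(contigs) <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1)
  ref_seq(contigs)
}

#' Write a reference to FASTA
#' @param ref a [ref_seq] object.
#' @param path output path.
#' @param width line width.
#' @return the path, invisibly.
#' @export
write_fasta <- function(ref, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(unlist(unclass(ref)))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Construct a reference-signature catalog
#'
#' @param mat numeric 96 x K matrix of channel probabilities with rownames
#'   giving channel labels and colnames the signature names.
#' @return an object of class `signature_catalog` with elements `channels`,
#'   `names` and `matrix` (96 x K, columns summing to 1, canonical channel
#'   order).
#' @export
signature_catalog <- function(mat) {
  channels <- sbs_channels()
  if (is.null(rownames(mat))) stop_format("signature matrix needs channel rownames")
  if (nrow(mat) != 96L || !setequal(rownames(mat), channels)) {
    stop_format("signature matrix must have exactly the 96 canonical channels; got ",
                nrow(mat), " rows")
  }
  mat <- as.matrix(mat[channels, , drop = FALSE])
  if (any(mat < 0)) stop_format("signature matrix has negative entries")
  cs <- colSums(mat)
  off <- abs(cs - 1) > 1e-4
  if (any(off)) {
    stop_format("signature column(s) not summing to 1 (tolerance 1e-4): ",
                paste(colnames(mat)[off], collapse = ", "))
  }
  mat <- sweep(mat, 2, cs, "/")
  structure(list(channels = channels, names = colnames(mat), matrix = mat),
            class = "signature_catalog")
}

#' @export
print.signature_catalog <- function(x, ...) {
  cat("signature_catalog:", length(x$names), "signature(s) over 96 channels\n")
  cat(" ", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' Read a COSMIC-layout reference-signature matrix
#'
#' Expects a TSV with a channel column (`Type`, values like `"A[C>A]A"`) and
#' one column per signature. Channels are reordered to the canonical order
#' and columns renormalised when within 1e-4 of 1.
#'
#' @param path TSV path (optionally gzipped).
#' @return a `signature_catalog`.
#' @export
read_signature_matrix <- function(path) {
  if (!file.exists(path)) stop_format("signature file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  type_col <- if ("Type" %in% names(dt)) "Type" else names(dt)[1]
  channels <- as.character(dt[[type_col]])
  mat <- as.matrix(dt[, setdiff(names(dt), type_col), with = FALSE])
  if (!is.numeric(mat)) stop_format("signature columns must be numeric")
  rownames(mat) <- channels
  signature_catalog(mat)
}

#' Write a signature catalog as a COSMIC-layout TSV
#' @param sigs a `signature_catalog`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_signature_matrix <- function(sigs, path) {
  dt <- data.table::data.table(Type = sigs$channels)
  for (nm in sigs$names) dt[[nm]] <- sigs$matrix[, nm]
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read gene intervals from a BED file
#'
#' BED is 0-based half-open on disk; intervals are converted to the
#' package-wide 1-based inclusive convention.
#'
#' @param path BED4+ path (chrom, start, end, name, [score, strand]).
#' @return a `data.table` with columns `chrom`, `start`, `end`, `gene`,
#'   `strand` (1-based inclusive coordinates).
#' @export
read_bed_genes <- function(path) {
  if (!file.exists(path)) stop_format("BED file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) < 4L) stop_format("BED needs at least 4 columns (chrom, start, end, name)")
  out <- data.table::data.table(
    chrom = normalize_chrom(dt[[1]]),
    start = as.integer(dt[[2]]) + 1L,
    end = as.integer(dt[[3]]),
    gene = as.character(dt[[4]]),
    strand = if (ncol(dt) >= 6L) as.character(dt[[6]]) else "*")
  if (any(out$start > out$end)) stop_format("BED interval with start > end")
  data.table::setorderv(out, c("chrom", "start", "end"))
  out[]
}

#' Write gene intervals to BED (inverse of [read_bed_genes()])
#' @param genes gene interval `data.table` (1-based inclusive).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bed_genes <- function(genes, path) {
  out <- data.table::data.table(genes$chrom, genes$start - 1L, genes$end,
                                genes$gene, 0L,
                                if ("strand" %in% names(genes)) genes$strand else "*")
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-sample expression table
#'
#' @param path TSV with a header and columns `sample_id` and `expression`
#'   (the first two columns are used if those names are absent).
#' @return a `data.table` with `sample_id` and non-negative finite
#'   `expression` values, one row per sample.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop_format("expression file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (ncol(dt) < 2L) stop_format("expression table needs sample_id and expression columns")
  sid <- if ("sample_id" %in% names(dt)) dt[["sample_id"]] else dt[[1]]
  expr <- if ("expression" %in% names(dt)) dt[["expression"]] else dt[[2]]
  expr <- as.numeric(expr)
  if (any(!is.finite(expr))) stop_format("expression table contains non-finite values")
  if (any(expr < 0)) stop_format("expression table contains negative values")
  if (anyDuplicated(sid)) stop_format("duplicated sample_id in expression table")
  data.table::data.table(sample_id = as.character(sid), expression = expr)
}

#' Read a per-sample survival table
#'
#' @param path TSV with a header and columns `sample_id`, `time` (days > 0)
#'   and `event` (0 censored / 1 death).
#' @return a `data.table` with `sample_id`, `time`, `event`.
#' @export
read_survival_table <- function(path) {
  if (!file.exists(path)) stop_format("survival file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("sample_id", "time", "event")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols)) {
    stop_format("survival table is missing column(s): ",
                paste(missing_cols, collapse = ", "))
  }
  time <- as.numeric(dt[["time"]])
  event <- as.integer(dt[["event"]])
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop_format("survival times must be finite and > 0")
  }
  if (any(!event %in% c(0L, 1L))) stop_format("survival events must be 0 or 1")
  if (anyDuplicated(dt[["sample_id"]])) stop_format("duplicated sample_id in survival table")
  data.table::data.table(sample_id = as.character(dt[["sample_id"]]),
                         time = time, event = event)
}
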