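#' Reference sequence container
#'
#' A `ref_seq` is a named list of uppercase base strings (one per contig),
#' the in-memory form of a FASTA reference. Contig names are normalised to
#' the prefix-less chromosome dialect.
#'
#' @param contigs named character vector or list of base strings.
#' @return an object of class `ref_seq`.
#' @export
ref_seq <- function(contigs) {
  if (length(contigs) == 0L) stop_format("reference has no contigs")
  if (is.null(names(contigs)) || any(!nzchar(names(contigs)))) {
    stop_format("every contig needs a name")
  }
  contigs <- lapply(contigs, function(s) toupper(as.character(s)))
  bad <- vapply(contigs, function(s) grepl("[^ACGTN]", s), logical(1))
  if (any(bad)) {
    stop_format("contig ", names(contigs)[bad][1], " contains non-ACGTN characters")
  }
  names(contigs) <- normalize_chrom(names(contigs))
  structure(contigs, class = "ref_seq")
}

#' @export
print.ref_seq <- function(x, ...) {
  cat("ref_seq with", length(x), "contig(s):\n")
  for (nm in names(x)) cat(" ", nm, ":", nchar(x[[nm]]), "bp\n")
  invisible(x)
}

#' Contig lengths of a reference
#' @param ref a [ref_seq] object.
#' @return named integer vector of contig lengths in bp.
#' @export
ref_lengths <- function(ref) {
  vapply(unclass(ref), nchar, integer(1))
}

#' Extract a window of reference sequence
#'
#' Coordinates are 1-based inclusive. Out-of-bounds lookups are an error;
#' use `clip = TRUE` to truncate the window at contig ends instead.
#'
#' @param ref a [ref_seq] object.
#' @param chrom contig name (either dialect).
#' @param start,end 1-based inclusive bounds.
#' @param clip truncate at contig boundaries instead of erroring.
#' @return uppercase base string.
#' @export
ref_window <- function(ref, chrom, start, end, clip = FALSE) {
  chrom <- normalize_chrom(chrom)
  s <- unclass(ref)[[chrom]]
  if (is.null(s)) stop_data("contig ", chrom, " not in reference")
  n <- nchar(s)
  if (clip) {
    start <- max(1L, start)
    end <- min(n, end)
  } else if (start < 1L || end > n || start > end) {
    stop_data("window ", chrom, ":", start, "-", end,
              " out of bounds (contig length ", n, ")")
  }
  substr(s, start, end)
}

# Vectorised base lookup on one contig: returns bases at `pos` (NA outside).
contig_bases <- function(contig_seq, pos) {
  n <- nchar(contig_seq)
  out <- rep(NA_character_, length(pos))
  ok <- pos >= 1L & pos <= n
  out[ok] <- substring(contig_seq, pos[ok], pos[ok])
  out
}
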