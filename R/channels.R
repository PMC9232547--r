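#' Canonical 96-channel single-base-substitution conventions
#'
#' Channels follow the COSMIC pyrimidine convention: six substitution classes
#' in the order C>A, C>G, C>T, T>A, T>C, T>G; within a class the 5' flank
#' varies slowest and the 3' flank fastest, each over A, C, G, T. Purine-
#' centred mutations are reverse-complemented onto the pyrimidine strand.
#'
#' @return `sbs_classes()`: the 6 class labels; `sbs_channels()`: the 96
#'   channel labels (e.g. `"A[C>T]G"`) in canonical order.
#' @export
sbs_channels <- function() {
  bases <- c("A", "C", "G", "T")
  unlist(lapply(sbs_classes(), function(cl) {
    as.vector(t(outer(bases, bases, function(f, t) paste0(f, "[", cl, "]", t))))
  }))
}

#' @rdname sbs_channels
#' @export
sbs_classes <- function() {
  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
}

# Base encoding A=0, C=1, G=2, T=3 (NA for anything else, incl. N).
BASE_INT <- local({
  v <- rep(NA_integer_, 256)
  v[utf8ToInt("A") + 1L] <- 0L
  v[utf8ToInt("C") + 1L] <- 1L
  v[utf8ToInt("G") + 1L] <- 2L
  v[utf8ToInt("T") + 1L] <- 3L
  v
})

encode_bases <- function(s) {
  BASE_INT[utf8ToInt(s) + 1L]
}

base_int1 <- function(b) {
  # single-character vectorised base -> integer
  BASE_INT[vapply(b, function(x) utf8ToInt(x)[1], integer(1)) + 1L]
}

INT_BASE <- c("A", "C", "G", "T")

# Pyrimidine-collapsed trinucleotide context ids 0..31 for positions
# 2..(L-1) of an integer-encoded contig; NA at N-containing triplets.
# id = 16*(centre is T) + 4*five + three, flanks on the pyrimidine strand.
contig_context_ids <- function(x) {
  L <- length(x)
  if (L < 3L) return(integer(0))
  five <- x[1:(L - 2L)]
  cen <- x[2:(L - 1L)]
  three <- x[3:L]
  pur <- cen == 0L | cen == 2L
  f <- ifelse(pur, 3L - three, five)
  t3 <- ifelse(pur, 3L - five, three)
  c2 <- ifelse(pur, 3L - cen, cen)
  ids <- 16L * (c2 == 3L) + 4L * f + t3
  ids[is.na(five) | is.na(cen) | is.na(three)] <- NA_integer_
  ids
}

# Human-readable 32 collapsed contexts in id order ("ACA".."TTT", C then T centre).
context_labels <- function() {
  bases <- c("A", "C", "G", "T")
  unlist(lapply(c("C", "T"), function(cen)
    as.vector(t(outer(bases, bases, function(f, t) paste0(f, cen, t))))))
}

# Channel index (1..96) from collapsed context id (0..31) and collapsed
# alt base integer. Purine-centred mutations must already be collapsed.
channel_index <- function(ctx_id, alt_int) {
  is_t <- ctx_id >= 16L
  cls <- integer(length(ctx_id))
  # centre C: alt A->C>A(0), G->C>G(1), T->C>T(2)
  cls[!is_t] <- match(alt_int[!is_t], c(0L, 2L, 3L)) - 1L
  # centre T: alt A->T>A(3), C->T>C(4), G->T>G(5)
  cls[is_t] <- match(alt_int[is_t], c(0L, 1L, 2L)) + 2L
  cls[is.na(ctx_id) | is.na(alt_int)] <- NA_integer_
  16L * cls + (ctx_id %% 16L) + 1L
}

# Index of eligible mutation sites per collapsed context.
# Returns a data.table(chrom, pos, ctx, pur): every internal position of
# every contig whose trinucleotide is N-free; `pur` marks purine centres
# (sites represented through their reverse complement).
context_site_index <- function(ref) {
  out <- lapply(names(ref), function(chrom) {
    x <- encode_bases(unclass(ref)[[chrom]])
    L <- length(x)
    if (L < 3L) return(NULL)
    ids <- contig_context_ids(x)
    pos <- 2:(L - 1L)
    keep <- !is.na(ids)
    data.table::data.table(chrom = chrom, pos = pos[keep], ctx = ids[keep],
                           pur = (x[pos] == 0L | x[pos] == 2L)[keep])
  })
  data.table::rbindlist(out)
}
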