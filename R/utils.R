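#' @importFrom stats setNames
#' @importFrom data.table data.table .N .SD :=
NULL

.datatable.aware <- TRUE

# Run code under a temporary RNG seed, restoring the caller's RNG state.
# All generators in the package are pure functions of (arguments, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("apobecscope_format_error", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("apobecscope_data_error", "error")))
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over character strings; IUPAC ambiguity
#' codes are complemented too (W/S are self-complementary).
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNWSRYKMacgtnwsrykm", "TGCANWSYRMKtgcanwsyrmk", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Normalize chromosome names to the canonical prefix-less dialect
# ("1".."22","X","Y","MT"); `style = "chr"` re-adds the prefix on output.
normalize_chrom <- function(chrom, style = c("plain", "chr")) {
  style <- match.arg(style)
  plain <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  plain[plain == "M"] <- "MT"
  if (style == "plain") plain else paste0("chr", plain)
}
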