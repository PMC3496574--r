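#' Genotype call vocabulary
#'
#' The allele alphabet used by DMET-style genotype tables, in canonical
#' order: `"-"` (absent allele / indel) sorts before the four nucleotides.
#' `"-"` is a legitimate allele, not a missing value; a call the platform
#' could not make is the distinct token `"NoCall"`.
#'
#' @format A character vector of length 5.
#' @export
dmet_alleles <- c("-", "A", "C", "G", "T")

#' Token representing a failed genotype call
#' @format A character string.
#' @export
nocall_token <- "NoCall"

#' Canonicalize diploid genotype calls
#'
#' Normalizes raw genotype strings to canonical `"X/Y"` form with the two
#' alleles sorted under the fixed ordering `- < A < C < G < T` (calls are
#' unphased, so `"G/C"` and `"C/G"` denote the same genotype and both map to
#' `"C/G"`). The tokens `"NoCall"`, `"---"` and `"./."` (case-insensitive)
#' map to [nocall_token]. Canonicalization is idempotent.
#'
#' @param x Character vector of raw calls, e.g. `c("G/C", "NoCall", "-/T")`.
#' @param context Optional character vector (recycled) naming the source of
#'   each value, used in error messages for unparseable cells.
#' @return Character vector of canonical genotype symbols.
#' @examples
#' canonicalize_genotype(c("G/C", "C/C", "-/T", "nocall"))
#' @export
canonicalize_genotype <- function(x, context = NULL) {
  x <- as.character(x)
  out <- stringr::str_trim(x)
  is_nc <- tolower(out) %in% c("nocall", "---", "./.")
  out[is_nc] <- nocall_token
  idx <- which(!is_nc)
  if (length(idx)) {
    m <- stringr::str_match(toupper(out[idx]), "^([ACGT-])/([ACGT-])$")
    bad <- is.na(m[, 1])
    if (any(bad)) {
      where <- if (is.null(context)) {
        paste0("element ", idx[bad][1])
      } else {
        rep_len(context, length(x))[idx[bad][1]]
      }
      abort(
        sprintf(
          "Unrecognized genotype token %s at %s (expected \"X/Y\" with X,Y in {A,C,G,T,-} or \"NoCall\").",
          encodeString(x[idx[bad][1]], quote = "\""), where
        ),
        class = "dmetr_parse_error"
      )
    }
    a1 <- m[, 2]
    a2 <- m[, 3]
    o1 <- match(a1, dmet_alleles)
    o2 <- match(a2, dmet_alleles)
    swap <- o1 > o2
    tmp <- a1[swap]
    a1[swap] <- a2[swap]
    a2[swap] <- tmp
    out[idx] <- paste0(a1, "/", a2)
  }
  out
}

#' Sort genotype symbols in canonical order
#'
#' Orders canonical genotype symbols by their allele pair under the alphabet
#' ordering `- < A < C < G < T` (so `"-/T"` sorts before `"A/A"`,
#' independent of locale collation). `"NoCall"`, if present, sorts last.
#'
#' @param symbols Character vector of canonical genotype symbols.
#' @return The input, sorted; duplicates removed.
#' @export
sort_genotypes <- function(symbols) {
  symbols <- unique(symbols)
  nc <- symbols == nocall_token
  gt <- symbols[!nc]
  if (length(gt)) {
    a1 <- match(substr(gt, 1, 1), dmet_alleles)
    a2 <- match(substr(gt, 3, 3), dmet_alleles)
    gt <- gt[order(a1, a2)]
  }
  c(gt, symbols[nc])
}
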