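#' Gc (VDBP) diplotype handling
#'
#' The vitamin D binding protein circulates as combinations of the Gc1f, Gc1s
#' and Gc2 protein variants; six unordered diplotypes are possible. Estimating
#' equations that adjust for diplotype use additive offsets against the
#' Gc1f/Gc1f reference. Diplotypes are unordered pairs, so "Gc1s/Gc2" and
#' "Gc2/Gc1s" denote the same phenotype; this package canonicalizes to the
#' labels used in the source tables (Gc2 written first when heterozygous with
#' a Gc1 variant, Gc1f before Gc1s otherwise).
#'
#' @name gc_phenotypes
NULL

.gc_alleles <- c("Gc1f", "Gc1s", "Gc2")

#' Canonical Gc diplotype labels
#'
#' @return Character vector of the six admissible diplotype labels, reference
#'   (Gc1f/Gc1f) first.
#' @examples
#' gc_diplotypes()
#' @export
gc_diplotypes <- function() {
  c("Gc1f/Gc1f", "Gc1f/Gc1s", "Gc1s/Gc1s",
    "Gc2/Gc1f", "Gc2/Gc1s", "Gc2/Gc2")
}

#' Normalize Gc diplotype strings to canonical labels
#'
#' Accepts any allele order and surrounding whitespace; case of the "Gc"/"f"/
#' "s" parts is tolerated. `NA` passes through as `NA`.
#'
#' @param x Character vector of diplotype strings, e.g. `"Gc1s/Gc2"`.
#' @return Character vector of canonical labels from [gc_diplotypes()].
#' @examples
#' normalize_phenotype("Gc1s/Gc2") # "Gc2/Gc1s"
#' @export
normalize_phenotype <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x) & nzchar(trimws(x))
  if (!any(ok)) return(out)
  canon_one <- function(s) {
    parts <- strsplit(trimws(s), "/", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop(sprintf("cannot parse Gc diplotype '%s'", s), call. = FALSE)
    }
    parts <- trimws(parts)
    idx <- match(tolower(parts), tolower(.gc_alleles))
    if (anyNA(idx)) {
      stop(sprintf("unknown Gc allele in '%s' (expected Gc1f, Gc1s or Gc2)", s),
           call. = FALSE)
    }
    a <- .gc_alleles[sort(idx)]
    # canonical label order: Gc2 leads a heterozygote, else Gc1f before Gc1s
    if (a[2] == "Gc2" && a[1] != "Gc2") paste(a[2], a[1], sep = "/")
    else paste(a[1], a[2], sep = "/")
  }
  out[ok] <- vapply(x[ok], canon_one, character(1), USE.NAMES = FALSE)
  out
}
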