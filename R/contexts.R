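#' Canonical 96 trinucleotide substitution classes
#'
#' Returns the 96 single-base-substitution class labels in the canonical
#' order used by the COSMIC v2 signature catalogs: the six
#' pyrimidine-centred substitutions (C>A, C>G, C>T, T>A, T>C, T>G), each
#' expanded over the 16 combinations of 5' and 3' flanking bases in
#' alphabetical order. Labels have the form \code{"A[C>A]A"}.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(sbs_classes())
sbs_classes <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(l, r) paste0(l, "[", s, "]", r))))
  }))
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, NULL), function(b) paste(rev(b), collapse = ""), ""))
}

#' Map an SNV to its pyrimidine-normalized substitution class
#'
#' Variants reported on the purine strand (reference base A or G) are
#' reverse-complemented, together with their trinucleotide context, so
#' that every substitution is expressed with a C or T reference base.
#'
#' @param ref Reference base (single character, one of A/C/G/T).
#' @param alt Alternate base.
#' @param context Trinucleotide context centred on the variant site,
#'   reported on the same strand as `ref`.
#' @return Class label such as \code{"A[C>T]A"}; vectorized.
#' @export
#' @examples
#' context_class("C", "T", "ACA")
#' context_class("G", "A", "TGT") # reverse-complemented to A[C>T]A
context_class <- function(ref, alt, context) {
  stopifnot(length(ref) == length(alt), length(ref) == length(context))
  ok <- nchar(context) == 3 & substr(context, 2, 2) == ref & ref != alt
  if (any(!ok)) {
    stop("context must be a 3-mer centred on the reference base, with ref != alt")
  }
  purine <- ref %in% c("A", "G")
  ref[purine] <- chartr("ACGT", "TGCA", ref[purine])
  alt[purine] <- chartr("ACGT", "TGCA", alt[purine])
  context[purine] <- revcomp(context[purine])
  cls <- paste0(
    substr(context, 1, 1), "[", ref, ">", alt, "]", substr(context, 3, 3)
  )
  bad <- !cls %in% sbs_classes()
  if (any(bad)) stop("invalid substitution class: ", cls[which(bad)[1]])
  cls
}
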