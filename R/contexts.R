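#' The canonical 96 single-base-substitution contexts
#'
#' Trinucleotide substitution classes in the standard (COSMIC-style)
#' ordering: the six pyrimidine-centred substitutions C>A, C>G, C>T, T>A,
#' T>C, T>G, each combined with the sixteen 5'/3' flanking-base pairs in
#' alphabetical order, written as e.g. \code{"A[C>A]A"}. Index \code{i}
#' (0-based 0..95) of a mutation's \code{context96} field refers to
#' position \code{i + 1} of this vector.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' sbs96_contexts()[1:4]
sbs96_contexts <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(96)
  i <- 0L
  for (s in subs) for (p5 in bases) for (p3 in bases) {
    i <- i + 1L
    out[i] <- paste0(p5, "[", s, "]", p3)
  }
  out
}

REV_COMP <- c(A = "T", C = "G", G = "C", T = "A")

rev_comp <- function(x) unname(REV_COMP[x])

#' Map a substitution with flanking bases to its 96-class index
#'
#' Purine-reference substitutions are reverse-complemented (both alleles
#' and both flanks, with the flanks swapped) so that every mutation is
#' expressed relative to a pyrimidine (C or T) reference base.
#'
#' @param ref,alt Single reference/alternate bases (A/C/G/T).
#' @param p5,p3 The 5' and 3' flanking bases.
#' @return Integer vector of 0-based context indices (0..95); \code{NA}
#'   for entries containing a base outside A/C/G/T.
#' @export
#' @examples
#' context96_index("C", "A", "A", "A")  # A[C>A]A -> 0
#' context96_index("G", "T", "T", "T")  # reverse complement of the above
context96_index <- function(ref, alt, p5, p3) {
  n <- max(length(ref), length(alt), length(p5), length(p3))
  ref <- rep_len(toupper(ref), n); alt <- rep_len(toupper(alt), n)
  p5 <- rep_len(toupper(p5), n);  p3 <- rep_len(toupper(p3), n)
  ok <- ref %in% names(REV_COMP) & alt %in% names(REV_COMP) &
    p5 %in% names(REV_COMP) & p3 %in% names(REV_COMP) & ref != alt
  flip <- ref %in% c("A", "G")
  r <- ifelse(flip, rev_comp(ref), ref)
  a <- ifelse(flip, rev_comp(alt), alt)
  f5 <- ifelse(flip, rev_comp(p3), p5)
  f3 <- ifelse(flip, rev_comp(p5), p3)
  key <- paste0(f5, "[", r, ">", a, "]", f3)
  idx <- match(key, sbs96_contexts()) - 1L
  idx[!ok] <- NA_integer_
  idx
}

# parse a COSMIC-style Type string like "A[C>A]A" to its 0-based index
context96_from_type <- function(type) {
  match(type, sbs96_contexts()) - 1L
}
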