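# IUPAC nucleotide ambiguity codes and the small sequence utilities the rest
# of the package builds on. A code matches a template base iff the base is in
# the code's set; N in a template matches anything.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# base-set signature (sorted, comma-joined) -> code
IUPAC_LOOKUP <- setNames(
  names(IUPAC_SETS),
  vapply(IUPAC_SETS, function(s) paste(sort(s), collapse = ","), character(1))
)

#' IUPAC code covering a set of bases
#'
#' Returns the minimal IUPAC ambiguity code whose base set equals the set of
#' observed bases.
#'
#' @param bases Character vector of bases from `A`, `C`, `G`, `T` (duplicates
#'   allowed).
#' @return Single IUPAC code letter.
#' @export
iupac_code <- function(bases) {
  bases <- unique(toupper(bases))
  bad <- setdiff(bases, c("A", "C", "G", "T"))
  if (length(bad) > 0) {
    abort(paste0("cannot encode residues: ", paste(bad, collapse = ", ")))
  }
  IUPAC_LOOKUP[[paste(sort(bases), collapse = ",")]]
}

#' Cardinality of an IUPAC code
#'
#' @param code Character vector of IUPAC code letters.
#' @return Integer vector: how many concrete bases each code covers.
#' @export
iupac_cardinality <- function(code) {
  code <- toupper(code)
  vapply(code, function(cc) length(IUPAC_SETS[[cc]]), integer(1), USE.NAMES = FALSE)
}

#' Degeneracy of a primer sequence
#'
#' Product of per-position IUPAC code cardinalities: the number of distinct
#' concrete oligos the degenerate primer encodes.
#'
#' @param seq Primer string over IUPAC codes.
#' @return Integer degeneracy (>= 1).
#' @export
primer_degeneracy <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  unknown <- setdiff(chars, names(IUPAC_SETS))
  if (length(unknown) > 0) {
    abort(paste0("not an IUPAC nucleotide code: ", paste(unknown, collapse = ", ")))
  }
  as.integer(round(prod(iupac_cardinality(chars))))
}

# translate an IUPAC primer into a plain regex (character classes)
iupac_regex <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  paste(vapply(chars, function(cc) {
    s <- IUPAC_SETS[[cc]]
    if (is.null(s)) abort(paste0("not an IUPAC code: ", cc))
    if (length(s) == 1) s else paste0("[", paste(s, collapse = ""), "N]")
  }, character(1)), collapse = "")
}

#' Reverse complement
#'
#' IUPAC-aware reverse complement of nucleotide strings.
#'
#' @param seq Character vector of sequences (IUPAC codes allowed).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(seq))
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# does each position of `seq` (concrete, possibly N) fall inside the matching
# position of IUPAC `pattern`? Both same length. N in seq matches anything.
iupac_match_count <- function(pattern, seq) {
  p <- strsplit(toupper(pattern), "")[[1]]
  s <- strsplit(toupper(seq), "")[[1]]
  stopifnot(length(p) == length(s))
  ok <- mapply(function(pc, sc) {
    sc == "N" || sc %in% IUPAC_SETS[[pc]]
  }, p, s)
  sum(!ok)
}

# Hamming distance between two equal-length plain strings
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) abort("hamming: sequences differ in length")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# vectorised Hamming distances of many strings (equal length L) to one ref
hamming_to_ref <- function(seqs, ref) {
  if (length(seqs) == 0) return(integer(0))
  L <- nchar(ref)
  m <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE), nrow = L)
  r <- strsplit(ref, "")[[1]]
  as.integer(colSums(m != r))
}

# end-gapped distance: Hamming over the shared prefix plus the length excess
end_gapped_dist <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  n <- min(la, lb)
  hamming(substr(a, 1, n), substr(b, 1, n)) + abs(la - lb)
}

# round half-up (the presentation convention for reported percentages)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
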