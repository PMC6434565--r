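# Reference haplotype panel: reading, validation, indexing.
#
# A panel is a tibble with one row per named haplotype (columns `id`,
# `species`, `seq`, `source`), all sequences aligned to the same length.
# Species codes default to the prefix before the first "-" in the record id
# ("ZM-A" -> "ZM"), the labelling style used for dreissenid COI haplotypes;
# a sidecar metadata table can override.

VALID_RESIDUES <- c(names(IUPAC_SETS), "-")

new_ref_alignment <- function(df) {
  structure(df, class = c("ref_alignment", class(tibble())))
}

validate_ref_alignment <- function(df) {
  if (nrow(df) < 2) abort("a reference panel needs at least 2 records")
  if (anyDuplicated(df$id)) {
    dup <- unique(df$id[duplicated(df$id)])
    abort(paste0("duplicate record id(s): ", paste(dup, collapse = ", ")))
  }
  lens <- nchar(df$seq)
  if (any(lens == 0)) abort("empty sequence in panel")
  if (length(unique(lens)) != 1) {
    off <- df$id[lens != lens[1]][1]
    abort(paste0(
      "records are not aligned to equal length (record '", off,
      "' has ", lens[df$id == off][1], " columns, expected ", lens[1], ")"
    ))
  }
  if (any(df$species == "" | is.na(df$species))) {
    abort("every record needs a non-empty species code")
  }
  chars <- unique(strsplit(paste(df$seq, collapse = ""), "")[[1]])
  bad <- setdiff(chars, VALID_RESIDUES)
  if (length(bad) > 0) {
    # locate first offending position for the error message
    for (i in seq_len(nrow(df))) {
      cc <- strsplit(df$seq[i], "")[[1]]
      j <- which(cc %in% bad)
      if (length(j) > 0) {
        abort(paste0(
          "invalid residue '", cc[j[1]], "' in record '", df$id[i],
          "' at column ", j[1]
        ))
      }
    }
  }
  df
}

#' Build a reference alignment from records
#'
#' @param id Character vector of haplotype labels (unique).
#' @param seq Character vector of aligned sequences over `A,C,G,T,N,-` and
#'   IUPAC codes; uppercased on input.
#' @param species Species codes; defaults to the id prefix before the first
#'   `-` (e.g. `"ZM-A"` -> `"ZM"`).
#' @param source Optional provenance strings (e.g. accessions).
#' @return A `ref_alignment` tibble with columns `id`, `species`, `seq`,
#'   `source`.
#' @export
ref_alignment <- function(id, seq, species = NULL, source = NA_character_) {
  species <- species %||% sub("-.*$", "", id)
  df <- tibble(
    id = as.character(id),
    species = as.character(species),
    seq = toupper(as.character(seq)),
    source = as.character(source)
  )
  new_ref_alignment(validate_ref_alignment(df))
}

#' Load an aligned reference panel from FASTA
#'
#' Reads an aligned FASTA of named haplotypes, validates it (equal lengths,
#' unique ids, legal residues) and attaches species codes. Input order is
#' preserved and sequences are uppercased.
#'
#' @param path Path to an aligned FASTA file.
#' @param metadata Optional sidecar: a data frame (or TSV path) with columns
#'   `id`, `species` and optionally `source`, overriding the id-prefix rule.
#' @return A [ref_alignment()] tibble.
#' @export
read_reference_alignment <- function(path, metadata = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  species <- sub("-.*$", "", ids)
  source <- rep(NA_character_, length(ids))
  if (!is.null(metadata)) {
    if (is.character(metadata)) {
      metadata <- utils::read.delim(metadata, stringsAsFactors = FALSE)
    }
    m <- match(ids, metadata$id)
    hit <- !is.na(m)
    species[hit] <- metadata$species[m[hit]]
    if ("source" %in% names(metadata)) source[hit] <- metadata$source[m[hit]]
  }
  ref_alignment(id = ids, seq = seqs, species = species, source = source)
}

#' Write a reference panel to FASTA
#'
#' @param aln A `ref_alignment`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_alignment <- function(aln, path) {
  ss <- Biostrings::BStringSet(setNames(aln$seq, aln$id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Alignment length in columns
#'
#' @param aln A `ref_alignment`.
#' @return Integer number of alignment columns.
#' @export
aln_length <- function(aln) {
  nchar(aln$seq[1])
}

#' Residues observed at an alignment column
#'
#' The set of non-gap residues at a column, optionally restricted to one
#' species. Columns are 1-based.
#'
#' @param aln A `ref_alignment`.
#' @param col Column index (1-based, `1 <= col <= aln_length(aln)`).
#' @param species Optional species code restricting the records considered.
#' @return Character vector of distinct non-gap residues (possibly empty).
#' @export
column_profile <- function(aln, col, species = NULL) {
  L <- aln_length(aln)
  if (length(col) != 1 || col < 1 || col > L) {
    abort(paste0("column ", col, " out of range [1, ", L, "]"))
  }
  seqs <- aln$seq
  if (!is.null(species)) {
    if (!species %in% aln$species) abort(paste0("unknown species: ", species))
    seqs <- seqs[aln$species == species]
  }
  res <- unique(substr(seqs, col, col))
  setdiff(res, "-")
}

# character matrix view of (part of) the alignment; rows = records
aln_matrix <- function(aln, cols = NULL) {
  L <- aln_length(aln)
  m <- matrix(unlist(strsplit(aln$seq, ""), use.names = FALSE),
    nrow = L
  )
  m <- t(m)
  rownames(m) <- aln$id
  if (!is.null(cols)) m <- m[, cols, drop = FALSE]
  m
}

#' @export
print.ref_alignment <- function(x, ...) {
  cat(
    "Reference alignment: ", nrow(x), " haplotypes, ",
    length(unique(x$species)), " species, ", aln_length(x), " columns\n",
    sep = ""
  )
  NextMethod()
}
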