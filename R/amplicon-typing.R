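# Per-sample read processing: trim primers/spacers from merged amplicon
# reads, dereplicate into exact-sequence ASVs, apply the cross-sample
# singleton filter, assign ASVs to haplotype groups by Hamming distance to
# reference amplicons, and summarise into group/species abundance profiles.

#' Read merged amplicon reads from FASTA/FASTQ
#'
#' @param path FASTA or FASTQ file (gzip allowed); format inferred from the
#'   extension.
#' @return Character vector of read sequences (uppercased).
#' @export
read_amplicon_reads <- function(path) {
  fmt <- if (grepl("\\.f(ast)?q(\\.gz)?$", path, ignore.case = TRUE)) "fastq" else "fasta"
  toupper(as.character(Biostrings::readDNAStringSet(path, format = fmt)))
}

#' Trim spacers and primers from merged reads
#'
#' Strips any leading spacer, the IUPAC-matched forward primer and the
#' trailing reverse complement of the reverse primer (plus any trailing
#' spacer), returning the inter-primer cores. Reads in which either primer
#' cannot be located within `max_mismatch` are rejected (counted, not fatal).
#'
#' @param reads Character vector of merged reads (or a FASTA/FASTQ path).
#' @param assay An [assay_def()].
#' @param max_mismatch Mismatches tolerated per primer site (default 0).
#' @return Tibble with column `seq` (the cores of accepted reads). Attributes
#'   `n_input` and `n_rejected` carry the read accounting.
#' @export
trim_reads <- function(reads, assay, max_mismatch = 0) {
  if (length(reads) == 1 && file.exists(reads)) reads <- read_amplicon_reads(reads)
  reads <- toupper(reads)
  n_in <- length(reads)
  fwd <- assay$fwd$seq
  rsite <- revcomp(assay$rev$seq)
  if (max_mismatch == 0) {
    fm <- regexpr(iupac_regex(fwd), reads, perl = TRUE)
    rm_ <- regexpr(iupac_regex(rsite), reads, perl = TRUE)
    core_start <- as.integer(fm) + attr(fm, "match.length")
    core_end <- as.integer(rm_) - 1L
    ok <- fm != -1L & rm_ != -1L & core_end >= core_start
    cores <- substr(reads[ok], core_start[ok], core_end[ok])
  } else {
    ss <- Biostrings::DNAStringSet(reads)
    f <- Biostrings::vmatchPattern(fwd, ss, max.mismatch = max_mismatch, fixed = FALSE)
    r <- Biostrings::vmatchPattern(rsite, ss, max.mismatch = max_mismatch, fixed = FALSE)
    fs <- vapply(Biostrings::startIndex(f), function(v) if (length(v)) v[1] else NA_integer_, integer(1))
    rs <- vapply(Biostrings::startIndex(r), function(v) if (length(v)) v[length(v)] else NA_integer_, integer(1))
    core_start <- fs + nchar(fwd)
    core_end <- rs - 1L
    ok <- !is.na(fs) & !is.na(rs) & core_end >= core_start
    cores <- substr(reads[ok], core_start[ok], core_end[ok])
  }
  out <- tibble(seq = cores)
  attr(out, "n_input") <- n_in
  attr(out, "n_rejected") <- n_in - length(cores)
  out
}

#' Dereplicate trimmed reads into ASVs
#'
#' Exact-sequence dereplication with an optional minimum-count filter;
#' deterministic order (count descending, then sequence).
#'
#' @param seqs Character vector of trimmed cores, or the tibble returned by
#'   [trim_reads()].
#' @param min_count Drop sequences seen fewer times (default 1 keeps all).
#' @param sample_id Optional sample label added as a column.
#' @return Tibble with `sample_id` (if given), `seq`, `count`. Warns when
#'   nothing survives the filter.
#' @export
dereplicate <- function(seqs, min_count = 1L, sample_id = NULL) {
  if (is.data.frame(seqs)) seqs <- seqs$seq
  if (length(seqs) == 0) {
    warn("no reads to dereplicate")
    out <- tibble(seq = character(), count = integer())
  } else {
    tab <- table(seqs)
    out <- tibble(seq = names(tab), count = as.integer(tab))
    out <- out[out$count >= min_count, , drop = FALSE]
    out <- out[order(-out$count, out$seq), , drop = FALSE]
    if (nrow(out) == 0) warn("ASV table empty after min_count filter")
  }
  if (!is.null(sample_id)) out <- dplyr::mutate(out, sample_id = sample_id, .before = 1)
  out
}

#' Remove ASVs present in only one sample
#'
#' The cross-sample artifact filter: an ASV sequence is retained iff it
#' occurs (count >= 1) in at least two samples of the batch; removal is
#' applied uniformly across samples.
#'
#' @param tables A single tidy ASV table with columns `sample_id`, `seq`,
#'   `count` (rows from several samples), or a list of per-sample tables.
#' @return Filtered tidy ASV table; attribute `removed` is a per-sample
#'   tibble of removed read counts. With a single-sample batch the input is
#'   passed through with a warning (the filter is undefined).
#' @export
filter_single_sample_asvs <- function(tables) {
  if (!is.data.frame(tables)) tables <- dplyr::bind_rows(tables)
  if (!all(c("sample_id", "seq", "count") %in% names(tables))) {
    abort("need columns sample_id, seq, count")
  }
  n_samp <- length(unique(tables$sample_id))
  if (n_samp < 2) {
    warn("single-sample batch: cross-sample filter undefined, passing through")
    attr(tables, "removed") <- tibble(sample_id = unique(tables$sample_id), removed_reads = 0L)
    return(tables)
  }
  presence <- tables |>
    dplyr::distinct(.data$sample_id, .data$seq) |>
    dplyr::count(.data$seq, name = "n_samples")
  keep <- presence$seq[presence$n_samples >= 2]
  removed <- tables |>
    dplyr::filter(!.data$seq %in% keep) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(removed_reads = sum(.data$count), .groups = "drop")
  out <- dplyr::filter(tables, .data$seq %in% keep)
  attr(out, "removed") <- removed
  out
}

#' Assign ASVs to haplotype groups
#'
#' Nearest-reference assignment: an exact match takes its group at distance
#' 0; otherwise the nearest group by Hamming distance on equal-length
#' sequences (length mismatches cost infinity unless within
#' `indel_tolerance`, then compared end-gapped with the length excess counted
#' as mismatches). Distances above `max_dist`, and ties between groups at the
#' minimal distance, yield `"unassigned"`.
#'
#' @param table ASV table (columns `seq`, `count`, optionally `sample_id`).
#' @param partition A [resolvability_partition()] (its `representative`
#'   column supplies the reference amplicons), or a named character vector of
#'   group representatives.
#' @param max_dist Maximum mismatches tolerated for an assignment (default 1).
#' @param indel_tolerance Maximum length difference compared end-gapped
#'   (default 0: length mismatch is never assignable).
#' @return The input table with columns `group_label`, `distance`,
#'   `ambiguous` appended (`group_label == "unassigned"` where applicable).
#' @export
assign_asvs <- function(table, partition, max_dist = 1L, indel_tolerance = 0L) {
  refs <- if (is.data.frame(partition)) {
    setNames(partition$representative, partition$group_label)
  } else {
    partition
  }
  if (length(refs) == 0) abort("empty reference amplicon set")
  uniq <- unique(table$seq)
  nref <- length(refs)
  reflen <- nchar(refs)

  dmat <- matrix(Inf, nrow = length(uniq), ncol = nref)
  ulen <- nchar(uniq)
  for (j in seq_len(nref)) {
    same <- which(ulen == reflen[j])
    if (length(same) > 0) {
      dmat[same, j] <- hamming_to_ref(uniq[same], refs[j])
    }
    if (indel_tolerance > 0) {
      near <- which(ulen != reflen[j] & abs(ulen - reflen[j]) <= indel_tolerance)
      for (i in near) dmat[i, j] <- end_gapped_dist(uniq[i], refs[j])
    }
  }
  best <- apply(dmat, 1, min)
  n_best <- rowSums(dmat == best)
  ambiguous <- n_best >= 2 & is.finite(best)
  label <- names(refs)[apply(dmat, 1, which.min)]
  label[ambiguous | best > max_dist] <- "unassigned"
  dist_out <- ifelse(is.finite(best), best, NA_real_)

  idx <- match(table$seq, uniq)
  dplyr::mutate(
    table,
    group_label = label[idx],
    distance = dist_out[idx],
    ambiguous = ambiguous[idx]
  )
}

#' Group- and species-level abundance profile of a sample
#'
#' Sums assigned reads by haplotype group and converts to proportions over
#' assigned reads; unassigned reads are reported separately and excluded
#' from denominators. Species are parsed from group labels (prefix before
#' the first `-`) or supplied via the partition.
#'
#' @param assignments Output of [assign_asvs()] (columns `seq`, `count`,
#'   `group_label`; `sample_id` optional).
#' @param partition Optional [resolvability_partition()] supplying
#'   group -> species (mixed groups get `NA`).
#' @return A `sample_profile` tibble: `sample_id`, `group`, `species`,
#'   `reads`, `proportion` (per sample, over assigned reads). Attribute
#'   `unassigned` is a per-sample tibble of unassigned read counts. Samples
#'   with zero assigned reads are flagged with a warning and dropped from
#'   the proportion table.
#' @export
profile_samples <- function(assignments, partition = NULL) {
  df <- assignments
  if (!"sample_id" %in% names(df)) df$sample_id <- "sample"
  unas <- df |>
    dplyr::filter(.data$group_label == "unassigned") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(unassigned_reads = sum(.data$count), .groups = "drop")
  asg <- df |>
    dplyr::filter(.data$group_label != "unassigned") |>
    dplyr::group_by(.data$sample_id, group = .data$group_label) |>
    dplyr::summarise(reads = sum(.data$count), .groups = "drop_last") |>
    dplyr::mutate(proportion = .data$reads / sum(.data$reads)) |>
    dplyr::ungroup()
  none <- setdiff(unique(df$sample_id), unique(asg$sample_id))
  if (length(none) > 0) {
    warn(paste0("no assigned reads for sample(s): ", paste(none, collapse = ", "),
                "; proportions undefined"))
  }
  asg$species <- group_species(asg$group, partition)
  out <- dplyr::select(asg, "sample_id", "group", "species", "reads", "proportion")
  out <- dplyr::arrange(out, .data$sample_id, dplyr::desc(.data$reads))
  class(out) <- c("sample_profile", class(out))
  attr(out, "unassigned") <- unas
  out
}

group_species <- function(groups, partition = NULL) {
  if (!is.null(partition) && is.data.frame(partition)) {
    sp <- partition$species[match(groups, partition$group_label)]
    fallback <- is.na(sp) & !groups %in% partition$group_label
    sp[fallback] <- sub("-.*$", "", groups[fallback])
    return(sp)
  }
  sub("-.*$", "", groups)
}

#' Build a profile directly from group read counts
#'
#' Convenience constructor for pre-tabulated read counts (e.g. a published
#' per-group read-number table).
#'
#' @param counts Named numeric vector of reads per group, or a tibble with
#'   columns `group`, `reads`.
#' @param sample_id Sample label.
#' @param partition Optional partition for group -> species mapping.
#' @return A `sample_profile` tibble (see [profile_samples()]).
#' @export
profile_from_counts <- function(counts, sample_id = "sample", partition = NULL) {
  if (!is.data.frame(counts)) {
    counts <- tibble(group = names(counts), reads = as.numeric(counts))
  }
  out <- counts |>
    dplyr::mutate(
      sample_id = sample_id,
      species = group_species(.data$group, partition),
      proportion = .data$reads / sum(.data$reads)
    ) |>
    dplyr::select("sample_id", "group", "species", "reads", "proportion")
  class(out) <- c("sample_profile", class(out))
  attr(out, "unassigned") <- tibble(sample_id = sample_id, unassigned_reads = 0)
  out
}

#' Collapse a profile to species level
#'
#' @param profile A `sample_profile`.
#' @return Tibble `sample_id`, `species`, `reads`, `proportion` (per sample).
#' @export
species_profile <- function(profile) {
  profile |>
    as_tibble() |>
    dplyr::group_by(.data$sample_id, .data$species) |>
    dplyr::summarise(reads = sum(.data$reads), .groups = "drop_last") |>
    dplyr::mutate(proportion = .data$reads / sum(.data$reads)) |>
    dplyr::ungroup()
}

#' Merge paired-end reads by naive overlap consensus
#'
#' A minimal overlap merger for pre-processing FASTQ pairs when merging has
#' not been done upstream: the best overlap (longest with at most
#' `max_mismatch` mismatches, at least `min_overlap` long) joins each pair;
#' pairs with no acceptable overlap are dropped.
#'
#' @param fwd,rev Character vectors of forward reads and reverse reads (the
#'   reverse reads are reverse-complemented internally).
#' @param min_overlap Minimum acceptable overlap length.
#' @param max_mismatch Maximum mismatches within the overlap.
#' @return Character vector of merged sequences (shorter than the input when
#'   pairs fail to merge).
#' @export
merge_pairs <- function(fwd, rev, min_overlap = 12L, max_mismatch = 0L) {
  stopifnot(length(fwd) == length(rev))
  rc <- revcomp(rev)
  out <- character(0)
  for (i in seq_along(fwd)) {
    a <- fwd[i]; b <- rc[i]
    la <- nchar(a); lb <- nchar(b)
    merged <- NA_character_
    for (ov in seq(min(la, lb), min_overlap)) {
      if (hamming(substr(a, la - ov + 1, la), substr(b, 1, ov)) <= max_mismatch) {
        merged <- paste0(a, substr(b, ov + 1, lb))
        break
      }
    }
    if (!is.na(merged)) out <- c(out, merged)
  }
  out
}
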