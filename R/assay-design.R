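# Assay discovery and evaluation on an aligned haplotype panel.
#
# An assay is a degenerate primer pair plus the inter-primer amplicon
# interval on the alignment (primers excluded). Interspecific diagnostic
# power is measured as fixed differences (columns whose residue sets are
# disjoint between two species); intraspecific resolvability as the
# partition of haplotypes into classes with identical gap-stripped amplicon
# substrings. All intervals are 1-based inclusive alignment columns.

#' Degenerate primer
#'
#' @param seq Primer string over IUPAC codes, 5'->3'.
#' @param start Alignment column of the window start (or `NA` for free
#'   primers).
#' @param orient `"forward"` or `"reverse"`.
#' @return A `degenerate_primer` object.
#' @export
degenerate_primer <- function(seq, start = NA_integer_, orient = c("forward", "reverse")) {
  orient <- match.arg(orient)
  seq <- toupper(seq)
  if (nchar(seq) < 1) abort("primer sequence must be non-empty")
  structure(
    list(seq = seq, start = as.integer(start), orient = orient,
         degeneracy = primer_degeneracy(seq)),
    class = "degenerate_primer"
  )
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat("<degenerate_primer> ", x$seq, " (", x$orient, ", degeneracy ",
      x$degeneracy, ")\n", sep = "")
  invisible(x)
}

#' Assay definition
#'
#' A named primer pair with its inter-primer amplicon interval (primers
#' excluded) on the alignment.
#'
#' @param name Assay label.
#' @param fwd,rev [degenerate_primer()] objects (rev given 5'->3' on the
#'   reverse strand).
#' @param amplicon_start,amplicon_end 1-based inclusive alignment columns of
#'   the amplicon.
#' @return An `assay_def` object.
#' @export
assay_def <- function(name, fwd, rev, amplicon_start, amplicon_end) {
  if (amplicon_end < amplicon_start) abort("amplicon interval is empty")
  structure(
    list(name = name, fwd = fwd, rev = rev,
         amplicon_start = as.integer(amplicon_start),
         amplicon_end = as.integer(amplicon_end)),
    class = "assay_def"
  )
}

#' @export
print.assay_def <- function(x, ...) {
  cat("<assay_def> ", x$name, ": amplicon columns [", x$amplicon_start, ", ",
      x$amplicon_end, "] (", x$amplicon_end - x$amplicon_start + 1, " nt)\n",
      "  F: ", x$fwd$seq, "\n  R: ", x$rev$seq, "\n", sep = "")
  invisible(x)
}

# expand a residue (IUPAC or N) seen in the panel to its concrete base set;
# gaps are dropped by callers before this is applied
expand_residues <- function(res) {
  unique(unlist(IUPAC_SETS[res], use.names = FALSE))
}

#' Degenerate consensus primer over a window
#'
#' Per column, emits the minimal IUPAC code covering all bases observed in
#' the panel; fails if any record carries a gap inside the window (conserved
#' primer sites must be gapless).
#'
#' @param aln A [ref_alignment()].
#' @param start,end Window columns (1-based inclusive).
#' @param orient `"forward"` (consensus as-is) or `"reverse"` (reverse
#'   complement of the column consensus, i.e. the primer as synthesised).
#' @return A [degenerate_primer()].
#' @export
degenerate_consensus <- function(aln, start, end, orient = c("forward", "reverse")) {
  orient <- match.arg(orient)
  L <- aln_length(aln)
  if (start < 1 || end > L || end < start) {
    abort(paste0("window [", start, ", ", end, "] outside alignment [1, ", L, "]"))
  }
  m <- aln_matrix(aln, start:end)
  if (any(m == "-")) {
    j <- which(apply(m == "-", 2, any))[1]
    abort(paste0("window contains a gap at column ", start + j - 1,
                 "; conserved primer sites must be gapless"))
  }
  codes <- apply(m, 2, function(col) iupac_code(expand_residues(unique(col))))
  seq <- paste(codes, collapse = "")
  if (orient == "reverse") seq <- revcomp(seq)
  degenerate_primer(seq, start = start, orient = orient)
}

#' Fixed differences between two species over an interval
#'
#' Counts alignment columns at which the (gap-free, ambiguity-expanded)
#' residue sets of the two species are disjoint and non-empty: the standard
#' diagnostic-SNP criterion. `N` expands to all four bases, so ambiguity
#' cannot create phantom diagnostics.
#'
#' @param aln A [ref_alignment()].
#' @param species_a,species_b Species codes present in the panel.
#' @param start,end Interval columns (default: whole alignment).
#' @return List with `count` and the diagnostic `columns` (1-based).
#' @export
fixed_differences <- function(aln, species_a, species_b,
                              start = 1L, end = aln_length(aln)) {
  for (sp in c(species_a, species_b)) {
    if (!sp %in% aln$species) abort(paste0("unknown species: ", sp))
  }
  idx <- fixed_diff_indicator(aln, species_a, species_b)
  cols <- which(idx[start:end]) + start - 1L
  list(count = length(cols), columns = cols)
}

# logical vector over all columns: TRUE where residue sets are disjoint
fixed_diff_indicator <- function(aln, species_a, species_b) {
  ma <- aln_matrix(aln[aln$species == species_a, , drop = FALSE])
  mb <- aln_matrix(aln[aln$species == species_b, , drop = FALSE])
  vapply(seq_len(ncol(ma)), function(j) {
    a <- setdiff(unique(ma[, j]), "-")
    b <- setdiff(unique(mb[, j]), "-")
    if (length(a) == 0 || length(b) == 0) return(FALSE)
    a <- expand_residues(a)
    b <- expand_residues(b)
    length(intersect(a, b)) == 0
  }, logical(1))
}

# canonical compressed label for a set of haplotype ids: "ZM-A,M,O" when all
# ids share one "SP-X" prefix, otherwise the sorted ids joined with "/"
compress_label <- function(ids) {
  ids <- sort(ids)
  pre <- sub("-.*$", "", ids)
  suf <- sub("^[^-]*-", "", ids)
  if (length(unique(pre)) == 1 && all(grepl("-", ids))) {
    paste0(pre[1], "-", paste(suf, collapse = ","))
  } else {
    paste(ids, collapse = "/")
  }
}

#' Resolvability partition of a panel under an assay
#'
#' Groups haplotypes whose gap-stripped amplicon substrings are identical:
#' the equivalence classes a sequencing read can resolve. Groups containing
#' more than one species are flagged (`mixed`); none are expected for a
#' species-diagnostic assay.
#'
#' @param aln A [ref_alignment()].
#' @param assay An [assay_def()] whose amplicon lies within the alignment.
#' @return A tibble (one row per group): `group_label`, `members` (list of
#'   ids), `n_members`, `species` (`NA` if mixed), `mixed`, `representative`
#'   (the shared amplicon substring). Attribute `assay` holds the assay name.
#' @export
resolvability_partition <- function(aln, assay) {
  sub <- substr(aln$seq, assay$amplicon_start, assay$amplicon_end)
  sub <- gsub("-", "", sub, fixed = TRUE)
  groups <- split(seq_len(nrow(aln)), sub)
  out <- purrr::map_dfr(groups, function(ix) {
    ids <- sort(aln$id[ix])
    sps <- unique(aln$species[ix])
    tibble(
      group_label = compress_label(ids),
      members = list(ids),
      n_members = length(ids),
      species = if (length(sps) == 1) sps else NA_character_,
      mixed = length(sps) > 1,
      representative = sub[ix[1]]
    )
  })
  out <- dplyr::arrange(out, .data$group_label)
  attr(out, "assay") <- assay$name
  out
}

#' Diagnostic report for an assay
#'
#' Summarises interspecific diagnostic power (fixed differences per species
#' pair within the amplicon) and intraspecific resolvability (single-species
#' groups per species).
#'
#' @param aln A [ref_alignment()].
#' @param assay An [assay_def()].
#' @return List with `assay`, `fixed_diffs` (tibble per species pair),
#'   `n_groups_per_species` (tibble), `diagnostic_columns`, and the
#'   `partition`.
#' @export
diagnostic_report <- function(aln, assay) {
  sps <- unique(aln$species)
  pairs <- utils::combn(sps, 2, simplify = FALSE)
  fd <- purrr::map_dfr(pairs, function(p) {
    r <- fixed_differences(aln, p[1], p[2], assay$amplicon_start, assay$amplicon_end)
    tibble(species_a = p[1], species_b = p[2], fixed_diffs = r$count,
           columns = list(r$columns))
  })
  part <- resolvability_partition(aln, assay)
  ng <- part |>
    dplyr::filter(!.data$mixed) |>
    dplyr::count(.data$species, name = "n_groups")
  list(
    assay = assay$name,
    fixed_diffs = fd,
    n_groups_per_species = ng,
    diagnostic_columns = sort(unique(unlist(fd$columns))),
    partition = part
  )
}

#' Scan for candidate assays
#'
#' Enumerates pairs of conserved (gapless, low-degeneracy) primer windows
#' whose inter-primer distance falls within the amplicon-length bounds, and
#' ranks candidates by descending minimum interspecific fixed differences,
#' then descending number of resolvability groups, then ascending combined
#' degeneracy; remaining ties break deterministically by descending total
#' primer length and ascending position.
#'
#' @param aln A [ref_alignment()].
#' @param primer_len Length-2 integer range of primer window lengths.
#' @param max_degeneracy Maximum degeneracy allowed per primer window.
#' @param amplicon_len Length-2 numeric range of inter-primer distances.
#' @return Tibble of ranked candidates with primer windows, sequences,
#'   amplicon interval, `fixed_diffs` (minimum over species pairs),
#'   `n_groups` and `degeneracy`. Empty (zero rows) when no window pair
#'   satisfies the constraints; a message states the binding constraint.
#' @export
scan_primer_windows <- function(aln, primer_len = c(18L, 30L),
                                max_degeneracy = 32,
                                amplicon_len = c(100L, 250L)) {
  stopifnot(length(primer_len) == 2, length(amplicon_len) == 2,
            all(primer_len >= 1), all(amplicon_len >= 1))
  L <- aln_length(aln)
  m <- aln_matrix(aln)
  codes <- vapply(seq_len(L), function(j) {
    col <- unique(m[, j])
    if ("-" %in% col) return(NA_character_) # gapped columns cannot host a primer
    iupac_code(expand_residues(col))
  }, character(1))
  card <- ifelse(is.na(codes), NA_real_, iupac_cardinality(ifelse(is.na(codes), "A", codes)))
  logcard <- log(card)
  code_str <- paste(ifelse(is.na(codes), "-", codes), collapse = "")

  # all (start, len) windows that are gapless with degeneracy <= cap
  windows <- list()
  for (len in seq(primer_len[1], primer_len[2])) {
    if (len > L) next
    starts <- seq_len(L - len + 1)
    # rolling log-degeneracy
    cs <- cumsum(c(0, logcard))
    ldeg <- cs[starts + len] - cs[starts]
    ok <- !is.na(ldeg) & ldeg <= log(max_degeneracy) + 1e-9
    if (any(ok)) {
      windows[[length(windows) + 1]] <- tibble(
        start = starts[ok], end = starts[ok] + len - 1L, len = len,
        degeneracy = round(exp(ldeg[ok]))
      )
    }
  }
  if (length(windows) == 0) {
    message("scan: no gapless window satisfies max_degeneracy = ", max_degeneracy)
    return(empty_scan_result())
  }
  win <- dplyr::bind_rows(windows)

  # pair windows: amplicon = (fwd end, rev start) exclusive interval
  sps <- unique(aln$species)
  pairs <- utils::combn(sps, 2, simplify = FALSE)
  ind <- lapply(pairs, function(p) cumsum(c(0, fixed_diff_indicator(aln, p[1], p[2]))))

  cand <- list()
  for (i in seq_len(nrow(win))) {
    fe <- win$end[i]
    amp_start <- fe + 1L
    rv <- win[win$start > fe + amplicon_len[1] - 1L &
              win$start <= fe + amplicon_len[2] + 1L, , drop = FALSE]
    if (nrow(rv) == 0) next
    alen <- rv$start - amp_start
    keep <- alen >= amplicon_len[1] & alen <= amplicon_len[2]
    rv <- rv[keep, , drop = FALSE]
    if (nrow(rv) == 0) next
    cand[[length(cand) + 1]] <- tibble(
      fwd_start = win$start[i], fwd_end = fe, fwd_deg = win$degeneracy[i],
      fwd_len = win$len[i],
      rev_start = rv$start, rev_end = rv$end, rev_deg = rv$degeneracy,
      rev_len = rv$len,
      amplicon_start = amp_start, amplicon_end = rv$start - 1L
    )
  }
  if (length(cand) == 0) {
    message("scan: conserved windows found, but no pair within amplicon length [",
            amplicon_len[1], ", ", amplicon_len[2], "]")
    return(empty_scan_result())
  }
  cand <- dplyr::bind_rows(cand)

  # score unique amplicon intervals once
  uniq <- dplyr::distinct(cand, .data$amplicon_start, .data$amplicon_end)
  uniq$fixed_diffs <- vapply(seq_len(nrow(uniq)), function(k) {
    s <- uniq$amplicon_start[k]; e <- uniq$amplicon_end[k]
    min(vapply(ind, function(cs) cs[e + 1] - cs[s], numeric(1)))
  }, numeric(1))
  uniq$n_groups <- vapply(seq_len(nrow(uniq)), function(k) {
    sub <- gsub("-", "", substr(aln$seq, uniq$amplicon_start[k], uniq$amplicon_end[k]),
                fixed = TRUE)
    length(unique(sub))
  }, numeric(1))

  cand <- dplyr::left_join(cand, uniq, by = c("amplicon_start", "amplicon_end"))
  cand$degeneracy <- cand$fwd_deg * cand$rev_deg
  cand <- dplyr::arrange(
    cand,
    dplyr::desc(.data$fixed_diffs), dplyr::desc(.data$n_groups),
    .data$degeneracy, dplyr::desc(.data$fwd_len + .data$rev_len),
    .data$fwd_start, .data$rev_start
  )
  cand$fwd_seq <- substring(code_str, cand$fwd_start, cand$fwd_end)
  cand$rev_seq <- revcomp(substring(code_str, cand$rev_start, cand$rev_end))
  cand$rank <- seq_len(nrow(cand))
  dplyr::select(
    cand, "rank", "fwd_start", "fwd_end", "fwd_seq", "rev_start", "rev_end",
    "rev_seq", "amplicon_start", "amplicon_end", "fixed_diffs", "n_groups",
    "degeneracy"
  )
}

empty_scan_result <- function() {
  tibble(
    rank = integer(), fwd_start = integer(), fwd_end = integer(),
    fwd_seq = character(), rev_start = integer(), rev_end = integer(),
    rev_seq = character(), amplicon_start = integer(), amplicon_end = integer(),
    fixed_diffs = numeric(), n_groups = numeric(), degeneracy = numeric()
  )
}

#' Turn a scan candidate into an assay definition
#'
#' @param aln A [ref_alignment()].
#' @param candidate One row of the [scan_primer_windows()] result.
#' @param name Assay label.
#' @return An [assay_def()].
#' @export
candidate_assay <- function(aln, candidate, name = "assay") {
  assay_def(
    name,
    fwd = degenerate_primer(candidate$fwd_seq, candidate$fwd_start, "forward"),
    rev = degenerate_primer(candidate$rev_seq, candidate$rev_start, "reverse"),
    amplicon_start = candidate$amplicon_start,
    amplicon_end = candidate$amplicon_end
  )
}

#' In-silico PCR on an unaligned template
#'
#' Locates the best IUPAC-aware match of the forward primer and of the
#' reverse primer's reverse complement (each with at most `max_mismatch`
#' mismatches) and returns the inter-primer substring, primers excluded.
#' When several placements tie, the leftmost forward site with the nearest
#' compatible reverse site wins.
#'
#' @param assay An [assay_def()] (or a list with `fwd$seq` and `rev$seq`).
#' @param template Template sequence over `A,C,G,T,N`.
#' @param max_mismatch Mismatches tolerated per primer (default 0).
#' @return The amplicon substring, or `NA_character_` when either primer has
#'   no acceptable site (a no-hit, not an error).
#' @export
in_silico_pcr <- function(assay, template, max_mismatch = 0) {
  template <- toupper(template)
  fwd <- assay$fwd$seq
  rsite <- revcomp(assay$rev$seq)
  f <- find_primer_sites(fwd, template, max_mismatch)
  if (length(f) == 0) return(NA_character_)
  r <- find_primer_sites(rsite, template, max_mismatch)
  if (length(r) == 0) return(NA_character_)
  fl <- nchar(fwd)
  for (fs in f) {
    ok <- r[r >= fs + fl] # reverse site must start at/after the fwd site end
    if (length(ok) > 0) {
      core <- substr(template, fs + fl, ok[1] - 1)
      if (nchar(core) == 0) return(NA_character_)
      return(core)
    }
  }
  NA_character_
}

# start positions of acceptable primer sites, ascending
find_primer_sites <- function(primer, template, max_mismatch) {
  if (max_mismatch == 0) {
    pat <- iupac_regex(primer)
    out <- integer(0)
    offset <- 0L
    rest <- template
    repeat {
      m <- regexpr(pat, rest, perl = TRUE)
      if (m == -1) break
      out <- c(out, offset + as.integer(m))
      skip <- as.integer(m)
      offset <- offset + skip
      rest <- substr(rest, skip + 1L, nchar(rest))
      if (nchar(rest) < nchar(primer)) break
    }
    out
  } else {
    hits <- Biostrings::matchPattern(
      primer, Biostrings::DNAString(template),
      max.mismatch = max_mismatch, fixed = FALSE
    )
    sort(Biostrings::start(hits))
  }
}

#' Serialise assays to YAML
#'
#' @param assays A named list of [assay_def()] objects (or a single one).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_assay_yaml <- function(assays, path) {
  if (inherits(assays, "assay_def")) assays <- setNames(list(assays), assays$name)
  doc <- lapply(assays, function(a) {
    list(
      name = a$name, fwd = a$fwd$seq, rev = a$rev$seq,
      amplicon_start = a$amplicon_start, amplicon_end = a$amplicon_end,
      amplicon_length = a$amplicon_end - a$amplicon_start + 1L
    )
  })
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read assays from YAML
#'
#' @param path YAML path written by [write_assay_yaml()].
#' @return Named list of [assay_def()] objects.
#' @export
read_assay_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  out <- lapply(doc, function(d) {
    start <- d$amplicon_start %||% 1L
    end <- if (!is.null(d$amplicon_end)) d$amplicon_end else start + d$amplicon_length - 1L
    assay_def(
      d$name,
      fwd = degenerate_primer(d$fwd, orient = "forward"),
      rev = degenerate_primer(d$rev, orient = "reverse"),
      amplicon_start = start,
      amplicon_end = end
    )
  })
  setNames(out, vapply(out, function(a) a$name, character(1)))
}
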