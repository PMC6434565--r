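# Synthetic data with planted ground truth: haplotype panels whose assay
# windows, fixed-difference columns and resolvability partitions are known
# by construction, plus multinomial read simulation with per-base error.
#
# The default panel emulates the structure of a two-species dreissenid COI
# panel: 20 "ZM" + 17 "QM" haplotypes aligned over 570 columns, two planted
# assays (a 169-nt core with 24 interspecific fixed differences flanked by
# 29/24-nt conserved primer windows, and a 175-nt core with 26 fixed
# differences flanked by 25/25-nt windows), and per-assay collapse plans
# that dictate which haplotypes share identical amplicons. Distinct
# within-species groups differ by a private block of 3 columns, so group
# amplicons are >= 3 substitutions apart and low-rate sequencing error
# cannot convert one group's reads into another's. Conserved regions are
# confined to the planted primer windows: pad regions carry high-diversity
# decoy columns every few positions so no other low-degeneracy window pair
# exists.

BASES <- c("A", "C", "G", "T")

default_plan_A <- function() {
  list(
    ZM = list(c("A", "M", "O"), "C", "G", c("B", "D"), c("E", "F"),
              c("H", "I"), c("J", "K"), c("L", "N"), c("P", "Q"),
              c("R", "S", "T")),
    QM = list("A", "F", "G", c("B", "C"), c("D", "E"), c("H", "I", "J"),
              c("K", "L", "M"), c("N", "O", "P", "Q"))
  )
}

default_plan_B <- function() {
  list(
    ZM = list(c("A", "C"), "G", "M", "O", c("B", "D", "E", "F", "H"),
              c("I", "J", "K", "L", "N"), c("P", "Q", "R", "S", "T")),
    QM = list(c("A", "F", "G"), "B", "C", c("D", "E"), c("H", "I"),
              c("J", "K"), c("L", "M"), c("N", "O"), c("P", "Q"))
  )
}

#' Specification for a synthetic haplotype panel
#'
#' @param n_zm,n_qm Haplotypes per species (lettered `A`, `B`, ...).
#' @param length Alignment length in columns.
#' @param fixed_diffs_a,fixed_diffs_b Interspecific fixed differences to
#'   plant in the two assay cores.
#' @param core_len_a,core_len_b Amplicon (inter-primer) lengths.
#' @param primer_len_a,primer_len_b Length-2 vectors: forward and reverse
#'   primer window lengths per assay.
#' @param plan_a,plan_b Collapse plans: per species, a list of haplotype
#'   letter groups partitioning the species (first group carries the core
#'   consensus). Defaults mirror a six-group / five-group focal structure.
#' @param group_sep Private columns mutated per non-reference group
#'   (pairwise group separation >= `group_sep`).
#' @param seed RNG seed; generation is bit-reproducible given the seed.
#' @return A `panel_spec` list.
#' @export
panel_spec <- function(n_zm = 20, n_qm = 17, length = 570,
                       fixed_diffs_a = 24, fixed_diffs_b = 26,
                       core_len_a = 169, core_len_b = 175,
                       primer_len_a = c(29L, 24L), primer_len_b = c(25L, 25L),
                       plan_a = default_plan_A(), plan_b = default_plan_B(),
                       group_sep = 3L, seed = 1L) {
  spec <- list(
    n_zm = n_zm, n_qm = n_qm, length = length,
    fixed_diffs_a = fixed_diffs_a, fixed_diffs_b = fixed_diffs_b,
    core_len_a = core_len_a, core_len_b = core_len_b,
    primer_len_a = primer_len_a, primer_len_b = primer_len_b,
    plan_a = plan_a, plan_b = plan_b, group_sep = group_sep,
    seed = seed
  )
  class(spec) <- "panel_spec"
  validate_panel_spec(spec)
  spec
}

validate_panel_spec <- function(spec) {
  if (spec$n_zm > 26 || spec$n_qm > 26) abort("at most 26 haplotypes per species")
  for (pl in list(spec$plan_a, spec$plan_b)) {
    for (sp in names(pl)) {
      n <- if (sp == "ZM") spec$n_zm else spec$n_qm
      want <- LETTERS[seq_len(n)]
      got <- sort(unlist(pl[[sp]]))
      if (!identical(got, sort(want))) {
        abort(paste0("collapse plan for ", sp, " is not a partition of ", n,
                     " haplotypes"))
      }
    }
  }
  need_a <- spec$fixed_diffs_a +
    spec$group_sep * (length(spec$plan_a$ZM) + length(spec$plan_a$QM) - 2)
  need_b <- spec$fixed_diffs_b +
    spec$group_sep * (length(spec$plan_b$ZM) + length(spec$plan_b$QM) - 2)
  if (need_a > spec$core_len_a || need_b > spec$core_len_b) {
    abort("planted columns do not fit inside the amplicon cores")
  }
  layout <- panel_layout(spec)
  if (layout$total > spec$length) {
    abort(paste0("alignment length ", spec$length, " too short for layout (needs ",
                 layout$total, ")"))
  }
  invisible(spec)
}

# fixed left-to-right layout: pad / buffer / fwdA / coreA / buffer / revA /
# buffer / pad / buffer / fwdB / coreB / buffer / revB / buffer / pad
panel_layout <- function(spec) {
  pos <- 1L
  take <- function(n) {
    out <- seq.int(pos, pos + n - 1L)
    pos <<- pos + n
    out
  }
  # buffers sit strictly outside the primer pairs: the inter-primer interval
  # (the physical amplicon) is exactly the planted core. Inward window
  # extension is blocked by the diagnostic columns at the core edges instead.
  pad1 <- take(20L)
  buf1 <- take(2L)
  fwdA <- take(spec$primer_len_a[1])
  coreA <- take(spec$core_len_a)
  revA <- take(spec$primer_len_a[2])
  buf2 <- take(2L)
  mid <- take(40L)
  buf3 <- take(2L)
  fwdB <- take(spec$primer_len_b[1])
  coreB <- take(spec$core_len_b)
  revB <- take(spec$primer_len_b[2])
  buf4 <- take(2L)
  total <- pos - 1L
  tail_pad <- if (total < spec$length) seq.int(pos, spec$length) else integer(0)
  list(
    pad = c(pad1, mid, tail_pad),
    buffers = c(buf1, buf2, buf3, buf4),
    fwdA = fwdA, coreA = coreA, revA = revA,
    fwdB = fwdB, coreB = coreB, revB = revB,
    total = total
  )
}

# positions (relative to a core of length L) of the planted fixed
# differences: always include the first and last core column, rest spread
plant_fixed_positions <- function(L, k) {
  if (k <= 2) return(unique(c(1L, L))[seq_len(k)])
  inner <- round(seq(3, L - 2, length.out = k - 2))
  unique(c(1L, as.integer(inner), L))
}

#' Generate a synthetic haplotype panel with known structure
#'
#' Builds the aligned panel dictated by a [panel_spec()] and returns it with
#' its ground truth: the planted assay definitions (consensus primers over
#' the conserved flanks), the per-assay collapse partitions, and the planted
#' fixed-difference columns.
#'
#' @param spec A [panel_spec()].
#' @return List: `alignment` (a [ref_alignment()]), `truth` (list with
#'   `assays`, `partitions` — named lists of member-id vectors —, and
#'   `fixed_columns`, absolute alignment columns per assay).
#' @export
make_panel <- function(spec = panel_spec()) {
  validate_panel_spec(spec)
  set.seed(spec$seed)
  L <- spec$length
  lay <- panel_layout(spec)
  ids <- c(paste0("ZM-", LETTERS[seq_len(spec$n_zm)]),
           paste0("QM-", LETTERS[seq_len(spec$n_qm)]))
  species <- sub("-.*$", "", ids)
  n <- length(ids)

  consensus <- sample(BASES, L, replace = TRUE)
  m <- matrix(rep(consensus, each = n), nrow = n)
  rownames(m) <- ids

  # decoy diversity: every 8th pad column and all buffer columns carry all
  # four bases, so no low-degeneracy window exists outside the planted flanks
  decoy <- c(lay$pad[seq_along(lay$pad) %% 8L == 1L], lay$buffers)
  for (cc in decoy) {
    m[, cc] <- BASES[(seq_len(n) - 1L) %% 4L + 1L]
  }

  truth <- list(assays = list(), partitions = list(), fixed_columns = list())
  plant_core <- function(m, core, k_fixed, plan) {
    fixed_rel <- plant_fixed_positions(length(core), k_fixed)
    fixed_abs <- core[fixed_rel]
    for (cc in fixed_abs) {
      alt <- BASES[(match(m[1, cc], BASES)) %% 4L + 1L]
      m[species == "QM", cc] <- alt
    }
    pool <- setdiff(seq_along(core), fixed_rel)
    used <- 0L
    for (sp in names(plan)) {
      groups <- plan[[sp]]
      for (g in seq_along(groups)[-1]) { # first group keeps the consensus
        block_rel <- pool[used + seq_len(spec$group_sep)]
        used <- used + spec$group_sep
        rows <- paste0(sp, "-", groups[[g]])
        for (cc in core[block_rel]) {
          alt <- BASES[(match(m[1, cc], BASES)) %% 4L + 1L]
          # the column consensus may already differ between species at fixed
          # columns; block columns are taken from the non-fixed pool so every
          # other row still carries the original consensus base
          m[rows, cc] <- alt
        }
      }
    }
    list(m = m, fixed_abs = fixed_abs)
  }

  pa <- plant_core(m, lay$coreA, spec$fixed_diffs_a, spec$plan_a)
  m <- pa$m
  pb <- plant_core(m, lay$coreB, spec$fixed_diffs_b, spec$plan_b)
  m <- pb$m

  seqs <- apply(m, 1, paste, collapse = "")
  aln <- ref_alignment(id = ids, seq = seqs, species = species,
                       source = "synthetic")

  mk_assay <- function(name, fwd_cols, core, rev_cols) {
    assay_def(
      name,
      fwd = degenerate_consensus(aln, fwd_cols[1], fwd_cols[length(fwd_cols)]),
      rev = degenerate_consensus(aln, rev_cols[1], rev_cols[length(rev_cols)],
                                 orient = "reverse"),
      amplicon_start = core[1], amplicon_end = core[length(core)]
    )
  }
  truth$assays <- list(
    assayA = mk_assay("assayA", lay$fwdA, lay$coreA, lay$revA),
    assayB = mk_assay("assayB", lay$fwdB, lay$coreB, lay$revB)
  )
  plan_members <- function(plan) {
    out <- list()
    for (sp in names(plan)) {
      for (g in plan[[sp]]) {
        ids_g <- paste0(sp, "-", g)
        out[[compress_label(ids_g)]] <- sort(ids_g)
      }
    }
    out[order(names(out))]
  }
  truth$partitions <- list(
    assayA = plan_members(spec$plan_a),
    assayB = plan_members(spec$plan_b)
  )
  truth$fixed_columns <- list(assayA = pa$fixed_abs, assayB = pb$fixed_abs)
  truth$layout <- lay

  list(alignment = aln, truth = truth)
}

#' Amplicon template sequences of a panel under an assay
#'
#' Gap-stripped inter-primer substrings, one per haplotype.
#'
#' @param aln A [ref_alignment()].
#' @param assay An [assay_def()].
#' @return Named character vector (haplotype id -> amplicon core).
#' @export
panel_amplicons <- function(aln, assay) {
  sub <- gsub("-", "", substr(aln$seq, assay$amplicon_start, assay$amplicon_end),
              fixed = TRUE)
  setNames(sub, aln$id)
}

# sample a concrete realisation of a degenerate primer for each of n reads
realise_primer <- function(primer, n) {
  chars <- strsplit(primer, "")[[1]]
  amb <- which(iupac_cardinality(chars) > 1)
  if (length(amb) == 0) return(rep(primer, n))
  out <- matrix(rep(chars, n), ncol = n)
  for (j in amb) {
    out[j, ] <- sample(IUPAC_SETS[[chars[j]]], n, replace = TRUE)
  }
  apply(out, 2, paste, collapse = "")
}

random_seqs <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(BASES, len[i], replace = TRUE), collapse = "")
  }, character(1))
}

# i.i.d. per-base substitution errors at the given rate
mutate_seqs <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  L <- nchar(seqs)
  nerr <- rbinom(length(seqs), L, rate)
  for (i in which(nerr > 0)) {
    ch <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(L[i], nerr[i])
    for (p in pos) ch[p] <- sample(setdiff(BASES, ch[p]), 1)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate merged amplicon reads for a mixed-template sample
#'
#' Read counts per template are a multinomial draw on the template weights
#' (copy numbers or proportions). Each read is `spacer + forward primer
#' realisation + template core + revcomp(reverse primer realisation) +
#' spacer`, with i.i.d. per-base substitution errors applied over the whole
#' read and optional corruption of the forward primer site.
#'
#' @param design Named numeric vector: template name -> copies (or
#'   proportions); names must exist in `templates`.
#' @param templates Named character vector of amplicon core sequences
#'   (e.g. [panel_amplicons()]).
#' @param assay An [assay_def()] supplying the primers.
#' @param depth Total reads to draw.
#' @param error_rate Per-base substitution probability (default 0).
#' @param spacer_len Integer range of random spacer lengths appended at both
#'   ends (default `7:17`).
#' @param primer_corruption Fraction of reads whose forward primer is
#'   replaced by random bases (unrecoverable at trimming; default 0).
#' @param seed Optional RNG seed.
#' @return Character vector of `depth` (or fewer if corruption removes
#'   nothing — always `depth`) reads in randomised order. Attribute
#'   `true_counts` carries the multinomial draw per template.
#' @export
simulate_reads <- function(design, templates, assay, depth,
                           error_rate = 0, spacer_len = 7:17,
                           primer_corruption = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  missing <- setdiff(names(design), names(templates))
  if (length(missing) > 0) {
    abort(paste0("design names absent from templates: ", paste(missing, collapse = ", ")))
  }
  if (depth <= 0) abort("depth must be positive")
  stopifnot(error_rate >= 0, error_rate <= 1,
            primer_corruption >= 0, primer_corruption <= 1)
  w <- as.numeric(design)
  counts <- as.integer(rmultinom(1, depth, w / sum(w)))
  names(counts) <- names(design)

  cores <- rep(unname(templates[names(design)]), counts)
  n <- length(cores)
  fwd <- realise_primer(assay$fwd$seq, n)
  if (primer_corruption > 0) {
    bad <- which(stats::runif(n) < primer_corruption)
    if (length(bad) > 0) {
      fwd[bad] <- random_seqs(length(bad), nchar(fwd[bad]))
    }
  }
  rev_site <- revcomp(realise_primer(assay$rev$seq, n))
  sp1 <- random_seqs(n, spacer_len[sample.int(length(spacer_len), n, replace = TRUE)])
  sp2 <- random_seqs(n, spacer_len[sample.int(length(spacer_len), n, replace = TRUE)])
  reads <- paste0(sp1, fwd, cores, rev_site, sp2)
  reads <- mutate_seqs(reads, error_rate)
  reads <- reads[sample.int(n)]
  attr(reads, "true_counts") <- counts
  reads
}

#' Simulate a multi-sample field-like batch
#'
#' One read set per (site, date) sample, each drawn from its own
#' haplotype-group proportion vector; optionally plants artifact ASVs
#' present in exactly one sample (to exercise the cross-sample filter).
#'
#' @param compositions Named list: sample id -> named proportion vector over
#'   template names.
#' @param templates Named character vector of amplicon cores.
#' @param assay An [assay_def()].
#' @param metadata Optional tibble with `sample_id`, `site`, `date`, `type`
#'   rows matching the composition names.
#' @param depth Reads per sample.
#' @param error_rate Per-base substitution probability.
#' @param artifact Optional list `(sample_id =, seq =, count =)`: spike
#'   `count` reads of an artifact core into one sample.
#' @param seed RNG seed.
#' @return List: `manifest` (tibble `sample_id`, `site`, `date`, `type`,
#'   `n_reads`), `reads` (named list of read vectors).
#' @export
make_field_batch <- function(compositions, templates, assay,
                             metadata = NULL, depth = 50000,
                             error_rate = 0, artifact = NULL, seed = 1L) {
  set.seed(seed)
  reads <- list()
  for (sid in names(compositions)) {
    reads[[sid]] <- simulate_reads(
      compositions[[sid]], templates, assay, depth, error_rate = error_rate
    )
  }
  if (!is.null(artifact)) {
    sid <- artifact$sample_id
    if (!sid %in% names(reads)) abort("artifact sample_id not in compositions")
    art <- simulate_reads(
      setNames(1, "artifact"), setNames(artifact$seq, "artifact"), assay,
      depth = artifact$count %||% 10L
    )
    reads[[sid]] <- sample(c(reads[[sid]], as.character(art)))
  }
  manifest <- tibble(
    sample_id = names(reads),
    n_reads = unname(vapply(reads, length, integer(1)))
  )
  if (!is.null(metadata)) {
    manifest <- dplyr::left_join(manifest, metadata, by = "sample_id")
  }
  list(manifest = manifest, reads = reads)
}

#' Write reads to FASTA
#'
#' @param reads Character vector of sequences.
#' @param path Output path (`.gz` allowed).
#' @param prefix Read-name prefix.
#' @return `path`, invisibly.
#' @export
write_reads_fasta <- function(reads, path, prefix = "read") {
  ss <- Biostrings::DNAStringSet(as.character(reads))
  names(ss) <- paste0(prefix, "_", seq_along(ss))
  Biostrings::writeXStringSet(ss, path, compress = grepl("\\.gz$", path))
  invisible(path)
}
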