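test_that("degenerate consensus emits minimal IUPAC codes with correct degeneracy", {
  aln <- ref_alignment(id = c("ZM-A", "ZM-B"), seq = c("ACGT", "ACGT"))
  pr <- degenerate_consensus(aln, 1, 4)
  expect_equal(pr$seq, "ACGT")
  expect_equal(pr$degeneracy, 1)

  aln2 <- ref_alignment(id = c("ZM-A", "ZM-B"), seq = c("ACG", "ATG"))
  pr2 <- degenerate_consensus(aln2, 1, 3)
  expect_equal(pr2$seq, "AYG")
  expect_equal(pr2$degeneracy, 2)

  aln3 <- ref_alignment(id = c("ZM-A", "ZM-B"), seq = c("A-GT", "ACGT"))
  expect_error(degenerate_consensus(aln3, 1, 4), "gap")
})

test_that("degeneracy of the published COIA primers comes from their 2-fold codes", {
  pr <- coia_primers()
  # five 2-fold codes (Y,K,R,W,K) in the forward primer -> 2^5
  expect_equal(pr$fwd$degeneracy, 32)
  expect_equal(pr$fwd$degeneracy,
               prod(iupac_cardinality(strsplit(pr$fwd$seq, "")[[1]])))
  expect_equal(pr$rev$degeneracy, 16)
})

test_that("fixed differences require disjoint residue sets", {
  aln <- tiny_panel() # ZM ACGT vs QM ACGA
  fd <- fixed_differences(aln, "ZM", "QM")
  expect_equal(fd$count, 1)
  expect_equal(fd$columns, 4L)

  # shared residue at the column breaks fixity
  aln2 <- ref_alignment(id = c("ZM-A", "ZM-B", "QM-A"),
                        seq = c("ACGT", "ACGC", "ACGC"))
  expect_equal(fixed_differences(aln2, "ZM", "QM")$count, 0)

  expect_error(fixed_differences(aln, "ZM", "XX"), "unknown species")
})

test_that("fixed differences match a brute-force double loop and are symmetric/additive", {
  set.seed(91)
  for (rep in 1:5) {
    aln <- random_panel(n = 8, len = 40, alphabet = c("A", "C", "G"))
    fd <- fixed_differences(aln, "S1", "S2")
    chars <- strsplit(aln$seq, "")
    oracle <- 0L
    for (col in 1:40) {
      a <- unique(vapply(chars[aln$species == "S1"], `[`, character(1), col))
      b <- unique(vapply(chars[aln$species == "S2"], `[`, character(1), col))
      if (length(intersect(a, b)) == 0) oracle <- oracle + 1L
    }
    expect_equal(fd$count, oracle)
    # symmetry
    expect_equal(fixed_differences(aln, "S2", "S1")$count, fd$count)
    # additivity over disjoint intervals
    expect_equal(
      fixed_differences(aln, "S1", "S2", 1, 20)$count +
        fixed_differences(aln, "S1", "S2", 21, 40)$count,
      fd$count
    )
  }
})

test_that("resolvability partition groups identical gap-stripped amplicons", {
  aln <- ref_alignment(
    id = c("ZM-A", "ZM-B", "ZM-C", "ZM-D"),
    seq = c("AACGTT", "AACGTT", "AACGTT", "AACCTT")
  )
  assay <- assay_def("t", degenerate_primer("AA"), degenerate_primer("AA"), 3, 4)
  part <- resolvability_partition(aln, assay)
  expect_equal(nrow(part), 2)
  expect_setequal(part$n_members, c(3, 1))
  expect_equal(part$group_label[part$n_members == 3], "ZM-A,B,C")
})

test_that("fixture collapse plans give six groups (assay A) and five (assay B) over the focal haplotypes", {
  p <- fixture_panel()
  partA <- resolvability_partition(p$alignment, p$truth$assays$assayA)
  partB <- resolvability_partition(p$alignment, p$truth$assays$assayB)
  focalA <- partA[vapply(partA$members, function(m) any(m %in% focal_haplotypes), logical(1)), ]
  focalB <- partB[vapply(partB$members, function(m) any(m %in% focal_haplotypes), logical(1)), ]
  expect_equal(nrow(focalA), 6)
  expect_equal(nrow(focalB), 5)
  expect_true("ZM-A,M,O" %in% focalA$group_label)
  expect_true("ZM-A,C" %in% focalB$group_label)
  expect_true("QM-A,F,G" %in% focalB$group_label)
  expect_false(any(partA$mixed))
})

test_that("partition under a wider interval refines the partition under a nested one", {
  p <- fixture_panel()
  A <- p$truth$assays$assayA
  inner <- assay_def("inner", A$fwd, A$rev, A$amplicon_start + 30, A$amplicon_end - 30)
  part_wide <- resolvability_partition(p$alignment, A)
  part_inner <- resolvability_partition(p$alignment, inner)
  # every wide group must sit inside exactly one inner group
  member_to_inner <- setNames(
    rep(part_inner$group_label, lengths(part_inner$members)),
    unlist(part_inner$members)
  )
  for (i in seq_len(nrow(part_wide))) {
    expect_length(unique(member_to_inner[part_wide$members[[i]]]), 1)
  }
})

test_that("every panel sequence matches its own window consensus under IUPAC semantics", {
  p <- fixture_panel()
  lay <- p$truth$layout
  pr <- degenerate_consensus(p$alignment, lay$fwdA[1], lay$fwdA[length(lay$fwdA)])
  for (s in substr(p$alignment$seq, lay$fwdA[1], lay$fwdA[length(lay$fwdA)])) {
    expect_equal(dreissamp:::iupac_match_count(pr$seq, s), 0)
  }
})

test_that("scanning finds the planted assay top-ranked and is deterministic", {
  p <- fixture_panel()
  A <- p$truth$assays$assayA
  B <- p$truth$assays$assayB
  candA <- scan_primer_windows(p$alignment, primer_len = c(18L, 29L),
                               max_degeneracy = 1, amplicon_len = c(150L, 172L))
  expect_equal(candA$amplicon_start[1], A$amplicon_start)
  expect_equal(candA$amplicon_end[1], A$amplicon_end)
  expect_equal(candA$fwd_seq[1], A$fwd$seq)
  expect_equal(candA$rev_seq[1], A$rev$seq)
  expect_equal(candA$fixed_diffs[1], 24)

  # with both cores in range, the 26-difference core outranks the 24
  cand <- scan_primer_windows(p$alignment, primer_len = c(18L, 29L),
                              max_degeneracy = 1, amplicon_len = c(150L, 200L))
  expect_equal(cand$amplicon_start[1], B$amplicon_start)
  expect_equal(cand$amplicon_end[1], B$amplicon_end)

  cand2 <- scan_primer_windows(p$alignment, primer_len = c(18L, 29L),
                               max_degeneracy = 1, amplicon_len = c(150L, 200L))
  expect_identical(cand, cand2)
})

test_that("max_degeneracy excludes windows spanning polymorphic columns", {
  aln <- ref_alignment(
    id = c("ZM-A", "ZM-B", "QM-A"),
    seq = c(
      paste0("AAAACCCCGGGG", "TTTT", "AAAACCCCGGGG"),
      paste0("AAAACCCCGGGG", "TTTT", "AAAACCCCGGGG"),
      paste0("AAAACCCCGGGG", "AAAA", "AAAACCCCGGGG")
    )
  )
  cand <- scan_primer_windows(aln, primer_len = c(4L, 4L), max_degeneracy = 1,
                              amplicon_len = c(4L, 8L))
  # no candidate window may overlap the polymorphic middle block
  expect_true(all(cand$fwd_end <= 12 | cand$fwd_start >= 17))
  expect_true(all(cand$rev_end <= 12 | cand$rev_start >= 17))
})

test_that("an all-identical panel yields candidates with zero fixed differences", {
  aln <- ref_alignment(
    id = c("ZM-A", "QM-A"),
    seq = rep(strrep("ACGT", 20), 2)
  )
  cand <- scan_primer_windows(aln, primer_len = c(10L, 10L), max_degeneracy = 1,
                              amplicon_len = c(20L, 40L))
  expect_gt(nrow(cand), 0)
  expect_true(all(cand$fixed_diffs == 0))
})

test_that("in-silico PCR recovers the inter-primer core and reports no-hits", {
  p <- fixture_panel()
  A <- p$truth$assays$assayA
  amp <- panel_amplicons(p$alignment, A)
  tmpl <- paste0("GATTACA", A$fwd$seq, amp[["ZM-C"]], revcomp(A$rev$seq), "TTG")
  expect_equal(in_silico_pcr(A, tmpl), unname(amp[["ZM-C"]]))
  # missing reverse site -> no-hit, distinguishable from an error
  expect_true(is.na(in_silico_pcr(A, paste0(A$fwd$seq, amp[["ZM-C"]]))))
  # one mismatch in the forward site needs tolerance
  broken <- tmpl
  substr(broken, 9, 9) <- if (substr(broken, 9, 9) == "A") "C" else "A"
  expect_true(is.na(in_silico_pcr(A, broken, max_mismatch = 0)))
  expect_equal(in_silico_pcr(A, broken, max_mismatch = 1), unname(amp[["ZM-C"]]))
})

test_that("in-silico PCR agrees with the aligned amplicon substrings", {
  p <- fixture_panel()
  A <- p$truth$assays$assayA
  amp <- panel_amplicons(p$alignment, A)
  full <- gsub("-", "", p$alignment$seq, fixed = TRUE)
  for (i in seq_len(8)) {
    expect_equal(in_silico_pcr(A, full[i]), unname(amp[i]))
  }
})

test_that("assay YAML round-trips", {
  p <- fixture_panel()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_assay_yaml(p$truth$assays, f)
  back <- read_assay_yaml(f)
  expect_equal(back$assayA$fwd$seq, p$truth$assays$assayA$fwd$seq)
  expect_equal(back$assayB$amplicon_end, p$truth$assays$assayB$amplicon_end)
})
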