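test_that("trimming strips spacers and primers and rejects broken primer sites", {
  p <- fixture_panel()
  A <- p$truth$assays$assayA
  amp <- panel_amplicons(p$alignment, A)
  core <- unname(amp[["QM-A"]])
  good <- paste0("ACGTACGT", A$fwd$seq, core, revcomp(A$rev$seq), "TTGACA")
  bad <- paste0("ACGTACGT", strrep("A", nchar(A$fwd$seq)), core, revcomp(A$rev$seq))
  tr <- trim_reads(c(good, bad), A)
  expect_equal(tr$seq, core)
  expect_equal(attr(tr, "n_input"), 2L)
  expect_equal(attr(tr, "n_rejected"), 1L)
  # mismatch-tolerant trimming recovers a read with one primer error
  one_off <- good
  substr(one_off, 10, 10) <- if (substr(one_off, 10, 10) == "A") "C" else "A"
  expect_equal(nrow(trim_reads(one_off, A, max_mismatch = 0)), 0)
  expect_equal(trim_reads(one_off, A, max_mismatch = 1)$seq, core)
})

test_that("a planted primer corruption rate is recovered by the reject fraction", {
  p <- fixture_panel()
  A <- p$truth$assays$assayA
  amp <- panel_amplicons(p$alignment, A)
  n <- 4000
  reads <- simulate_reads(
    setNames(c(2, 1), c("ZM-C", "QM-A")), amp, A, depth = n,
    error_rate = 0, primer_corruption = 0.05, seed = 21
  )
  tr <- trim_reads(reads, A)
  frac <- attr(tr, "n_rejected") / n
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("dereplication counts exactly, filters by min_count, orders deterministically", {
  tab <- dereplicate(c("AAA", "AAA", "AAT"))
  expect_equal(tab$seq, c("AAA", "AAT"))
  expect_equal(tab$count, c(2L, 1L))
  tab2 <- dereplicate(c("AAA", "AAA", "AAT"), min_count = 2)
  expect_equal(tab2$seq, "AAA")
  expect_warning(dereplicate(character(0)), "no reads")

  # monotonicity: increasing min_count never increases the ASV count
  set.seed(5)
  reads <- sample(c("AA", "AC", "AG", "AT"), 300, replace = TRUE,
                  prob = c(.5, .3, .15, .05))
  n_asv <- vapply(1:30, function(k) nrow(dereplicate(reads, min_count = k)), integer(1))
  expect_true(all(diff(n_asv) <= 0))
})

test_that("the cross-sample filter removes exactly the single-sample ASVs, order-invariantly", {
  tabs <- dplyr::bind_rows(
    tibble::tibble(sample_id = "s1", seq = c("X", "Y"), count = c(5L, 2L)),
    tibble::tibble(sample_id = "s2", seq = "X", count = 7L)
  )
  out <- filter_single_sample_asvs(tabs)
  expect_setequal(unique(out$seq), "X")
  removed <- attr(out, "removed")
  expect_equal(removed$removed_reads[removed$sample_id == "s1"], 2L)

  # all shared -> unchanged
  shared <- dplyr::bind_rows(
    tibble::tibble(sample_id = "s1", seq = c("X", "Y"), count = c(1L, 1L)),
    tibble::tibble(sample_id = "s2", seq = c("X", "Y"), count = c(9L, 9L))
  )
  expect_equal(nrow(filter_single_sample_asvs(shared)), 4)

  # permutation invariance over sample order
  flipped <- filter_single_sample_asvs(tabs[order(tabs$sample_id, decreasing = TRUE), ])
  expect_setequal(unique(flipped$seq), "X")

  expect_warning(
    filter_single_sample_asvs(tibble::tibble(sample_id = "s1", seq = "X", count = 1L)),
    "single-sample"
  )
})

test_that("assignment picks the nearest group, honours max_dist, and calls ties unassigned", {
  refs <- c("g1" = "AAAA", "g2" = "AATT", "g3" = "GGGGG")
  tab <- tibble::tibble(
    seq = c("AAAA", "AAAT", "AATA", "CCCA", "GGGG"),
    count = rep(1L, 5)
  )
  out <- assign_asvs(tab, refs, max_dist = 1)
  expect_equal(out$group_label[1], "g1")
  expect_equal(out$distance[1], 0)
  # AAAT: 1 from g1, 1 from g2 -> tie -> unassigned + ambiguous
  expect_equal(out$group_label[2], "unassigned")
  expect_true(out$ambiguous[2])
  # AATA: 1 from g1 (pos 3) and 1 from g2 (pos 4) -> also a tie
  expect_equal(out$group_label[3], "unassigned")
  # CCCA: uniquely nearest g1 at distance 3, beyond max_dist
  expect_equal(out$group_label[4], "unassigned")
  expect_false(out$ambiguous[4])
  # GGGG: length mismatch to g3 -> unassignable without indel tolerance
  expect_equal(out$group_label[5], "unassigned")
  out2 <- assign_asvs(tab[5, ], refs, max_dist = 1, indel_tolerance = 1)
  expect_equal(out2$group_label, "g3")
  expect_equal(out2$distance, 1)

  expect_error(assign_asvs(tab, character(0)), "empty reference")
})

test_that("assignment distances agree with a brute-force all-pairs oracle", {
  set.seed(77)
  bases <- c("A", "C", "G", "T")
  refs <- setNames(
    replicate(4, paste(sample(bases, 12, replace = TRUE), collapse = "")),
    paste0("g", 1:4)
  )
  asvs <- replicate(40, paste(sample(bases, 12, replace = TRUE), collapse = ""))
  tab <- tibble::tibble(seq = unique(asvs), count = 1L)
  out <- assign_asvs(tab, refs, max_dist = 12)
  for (i in seq_len(nrow(out))) {
    d <- vapply(refs, function(r) {
      sum(strsplit(out$seq[i], "")[[1]] != strsplit(r, "")[[1]])
    }, numeric(1))
    expect_equal(out$distance[i], min(d))
    if (sum(d == min(d)) == 1) {
      expect_equal(out$group_label[i], names(which.min(d)))
    } else {
      expect_equal(out$group_label[i], "unassigned")
    }
  }
})

test_that("profiles turn the published MC1 read counts into the published percentages", {
  counts <- mock_read_counts("COIA")
  mc1 <- counts[counts$community == 1, ]
  prof <- profile_from_counts(setNames(mc1$reads, mc1$group), sample_id = "MC1")
  pct <- dreissamp:::round_half_up(100 * prof$proportion, 1)
  expect_equal(pct[prof$group == "ZM-A,M,O"], 31.4)
  expect_equal(pct[prof$group == "QM-A"], 57.3)
  # species rollup: ZM groups + QM groups cover all reads
  sp <- species_profile(prof)
  expect_equal(sum(sp$reads), sum(mc1$reads))
  expect_equal(sum(sp$proportion), 1)
})

test_that("reads are conserved across trim, assignment and profile accounting", {
  p <- fixture_panel()
  A <- p$truth$assays$assayA
  amp <- panel_amplicons(p$alignment, A)
  part <- resolvability_partition(p$alignment, A)
  reads <- simulate_reads(
    mc_design_vector(1), amp, A, depth = 5000,
    error_rate = 0.002, primer_corruption = 0.03, seed = 31
  )
  tr <- trim_reads(reads, A)
  tab <- dereplicate(tr, sample_id = "s")
  asg <- assign_asvs(tab, part, max_dist = 1)
  prof <- profile_samples(asg, part)
  assigned <- sum(prof$reads)
  unassigned <- sum(attr(prof, "unassigned")$unassigned_reads)
  expect_equal(assigned + unassigned + attr(tr, "n_rejected"), 5000)
})

test_that("error-free typing returns the generator's multinomial frequencies exactly", {
  p <- fixture_panel()
  A <- p$truth$assays$assayA
  amp <- panel_amplicons(p$alignment, A)
  part <- resolvability_partition(p$alignment, A)
  des <- mc_design_vector(1)
  reads <- simulate_reads(des, amp, A, depth = sum(des), error_rate = 0, seed = 13)
  truth <- attr(reads, "true_counts")
  prof <- reads |>
    trim_reads(A) |>
    dereplicate(sample_id = "MC1") |>
    assign_asvs(part, max_dist = 0) |>
    profile_samples(part)
  groups <- assay_groups("COIA")
  for (g in names(groups)) {
    expect_equal(prof$reads[prof$group == g], sum(truth[groups[[g]]]))
  }
  expect_equal(sum(prof$reads), sum(des))
})

test_that("naive pair merging joins on the best overlap and drops unmergeable pairs", {
  a <- "ACGTACGTACGTAAAA"
  merged <- merge_pairs(a, revcomp("ACGTAAAACCGGTTCC"), min_overlap = 8)
  expect_equal(merged, "ACGTACGTACGTAAAACCGGTTCC")
  expect_length(merge_pairs("AAAATTTT", revcomp("GGGGCCCC"), min_overlap = 4), 0)
})
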