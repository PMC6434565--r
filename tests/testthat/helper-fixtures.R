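# Shared fixtures: one default synthetic panel (built once per test run)
# and a couple of tiny hand-made alignments.

fixture_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_panel(panel_spec(seed = 7))
    cache
  }
})

# minimal two-record panel
tiny_panel <- function() {
  ref_alignment(id = c("ZM-A", "QM-A"), seq = c("ACGT", "ACGA"))
}

# random small aligned panel (no gaps unless asked); restricted alphabet
# makes substring collisions (shared amplicons) likely
random_panel <- function(n = 10, len = 60, alphabet = c("A", "C"), gaps = FALSE,
                         n_species = 2) {
  sp <- rep_len(paste0("S", seq_len(n_species)), n)
  seqs <- vapply(seq_len(n), function(i) {
    chars <- sample(alphabet, len, replace = TRUE)
    if (gaps) {
      k <- sample(0:2, 1)
      if (k > 0) chars[sample.int(len, k)] <- "-"
    }
    paste(chars, collapse = "")
  }, character(1))
  ref_alignment(id = paste0(sp, "-", sprintf("%02d", seq_len(n))),
                seq = seqs, species = sp)
}

# the eight focal mock-community haplotypes
focal_haplotypes <- c("ZM-A", "ZM-M", "ZM-O", "ZM-C", "ZM-G",
                      "QM-A", "QM-F", "QM-G")

mc_design_vector <- function(mc) {
  d <- mock_design(mc)
  setNames(d$copies, d$haplotype)
}
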