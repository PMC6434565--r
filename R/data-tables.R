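# Published input tables for the dreissenid COI assays: the mock-community
# template copy numbers, the per-group sequencing read numbers for mock
# communities 1-4, the aquarium census, and the COIA primer pair. These are
# benchmark inputs (not computed results) and feed the validation vignettes,
# tests and the acceptance script.

#' Mock-community template copy numbers
#'
#' Eight mock communities rotating the copy-number series 6,000 / 3,000 /
#' 1,500 / 750 / 375 / 188 / 94 / 47 across five zebra mussel haplotypes
#' (ZM-A, ZM-C, ZM-G, ZM-M, ZM-O) and three quagga mussel haplotypes (QM-A,
#' QM-F, QM-G).
#'
#' @param communities Which communities to return (default all eight).
#' @return Tidy tibble: `community`, `haplotype`, `copies`.
#' @export
mock_design <- function(communities = 1:8) {
  haps <- c("QM-A", "ZM-A", "ZM-M", "ZM-C", "QM-G", "QM-F", "ZM-G", "ZM-O")
  series <- c(6000, 3000, 1500, 750, 375, 188, 94, 47)
  purrr::map_dfr(communities, function(mc) {
    tibble(
      community = mc,
      haplotype = haps,
      copies = series[((seq_along(haps) - 1 + (mc - 1)) %% 8) + 1]
    )
  })
}

#' Sequencing read numbers per haplotype group, mock communities 1-4
#'
#' Read counts per resolvable haplotype group for the two assays; the COIB
#' MC4 row block is reproduced as printed although its counts are internally
#' inconsistent with the published percentages.
#'
#' @param assay `"COIA"` or `"COIB"`.
#' @return Tidy tibble: `assay`, `community`, `group`, `reads`.
#' @export
mock_read_counts <- function(assay = c("COIA", "COIB")) {
  assay <- match.arg(assay)
  if (assay == "COIA") {
    groups <- c("ZM-A,M,O", "ZM-C", "ZM-G", "QM-A", "QM-G", "QM-F")
    counts <- list(
      `1` = c(44985, 5649, 1695, 82114, 6321, 2577),
      `2` = c(99521, 5058, 1544, 71510, 4521, 3237),
      `3` = c(42468, 1687, 98326, 54804, 6454, 2024),
      `4` = c(21288, 602, 52667, 8828, 1540, 111060)
    )
  } else {
    groups <- c("ZM-A,C", "ZM-M", "ZM-G", "ZM-O", "QM-A,F,G")
    counts <- list(
      `1` = c(125618, 43243, 1040, 508, 161660),
      `2` = c(681, 66, 5, 641, 974),
      `3` = c(34876, 13122, 114816, 12560, 70771),
      `4` = c(17288, 5523, 61521, 7076, 105464)
    )
  }
  purrr::map_dfr(names(counts), function(mc) {
    tibble(assay = assay, community = as.integer(mc), group = groups,
           reads = counts[[mc]])
  })
}

#' Haplotype-group memberships of the two COI assays
#'
#' The collapse structure over the eight mock-community haplotypes: COIA
#' resolves six groups (ZM-A, ZM-M and ZM-O share one amplicon), COIB five
#' (ZM-A with ZM-C; QM-A, QM-F and QM-G together).
#'
#' @param assay `"COIA"` or `"COIB"`.
#' @return Named list: group label -> member haplotype ids.
#' @export
assay_groups <- function(assay = c("COIA", "COIB")) {
  assay <- match.arg(assay)
  if (assay == "COIA") {
    list(
      "ZM-A,M,O" = c("ZM-A", "ZM-M", "ZM-O"),
      "ZM-C" = "ZM-C",
      "ZM-G" = "ZM-G",
      "QM-A" = "QM-A",
      "QM-G" = "QM-G",
      "QM-F" = "QM-F"
    )
  } else {
    list(
      "ZM-A,C" = c("ZM-A", "ZM-C"),
      "ZM-M" = "ZM-M",
      "ZM-G" = "ZM-G",
      "ZM-O" = "ZM-O",
      "QM-A,F,G" = c("QM-A", "QM-F", "QM-G")
    )
  }
}

#' Aquarium census: individuals and wet mass per haplotype
#'
#' Known compositions of the three mixed-species aquarium experiments:
#' numbers of adults and end-of-experiment wet mass (g) per COIA-resolvable
#' haplotype group.
#'
#' @return Tidy tibble: `aquarium`, `group`, `species`, `n`, `mass_g`.
#' @export
aquarium_census <- function() {
  tibble(
    aquarium = rep(1:3, each = 4),
    group = rep(c("ZM-A", "ZM-M", "QM-A", "QM-G"), 3),
    species = rep(c("ZM", "ZM", "QM", "QM"), 3),
    n = c(24, 6, 6, 0, 12, 5, 13, 1, 15, 1, 10, 0),
    mass_g = c(3.03, 0.75, 1.28, 0, 1.14, 0.65, 1.56, 0.10, 2.68, 0.06, 6.37, 0)
  )
}

#' The COIA degenerate primer pair
#'
#' The published species- and haplotype-diagnostic COI primer set flanking a
#' 169-nt amplicon with 24 fixed interspecific differences.
#'
#' @return List with `fwd` and `rev` [degenerate_primer()] objects.
#' @export
coia_primers <- function() {
  list(
    fwd = degenerate_primer("AGTGTTYTKATTCGTTTRGAGCTWAGKGC", orient = "forward"),
    rev = degenerate_primer("GAYAGGTARAACCCAAAAWCTWAC", orient = "reverse")
  )
}
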