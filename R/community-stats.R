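# Multi-sample community comparison: Bray-Curtis and Kulczynski
# dissimilarities of haplotype-group relative abundances, NMDS ordination
# (vegan::metaMDS) with ANOSIM grouping tests, and the minimum-spanning
# haplotype network weighted by nucleotide differences.

#' Bray-Curtis dissimilarity
#'
#' `1 - 2 * sum(min(x, y)) / (sum(x) + sum(y))`, in `[0, 1]`.
#'
#' @param x,y Non-negative abundance vectors of equal length, not both all
#'   zero.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  check_abund_pair(x, y)
  1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
}

#' Kulczynski dissimilarity
#'
#' `1 - 0.5 * (sum(min(x, y)) / sum(x) + sum(min(x, y)) / sum(y))`, the
#' abundance-based Kulczynski index in `[0, 1]` (0 = equal, 1 = completely
#' different).
#'
#' @inheritParams bray_curtis
#' @return Dissimilarity in `[0, 1]`.
#' @export
kulczynski <- function(x, y) {
  check_abund_pair(x, y)
  if (sum(x) == 0 || sum(y) == 0) abort("zero-sum vector: dissimilarity undefined")
  w <- sum(pmin(x, y))
  1 - 0.5 * (w / sum(x) + w / sum(y))
}

check_abund_pair <- function(x, y) {
  if (length(x) != length(y)) abort("vectors differ in length")
  if (any(x < 0) || any(y < 0)) abort("abundances must be non-negative")
  if (sum(x) + sum(y) == 0) abort("both vectors all-zero: dissimilarity undefined")
  invisible(TRUE)
}

#' Samples-by-groups community matrix from profiles
#'
#' Pivots tidy profiles to a wide matrix of relative abundances (rows =
#' samples, columns = groups, rows summing to 1), the input for ordination.
#'
#' @param profiles A `sample_profile` (or tibble with `sample_id`, `group`,
#'   `proportion`).
#' @return Numeric matrix with sample rownames.
#' @export
community_matrix <- function(profiles) {
  wide <- profiles |>
    as_tibble() |>
    dplyr::select("sample_id", "group", "proportion") |>
    tidyr::pivot_wider(names_from = "group", values_from = "proportion",
                       values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  m
}

#' Pairwise dissimilarity matrix
#'
#' @param m Community matrix (samples x groups) of non-negative abundances.
#' @param method `"bray"` or `"kulczynski"`.
#' @return A `dist` object over the rows of `m`.
#' @export
dissimilarity_matrix <- function(m, method = c("bray", "kulczynski")) {
  method <- match.arg(method)
  f <- if (method == "bray") bray_curtis else kulczynski
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- f(m[i, ], m[j, ])
    }
  }
  stats::as.dist(d)
}

#' Pool samples before dissimilarity (grouped comparisons)
#'
#' Pools read counts by a grouping variable (e.g. location), then converts
#' to proportions: the convention used for location-level dissimilarities.
#'
#' @param profiles A `sample_profile` with a metadata column to pool on.
#' @param by Column name to pool by.
#' @param method `"sum"` pools read counts (default); `"mean"` averages
#'   per-sample proportions instead.
#' @return A `sample_profile` with one pooled sample per level of `by`.
#' @export
pool_profiles <- function(profiles, by, method = c("sum", "mean")) {
  method <- match.arg(method)
  df <- as_tibble(profiles)
  if (!by %in% names(df)) abort(paste0("no column ", by, " in profiles"))
  pooled <- if (method == "sum") {
    df |>
      dplyr::group_by(sample_id = .data[[by]], .data$group) |>
      dplyr::summarise(reads = sum(.data$reads), .groups = "drop_last") |>
      dplyr::mutate(proportion = .data$reads / sum(.data$reads)) |>
      dplyr::ungroup()
  } else {
    df |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::mutate(proportion = .data$reads / sum(.data$reads)) |>
      dplyr::group_by(sample_id = .data[[by]], .data$group) |>
      dplyr::summarise(reads = sum(.data$reads),
                       proportion = mean(.data$proportion), .groups = "drop_last") |>
      dplyr::mutate(proportion = .data$proportion / sum(.data$proportion)) |>
      dplyr::ungroup()
  }
  pooled$species <- group_species(pooled$group)
  out <- dplyr::select(pooled, "sample_id", "group", "species", "reads", "proportion")
  class(out) <- c("sample_profile", class(out))
  out
}

#' NMDS ordination of a dissimilarity matrix
#'
#' Non-metric multidimensional scaling minimising Kruskal stress-1, via
#' `vegan::metaMDS` with multiple random restarts. Coordinates are centred
#' at the origin.
#'
#' @param d A `dist` (or symmetric matrix) of sample dissimilarities.
#' @param k Ordination dimensions (default 2).
#' @param n_restarts Random restarts (default 50).
#' @param seed Optional RNG seed for reproducible restarts.
#' @param max_iter Iteration cap per run.
#' @return An `nmds_ord` object: `points` (centred coordinates), `stress`
#'   (Kruskal stress-1, in `[0, 1]`), `converged`, `n_restarts`.
#' @export
nmds <- function(d, k = 2, n_restarts = 50, seed = NULL, max_iter = 200) {
  if (is.matrix(d)) {
    if (!isTRUE(all.equal(d, t(d)))) abort("dissimilarity matrix must be symmetric")
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  if (n <= k) abort("need more samples than ordination dimensions")
  if (length(unique(round(as.vector(d), 12))) == 1) {
    warn("all dissimilarities equal: ordination carries no information")
  }
  if (!is.null(seed)) set.seed(seed)
  fit <- suppressWarnings(
    vegan::metaMDS(d, k = k, trymax = n_restarts, maxit = max_iter, trace = 0)
  )
  pts <- fit$points
  pts <- sweep(pts, 2, colMeans(pts))
  structure(
    list(points = pts, stress = fit$stress, converged = isTRUE(fit$converged),
         n_restarts = n_restarts, engine = fit),
    class = "nmds_ord"
  )
}

#' @export
print.nmds_ord <- function(x, ...) {
  cat("<nmds_ord> ", nrow(x$points), " samples in ", ncol(x$points),
      " dimensions; stress-1 = ", signif(x$stress, 4),
      if (x$converged) " (converged)\n" else " (no convergent solution)\n", sep = "")
  invisible(x)
}

#' @export
tidy.nmds_ord <- function(x, ...) {
  pts <- as.data.frame(x$points)
  names(pts) <- paste0("NMDS", seq_len(ncol(pts)))
  dplyr::bind_cols(tibble(sample_id = rownames(x$points) %||%
                            as.character(seq_len(nrow(pts)))), as_tibble(pts))
}

#' @export
autoplot.nmds_ord <- function(object, grouping = NULL, ...) {
  df <- tidy(object)
  if (!is.null(grouping)) df$grouping <- grouping
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2))
  p <- if (is.null(grouping)) {
    p + ggplot2::geom_point(size = 2)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$grouping), size = 2)
  }
  p +
    ggplot2::labs(caption = sprintf("stress = %.3f", object$stress)) +
    ggplot2::theme_minimal()
}

#' Recompute Kruskal stress-1 from a configuration
#'
#' Independent stress evaluation: monotone (isotonic) regression of the
#' configuration distances on the input dissimilarity order, then
#' `sqrt(sum((d - dhat)^2) / sum(d^2))`.
#'
#' @param d Input dissimilarities (`dist`).
#' @param points Configuration coordinates.
#' @return Stress-1 value.
#' @export
kruskal_stress <- function(d, points) {
  dd <- as.vector(stats::as.dist(d))
  cd <- as.vector(dist(points))
  o <- order(dd)
  ir <- stats::isoreg(dd[o], cd[o])
  sqrt(sum((cd[o] - ir$yf)^2) / sum(cd[o]^2))
}

#' ANOSIM grouping test
#'
#' Analysis of similarities: `R = (mean between-group rank - mean
#' within-group rank) / (M / 2)` with `M = n (n - 1) / 2`, significance by
#' label permutation (observed statistic included in numerator and
#' denominator). Wraps `vegan::anosim`.
#'
#' @param d Sample dissimilarities (`dist` or symmetric matrix).
#' @param grouping Factor of group labels (>= 2 groups).
#' @param n_permutations Number of permutations (default 999).
#' @param seed Optional RNG seed.
#' @return An `anosim_test` list: `statistic` (R), `p_value`,
#'   `n_permutations`, plus the vegan fit.
#' @export
anosim_test <- function(d, grouping, n_permutations = 999, seed = NULL) {
  if (is.matrix(d)) d <- stats::as.dist(d)
  grouping <- as.factor(grouping)
  if (length(unique(grouping)) < 2) abort("grouping must have at least 2 levels")
  if (n_permutations < 99) abort("use at least 99 permutations")
  if (!is.null(seed)) set.seed(seed)
  # small designs enumerate the full permutation set; quietly accept that
  fit <- suppressMessages(vegan::anosim(d, grouping, permutations = n_permutations))
  structure(
    list(statistic = unname(fit$statistic), p_value = fit$signif,
         n_permutations = n_permutations, engine = fit),
    class = "anosim_test"
  )
}

#' @export
print.anosim_test <- function(x, ...) {
  cat("<anosim_test> R = ", signif(x$statistic, 4), ", p = ",
      signif(x$p_value, 4), " (", x$n_permutations, " permutations)\n", sep = "")
  invisible(x)
}

#' @export
tidy.anosim_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value,
         n.permutations = x$n_permutations)
}

#' Minimum-spanning haplotype network
#'
#' Builds the complete graph over haplotype-group representative amplicons
#' weighted by Hamming distance and reduces it to a minimum spanning tree
#' (Kruskal, with deterministic lexicographic tie-breaking on edge labels).
#' Representatives of a species must share one length; when two species'
#' amplicons differ in length the species form separate Hamming components
#' joined by the single shortest end-gapped cross edge.
#'
#' @param representatives Named character vector: group label -> gap-free
#'   amplicon sequence.
#' @param annotations Optional tibble of node annotations (column `group`
#'   plus e.g. per-location read proportions).
#' @return A `hap_network`: `nodes` tibble and `edges` tibble
#'   (`from`, `to`, `weight` = nucleotide differences).
#' @export
build_haplotype_network <- function(representatives, annotations = NULL) {
  if (length(representatives) < 2) abort("need at least 2 groups")
  labels <- names(representatives)
  if (is.null(labels) || any(labels == "")) abort("representatives must be named")
  species <- sub("-.*$", "", labels)
  for (sp in unique(species)) {
    lens <- unique(nchar(representatives[species == sp]))
    if (length(lens) > 1) {
      abort(paste0("unequal amplicon lengths within species ", sp))
    }
  }
  n <- length(representatives)
  edges <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      a <- representatives[i]; b <- representatives[j]
      w <- if (nchar(a) == nchar(b)) hamming(a, b) else end_gapped_dist(a, b)
      cross <- species[i] != species[j] && nchar(a) != nchar(b)
      edges[[length(edges) + 1]] <- tibble(
        from = labels[i], to = labels[j], weight = w, cross_length = cross
      )
    }
  }
  edges <- dplyr::bind_rows(edges)
  # when species blocks have unequal lengths, only the single shortest cross
  # edge may join them; equal-length cross edges compete normally
  if (any(edges$cross_length)) {
    cl <- edges[edges$cross_length, , drop = FALSE]
    cl <- cl[order(cl$weight, cl$from, cl$to), , drop = FALSE]
    edges <- dplyr::bind_rows(edges[!edges$cross_length, , drop = FALSE], cl[1, ])
  }
  mst <- kruskal_mst(labels, edges)
  nodes <- tibble(group = labels, species = species,
                  representative = unname(representatives))
  if (!is.null(annotations)) nodes <- dplyr::left_join(nodes, annotations, by = "group")
  structure(
    list(nodes = nodes, edges = mst),
    class = "hap_network"
  )
}

# deterministic Kruskal: edges sorted by (weight, from, to), union-find
kruskal_mst <- function(labels, edges) {
  edges <- edges[order(edges$weight, edges$from, edges$to), , drop = FALSE]
  parent <- setNames(seq_along(labels), labels)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  keep <- logical(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    ri <- find(match(edges$from[e], labels))
    rj <- find(match(edges$to[e], labels))
    if (ri != rj) {
      parent[ri] <- rj
      keep[e] <- TRUE
    }
  }
  out <- edges[keep, c("from", "to", "weight"), drop = FALSE]
  out[order(out$weight, out$from, out$to), , drop = FALSE]
}

#' @export
print.hap_network <- function(x, ...) {
  cat("<hap_network> ", nrow(x$nodes), " haplotype groups, ",
      nrow(x$edges), " edges, total weight ", sum(x$edges$weight), "\n", sep = "")
  invisible(x)
}

#' @export
autoplot.hap_network <- function(object, size = NULL, ...) {
  # classical MDS of pairwise sequence distances as a simple deterministic layout
  reps <- setNames(object$nodes$representative, object$nodes$group)
  n <- length(reps)
  d <- matrix(0, n, n, dimnames = list(names(reps), names(reps)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- end_gapped_dist(reps[i], reps[j])
    }
  }
  xy <- cmdscale(stats::as.dist(d), k = 2)
  nodes <- dplyr::mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  seg <- object$edges |>
    dplyr::left_join(nodes[, c("group", "x", "y")], by = c("from" = "group")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(nodes[, c("group", "x", "y")], by = c("to" = "group"))
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x, yend = .data$y),
      colour = "grey50"
    ) +
    ggplot2::geom_label(
      data = seg,
      ggplot2::aes(x = (.data$x0 + .data$x) / 2, y = (.data$y0 + .data$y) / 2,
                   label = .data$weight),
      size = 3, label.size = 0
    )
  if (!is.null(size) && size %in% names(nodes)) {
    p <- p + ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$species,
                   size = .data[[size]])
    )
  } else {
    p <- p + ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$species), size = 4
    )
  }
  p +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$group),
      vjust = -1.2, size = 3
    ) +
    ggplot2::theme_void()
}
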