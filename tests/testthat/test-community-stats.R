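test_that("dissimilarities match hand evaluation and the standard identities", {
  x <- c(0.7, 0.3); y <- c(0.3, 0.7)
  expect_equal(bray_curtis(x, y), 0.4)
  expect_equal(kulczynski(x, y), 0.4)
  expect_equal(bray_curtis(x, x), 0)
  expect_equal(kulczynski(x, x), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 2)), 1)
  expect_equal(kulczynski(c(1, 0), c(0, 2)), 1)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(kulczynski(c(1, 1), c(0, 0)), "zero-sum")
})

test_that("dissimilarities are symmetric, bounded and rescale-invariant on random vectors", {
  set.seed(10)
  for (i in 1:50) {
    x <- runif(6); y <- runif(6)
    for (f in list(bray_curtis, kulczynski)) {
      d <- f(x, y)
      expect_gte(d, 0); expect_lte(d, 1)
      expect_equal(f(y, x), d)
      expect_equal(f(3.7 * x, 3.7 * y), d, tolerance = 1e-12)
    }
  }
})

test_that("pairwise dissimilarity matrices agree with vegan::vegdist", {
  set.seed(11)
  m <- matrix(runif(8 * 5), 8, 5)
  m <- m / rowSums(m)
  rownames(m) <- paste0("s", 1:8)
  expect_equal(as.vector(dissimilarity_matrix(m, "bray")),
               as.vector(vegan::vegdist(m, "bray")), tolerance = 1e-12)
  expect_equal(as.vector(dissimilarity_matrix(m, "kulczynski")),
               as.vector(vegan::vegdist(m, "kulczynski")), tolerance = 1e-12)
})

test_that("community matrices pivot profiles with unit row sums", {
  prof <- dplyr::bind_rows(
    profile_from_counts(c("ZM-A" = 70, "QM-A" = 30), sample_id = "s1"),
    profile_from_counts(c("ZM-A" = 20, "QM-A" = 60, "QM-G" = 20), sample_id = "s2")
  )
  m <- community_matrix(prof)
  expect_equal(dim(m), c(2, 3))
  expect_equal(unname(rowSums(m)), c(1, 1))
  expect_equal(m["s1", "QM-G"], 0)
})

test_that("NMDS embeds exactly embeddable configurations at (near) zero stress", {
  # three collinear samples in one dimension
  d <- dist(c(0, 1, 3))
  fit <- nmds(d, k = 1, n_restarts = 20, seed = 2)
  expect_lt(fit$stress, 1e-6)
  # 2-D Euclidean points recovered with rank-perfect distances
  set.seed(3)
  pts <- matrix(rnorm(16), 8, 2)
  d2 <- dist(pts)
  fit2 <- nmds(d2, k = 2, n_restarts = 20, seed = 4)
  expect_lt(fit2$stress, 1e-6)
  expect_equal(cor(as.vector(dist(fit2$points)), as.vector(d2), method = "spearman"), 1)
  # coordinates are centred
  expect_equal(unname(colMeans(fit2$points)), c(0, 0), tolerance = 1e-10)
})

test_that("duplicate samples land on coincident coordinates", {
  set.seed(6)
  m <- matrix(runif(5 * 4), 5, 4); m <- rbind(m, m[1, ])
  m <- m / rowSums(m)
  rownames(m) <- paste0("s", 1:6)
  fit <- nmds(dissimilarity_matrix(m, "bray"), k = 2, n_restarts = 20, seed = 8)
  expect_lt(as.matrix(dist(fit$points))[1, 6], 1e-8)
})

test_that("reported stress equals an independent stress-1 recomputation", {
  set.seed(12)
  m <- matrix(runif(10 * 6), 10, 6); m <- m / rowSums(m)
  d <- dissimilarity_matrix(m, "bray")
  fit <- nmds(d, k = 2, n_restarts = 20, seed = 13)
  expect_gt(fit$stress, 0) # a genuinely non-embeddable configuration
  expect_equal(kruskal_stress(d, fit$points), fit$stress, tolerance = 1e-8)
})

test_that("ANOSIM separates constructed groups and stays within its bounds", {
  # all within-group distances smaller than any between-group distance -> R = 1
  pts <- c(0, 0.1, 0.2, 0.3, 10, 10.1, 10.2, 10.3)
  d <- dist(pts)
  g <- rep(c("a", "b"), each = 4)
  res <- anosim_test(d, g, n_permutations = 199, seed = 5)
  expect_equal(res$statistic, 1)
  expect_lte(res$p_value, 0.05) # 2 of choose(8,4) labelings reach R = 1
  expect_gte(res$statistic, -1)

  # reproducible under a fixed seed
  res2 <- anosim_test(d, g, n_permutations = 199, seed = 5)
  expect_identical(res$p_value, res2$p_value)

  # duplicated points split across both labels -> no separation, R <= 0
  m <- matrix(runif(3 * 4), 3, 4)
  mm <- rbind(m, m)
  rownames(mm) <- paste0("s", 1:6)
  d2 <- dist(mm)
  res3 <- anosim_test(d2, rep(c("a", "b"), each = 3), n_permutations = 199, seed = 6)
  expect_lte(res3$statistic, 0)

  expect_error(anosim_test(d, rep("a", 6)), "2 levels")
})

test_that("pooling profiles by location sums reads before proportions", {
  prof <- dplyr::bind_rows(
    profile_from_counts(c("ZM-A" = 90, "QM-A" = 10), sample_id = "s1"),
    profile_from_counts(c("ZM-A" = 10, "QM-A" = 90), sample_id = "s2")
  )
  prof$site <- ifelse(prof$sample_id == "s1", "L1", "L2")
  pooled <- pool_profiles(prof, by = "site")
  expect_equal(sort(unique(pooled$sample_id)), c("L1", "L2"))
  expect_equal(pooled$proportion[pooled$sample_id == "L1" & pooled$group == "ZM-A"], 0.9)

  # pooling two samples of one site averages their reads into one profile
  prof2 <- dplyr::bind_rows(
    profile_from_counts(c("ZM-A" = 90, "QM-A" = 10), sample_id = "s1"),
    profile_from_counts(c("ZM-A" = 30, "QM-A" = 70), sample_id = "s2")
  )
  prof2$site <- "L1"
  pooled2 <- pool_profiles(prof2, by = "site")
  expect_equal(pooled2$proportion[pooled2$group == "ZM-A"], 0.6)
})

test_that("the haplotype network is a deterministic minimum spanning tree", {
  reps <- c("h1" = "AAAA", "h2" = "AAAT", "h3" = "AATT")
  net <- build_haplotype_network(reps)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(paste(net$edges$from, net$edges$to), c("h1 h2", "h2 h3"))
  expect_equal(sum(net$edges$weight), 2)

  # two sequences three substitutions apart -> single edge of weight 3
  net2 <- build_haplotype_network(c("a" = "AAAA", "b" = "ATTT"))
  expect_equal(net2$edges$weight, 3)
})

test_that("MST weight equals the exhaustive spanning-tree minimum (n = 7)", {
  set.seed(17)
  n <- 7
  reps <- setNames(
    replicate(n, paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE), collapse = "")),
    paste0("ZM-", LETTERS[1:n])
  )
  net <- build_haplotype_network(reps)
  expect_equal(nrow(net$edges), n - 1)

  dmat <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dmat[i, j] <- dmat[j, i] <-
      sum(strsplit(reps[i], "")[[1]] != strsplit(reps[j], "")[[1]])
  }
  # enumerate all labelled spanning trees of K_n via Pruefer sequences
  prufer_weight <- function(code) {
    degree <- rep(1L, n)
    for (v in code) degree[v] <- degree[v] + 1L
    w <- 0
    avail <- degree
    for (v in code) {
      leaf <- which(avail == 1L)[1]
      w <- w + dmat[leaf, v]
      avail[leaf] <- 0L
      avail[v] <- avail[v] - 1L
    }
    u <- which(avail == 1L)
    w + dmat[u[1], u[2]]
  }
  codes <- as.matrix(expand.grid(rep(list(1:n), n - 2)))
  best <- min(apply(codes, 1, prufer_weight))
  expect_equal(sum(net$edges$weight), best)
})

test_that("species blocks of unequal amplicon length join by one cross edge", {
  reps <- c("ZM-A" = "AAAAAA", "ZM-B" = "AAATAA", "QM-A" = "CCCC", "QM-B" = "CCGC")
  net <- build_haplotype_network(reps)
  cross <- net$edges$from %in% c("ZM-A", "ZM-B") != net$edges$to %in% c("ZM-A", "ZM-B")
  expect_equal(sum(cross), 1)
  expect_error(
    build_haplotype_network(c("ZM-A" = "AAAA", "ZM-B" = "AAA")),
    "unequal amplicon lengths"
  )
})
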