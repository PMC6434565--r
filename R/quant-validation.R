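# Mock-community and aquarium validation statistics: expected group
# proportions under amplicon collapsing, observed-versus-expected log-log
# regression with a slope-vs-1 test, and likelihood-ratio G-tests against
# known compositions.

#' Expected group proportions of a mock community
#'
#' Collapses per-haplotype template copy numbers into resolvability groups
#' and converts to expected read percentages: group copies summed over
#' members, percentage = 100 * group copies / total copies.
#'
#' @param design Copy numbers per haplotype: a named numeric vector, or a
#'   tibble with columns `haplotype`, `copies`.
#' @param partition A [resolvability_partition()] or a named list of member
#'   id vectors (group label -> haplotype ids).
#' @return Tibble `group`, `copies`, `expected_pct`, summing to 100.
#' @export
expected_group_proportions <- function(design, partition) {
  if (is.data.frame(design)) {
    copies <- setNames(design$copies, design$haplotype)
  } else {
    copies <- design
  }
  groups <- if (is.data.frame(partition)) {
    setNames(partition$members, partition$group_label)
  } else {
    partition
  }
  member2group <- stats::setNames(
    rep(names(groups), lengths(groups)),
    unlist(groups, use.names = FALSE)
  )
  missing <- setdiff(names(copies), names(member2group))
  if (length(missing) > 0) {
    abort(paste0("haplotype(s) absent from partition: ", paste(missing, collapse = ", ")))
  }
  df <- tibble(
    group = unname(member2group[names(copies)]),
    copies = as.numeric(copies)
  ) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(copies = sum(.data$copies), .groups = "drop")
  df$expected_pct <- 100 * df$copies / sum(df$copies)
  df
}

#' Observed-versus-expected log-log regression
#'
#' Ordinary least squares of `log10(observed)` on `log10(expected)` percent
#' read abundances, with goodness-of-fit and a two-sided t-test of the slope
#' against 1 (`t = (slope - 1) / SE(slope)`, `n - 2` df). A perfectly
#' quantitative assay gives slope 1.
#'
#' @param observed,expected Positive percentage vectors of equal length
#'   (>= 3 points). Callers must drop absent (zero) groups beforehand.
#' @return A `loglog_fit` object (also carrying the underlying `lm`).
#' @export
loglog_fit <- function(observed, expected) {
  if (length(observed) != length(expected)) abort("observed/expected lengths differ")
  if (length(observed) < 3) abort("need at least 3 points for a fit")
  if (any(observed <= 0) || any(expected <= 0)) {
    abort("log-log fit needs positive percentages; drop absent groups first")
  }
  df <- data.frame(x = log10(expected), y = log10(observed))
  fit <- lm(y ~ x, data = df)
  # a perfect fit is a legitimate input here (observed == expected)
  s <- suppressWarnings(summary(fit))
  slope <- unname(coef(fit)[2])
  se <- s$coefficients[2, 2]
  n <- length(observed)
  t1 <- (slope - 1) / se
  # a numerically perfect fit degenerates the slope test: both the slope
  # deviation and its SE are floating-point noise
  p_slope1 <- if (is.nan(t1) || (se < 1e-10 && abs(slope - 1) < 1e-10)) {
    1
  } else {
    2 * pt(-abs(t1), df = n - 2)
  }
  structure(
    list(
      slope = slope,
      intercept = unname(coef(fit)[1]),
      r_squared = s$r.squared,
      p_fit = unname(s$coefficients[2, 4]),
      p_slope1 = p_slope1,
      n_points = n,
      fit = fit,
      data = df
    ),
    class = "loglog_fit"
  )
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat("<loglog_fit> slope = ", signif(x$slope, 4),
      ", R^2 = ", signif(x$r_squared, 4),
      ", p(slope != 0) = ", signif(x$p_fit, 3),
      ", p(slope != 1) = ", signif(x$p_slope1, 3),
      ", n = ", x$n_points, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.loglog_fit <- function(x, ...) {
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = summary(x$fit)$coefficients[, 2],
    p.value = summary(x$fit)$coefficients[, 4]
  )
}

#' @export
glance.loglog_fit <- function(x, ...) {
  tibble(
    slope = x$slope, intercept = x$intercept, r.squared = x$r_squared,
    p.fit = x$p_fit, p.slope1 = x$p_slope1, n = x$n_points
  )
}

#' @export
autoplot.loglog_fit <- function(object, ...) {
  df <- object$data
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "log10 expected read %", y = "log10 observed read %",
      title = sprintf("slope = %.2f, R² = %.2f", object$slope, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Likelihood-ratio G-test
#'
#' Goodness of fit against a known composition (`p`), or a 2-by-k test of
#' independence between two observed count vectors (`y`). The statistic is
#' `G = 2 * sum(O * ln(O / E))`; expected counts derive from the reference
#' proportions scaled to the observed total (goodness of fit) or from the
#' table margins (independence, df = k - 1 for 2 rows).
#'
#' @param x Non-negative observed counts.
#' @param p Reference composition: proportions (summing to 1) or reference
#'   counts, normalised internally. Categories with zero expectation but
#'   non-zero observation are invalid.
#' @param y Second observed count vector (independence mode; overrides `p`).
#' @param williams Apply the Williams continuity correction (off by
#'   default).
#' @return An object of class `htest` with `statistic`, `parameter` (df) and
#'   `p.value`.
#' @export
g_test <- function(x, p = NULL, y = NULL, williams = FALSE) {
  x <- as.numeric(x)
  if (any(x < 0)) abort("counts must be non-negative")
  if (sum(x) <= 0) abort("observed total must be positive")
  if (!is.null(y)) {
    y <- as.numeric(y)
    if (length(y) != length(x)) abort("count vectors differ in length")
    tab <- rbind(x, y)
    keep <- colSums(tab) > 0
    tab <- tab[, keep, drop = FALSE]
    k <- ncol(tab)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    O <- tab
    G <- 2 * sum(O[O > 0] * log(O[O > 0] / E[O > 0]))
    df <- k - 1
    method <- "G-test of independence (2 x k)"
    n <- sum(tab)
    q <- if (williams) {
      1 + (n * sum(1 / rowSums(tab)) - 1) * (n * sum(1 / colSums(tab)) - 1) /
        (6 * n * (nrow(tab) - 1) * (k - 1))
    } else 1
  } else {
    if (is.null(p)) abort("supply a reference composition p or a second vector y")
    p <- as.numeric(p)
    if (length(p) != length(x)) abort("reference length differs from observed")
    if (any(p < 0)) abort("reference proportions must be non-negative")
    p <- p / sum(p)
    bad <- p == 0 & x > 0
    if (any(bad)) {
      abort(paste0("zero expected proportion with non-zero observed count at category ",
                   which(bad)[1]))
    }
    keep <- p > 0
    x <- x[keep]; p <- p[keep]
    E <- sum(x) * p
    G <- 2 * sum(x[x > 0] * log(x[x > 0] / E[x > 0]))
    df <- length(x) - 1
    method <- "G-test goodness of fit"
    n <- sum(x)
    q <- if (williams) 1 + (length(x)^2 - 1) / (6 * n * df) else 1
  }
  G <- G / q
  structure(
    list(
      statistic = c(G = G),
      parameter = c(df = df),
      p.value = pchisq(G, df = df, lower.tail = FALSE),
      method = if (williams) paste(method, "(Williams-corrected)") else method,
      data.name = deparse(substitute(x))
    ),
    class = "htest"
  )
}

significance_stars <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Run a planned set of composition comparisons
#'
#' Applies [g_test()] to each planned pair: a sample's read counts against a
#' known reference composition (individual counts, biomass shares, template
#' copies), or one sample's counts against another's (independence).
#'
#' @param profiles A `sample_profile` (or any tibble with `sample_id`,
#'   a category column and `reads`).
#' @param references Tibble with columns `reference_id`, the category
#'   column, and `value` (counts or proportions; normalised internally).
#' @param plan Tibble describing the comparisons, columns `sample_id` and
#'   either `reference_id` (reference mode) or `sample_b` (profile-vs-profile
#'   mode); both columns may be present with `NA` marking the unused one.
#' @param category Name of the category column (default `"species"`;
#'   `"group"` compares at haplotype-group level).
#' @return Tidy tibble: one row per comparison with `g`, `df`, `p_value` and
#'   significance `stars` (0.05 / 0.01 / 0.001).
#' @export
composition_comparison_suite <- function(profiles, references = NULL, plan,
                                         category = "species") {
  prof <- as_tibble(profiles)
  if (!category %in% names(prof)) abort(paste0("profiles lack column ", category))
  get_counts <- function(sid) {
    d <- prof[prof$sample_id == sid, , drop = FALSE]
    if (nrow(d) == 0) abort(paste0("sample not found: ", sid))
    d |>
      dplyr::group_by(cat = .data[[category]]) |>
      dplyr::summarise(reads = sum(.data$reads), .groups = "drop")
  }
  purrr::map_dfr(seq_len(nrow(plan)), function(i) {
    sid <- plan$sample_id[i]
    a <- get_counts(sid)
    if ("sample_b" %in% names(plan) && !is.na(plan$sample_b[i] %||% NA)) {
      b <- get_counts(plan$sample_b[i])
      cats <- union(a$cat, b$cat)
      xa <- setNames(rep(0, length(cats)), cats); xa[a$cat] <- a$reads
      xb <- setNames(rep(0, length(cats)), cats); xb[b$cat] <- b$reads
      ht <- g_test(xa, y = xb)
      lab <- paste0(sid, " vs ", plan$sample_b[i])
    } else {
      rid <- plan$reference_id[i]
      ref <- references[references$reference_id == rid, , drop = FALSE]
      if (nrow(ref) == 0) abort(paste0("reference not found: ", rid))
      unmatched <- setdiff(a$cat, ref[[category]])
      if (length(unmatched) > 0) {
        abort(paste0("categories missing from reference '", rid, "': ",
                     paste(unmatched, collapse = ", ")))
      }
      m <- match(ref[[category]], a$cat)
      x <- rep(0, nrow(ref))
      x[!is.na(m)] <- a$reads[m[!is.na(m)]]
      ht <- g_test(x, p = ref$value)
      lab <- paste0(sid, " vs ", rid)
    }
    tibble(
      comparison = lab,
      g = unname(ht$statistic),
      df = unname(ht$parameter),
      p_value = ht$p.value,
      stars = significance_stars(ht$p.value)
    )
  })
}
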