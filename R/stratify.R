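# Cohort stratification and comparison: prevalence/dominance summaries,
# enrichment tests, distribution comparisons, kernel densities and the
# HRd-status split of TNBC samples.

#' Prevalence and dominance summary per signature group
#'
#' Per group: prevalence as a percentage of the cohort, the fraction of
#' samples in which the group is the first / second dominant signature, and
#' the mean and range of relative contributions among samples in which the
#' group is present. Percentages are reported to two decimal places.
#'
#' @param presence Presence tibble from [call_presence()].
#' @param contributions Contribution tibble from [relative_contributions()].
#' @param dominants Tibble from [dominant_signatures()].
#' @return Tibble with one row per group: `group`, `n`, `n_present`,
#'   `prevalence_pct`, `first_dominant_n`, `first_dominant_pct`,
#'   `second_dominant_n`, `second_dominant_pct`, `mean_contribution`,
#'   `min_contribution`, `max_contribution`.
#' @export
summarize_prevalence <- function(presence, contributions, dominants) {
  groups <- setdiff(names(presence), "sample_id")
  stopifnot(identical(presence$sample_id, contributions$sample_id),
            identical(presence$sample_id, dominants$sample_id))
  N <- nrow(presence)
  purrr::map_dfr(groups, function(g) {
    present <- presence[[g]] == 1L
    contrib <- contributions[[g]][present]
    tibble::tibble(
      group = g,
      n = N,
      n_present = sum(present),
      prevalence_pct = round(100 * sum(present) / N, 2),
      first_dominant_n = sum(dominants$first_dominant == g, na.rm = TRUE),
      first_dominant_pct = round(100 * sum(dominants$first_dominant == g,
                                           na.rm = TRUE) / N, 2),
      second_dominant_n = sum(dominants$second_dominant == g, na.rm = TRUE),
      second_dominant_pct = round(100 * sum(dominants$second_dominant == g,
                                            na.rm = TRUE) / N, 2),
      mean_contribution = if (any(present)) mean(contrib) else NA_real_,
      min_contribution = if (any(present)) min(contrib) else NA_real_,
      max_contribution = if (any(present)) max(contrib) else NA_real_
    )
  })
}

#' Enrichment test on a contingency table
#'
#' 2x2 tables use the exact two-sided Fisher test (sum of table
#' probabilities at or below the observed one); larger tables use a seeded
#' Monte-Carlo exact test with fixed margins.
#'
#' @param tab Non-negative integer matrix, at least 2x2. Zero-margin rows or
#'   columns are dropped with a warning.
#' @param B Monte-Carlo draws for tables larger than 2x2.
#' @param seed Integer seed for the Monte-Carlo test.
#' @return The two-sided p-value.
#' @export
enrichment_test <- function(tab, B = 1e5, seed = 1L) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("contingency table must hold non-negative integers")
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping zero-margin rows/columns from the contingency table")
    tab <- tab[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("contingency table must be at least 2x2 after dropping zero margins")
  if (nrow(tab) == 2L && ncol(tab) == 2L) {
    stats::fisher.test(tab)$p.value
  } else {
    withr::with_seed(seed,
      stats::fisher.test(tab, simulate.p.value = TRUE, B = B)$p.value)
  }
}

#' Compare two contribution distributions
#'
#' Two-sided Mann-Whitney U test on all values, and two-sided
#' Kolmogorov-Smirnov test on the empirical distribution functions
#' restricted to samples with nonzero contribution (the convention used for
#' signature contribution curves: only samples in which the signature is
#' detected enter the distribution shape).
#'
#' @param values_a,values_b Numeric vectors (both non-empty).
#' @return One-row tibble with `mwu_u`, `mwu_p`, `ks_d`, `ks_p`,
#'   `n_a_nonzero`, `n_b_nonzero` and an `insufficient_data` flag set when a
#'   nonzero-restricted sample has fewer than two values.
#' @export
compare_distributions <- function(values_a, values_b) {
  stopifnot(length(values_a) > 0, length(values_b) > 0)
  mwu <- suppressWarnings(stats::wilcox.test(values_a, values_b))
  a <- values_a[values_a > 0]
  b <- values_b[values_b > 0]
  insufficient <- length(a) < 2L || length(b) < 2L
  if (length(a) >= 1L && length(b) >= 1L) {
    ks <- suppressWarnings(stats::ks.test(a, b))
    ks_d <- unname(ks$statistic); ks_p <- ks$p.value
  } else {
    ks_d <- NA_real_; ks_p <- NA_real_
  }
  tibble::tibble(
    mwu_u = unname(mwu$statistic), mwu_p = mwu$p.value,
    ks_d = ks_d, ks_p = ks_p,
    n_a_nonzero = length(a), n_b_nonzero = length(b),
    insufficient_data = insufficient
  )
}

#' Kruskal-Wallis rank sum test across groups
#'
#' @param values List of numeric vectors (one per group, each non-empty), or
#'   a numeric vector accompanied by `groups`.
#' @param groups Optional grouping factor when `values` is a vector.
#' @return One-row tibble with `H`, `df` and `p` (tie-corrected H,
#'   chi-square p). When all values are identical the degenerate case is
#'   flagged with `H = 0` and `p = 1`.
#' @export
kruskal_wallis <- function(values, groups = NULL) {
  if (is.list(values)) {
    stopifnot(length(values) >= 2L, all(lengths(values) > 0))
    x <- unlist(values, use.names = FALSE)
    g <- factor(rep(seq_along(values), lengths(values)))
  } else {
    stopifnot(!is.null(groups))
    x <- values
    g <- factor(groups)
  }
  if (length(unique(x)) == 1L) {
    return(tibble::tibble(H = 0, df = nlevels(g) - 1L, p = 1,
                          degenerate = TRUE))
  }
  kt <- stats::kruskal.test(x, g)
  tibble::tibble(H = unname(kt$statistic), df = unname(kt$parameter),
                 p = kt$p.value, degenerate = FALSE)
}

#' Gaussian kernel density with Silverman's normal-reference bandwidth
#'
#' Bandwidth `h = 1.06 * sd(x) * n^(-1/5)`; the returned curve integrates to
#' 1 (trapezoidal rule, within 1e-3 on its grid).
#'
#' @param values Numeric vector with at least two distinct values.
#' @param bw Bandwidth; `"silverman"` (default) or a positive number.
#' @param n_grid Grid size.
#' @return Tibble with `x` and `density`.
#' @export
kernel_density <- function(values, bw = "silverman", n_grid = 512L) {
  stopifnot(length(values) >= 2L)
  if (length(unique(values)) == 1L)
    stop("degenerate bandwidth: all values identical")
  h <- if (identical(bw, "silverman")) {
    1.06 * stats::sd(values) * length(values)^(-1 / 5)
  } else {
    stopifnot(is.numeric(bw), bw > 0)
    bw
  }
  d <- stats::density(values, bw = h, n = n_grid)
  tibble::tibble(x = d$x, density = d$y)
}

#' Split samples by homologous-recombination-deficiency status
#'
#' Samples with a bi-allelic inactivation of BRCA1/BRCA2/PALB2 are `"HRd"`;
#' otherwise samples with an HRd score below 0.1 are `"non-HRd"`; everything
#' else (score at or above 0.1, or missing score without the flag) is
#' `"unassigned"`. Every sample lands in exactly one class.
#'
#' @param annotations Tibble with `sample_id`, `biallelic_hrd_gene`
#'   (logical) and `hrd_score` (numeric in `[0, 1]` or NA).
#' @param score_cutoff HRd score below which unflagged samples are non-HRd.
#' @return `annotations` with an `hrd_status` column appended.
#' @export
split_hrd_status <- function(annotations, score_cutoff = 0.1) {
  score <- annotations$hrd_score
  if (any(!is.na(score) & (score < 0 | score > 1)))
    stop("hrd_score must lie in [0, 1]")
  dplyr::mutate(annotations, hrd_status = dplyr::case_when(
    .data$biallelic_hrd_gene                    ~ "HRd",
    !is.na(.data$hrd_score) & .data$hrd_score < score_cutoff ~ "non-HRd",
    TRUE                                        ~ "unassigned"
  ))
}

#' Stratified cohort comparison
#'
#' Per stratum of the chosen stratifier: a prevalence/dominance summary;
#' an exact enrichment test of the first-dominant-signature x stratum
#' contingency table; and pairwise distribution comparisons per group
#' between strata (on samples where the group is present).
#'
#' @param profiles Tibble from [sample_profiles()] (carries the `presence`
#'   attribute).
#' @param annotations Annotation tibble with `sample_id` and the stratifier
#'   column.
#' @param stratifier Name of the annotation column to stratify by (e.g.
#'   `"grade"` or `"hrd_status"`).
#' @param seed Seed for Monte-Carlo enrichment tests.
#' @return A list of class `sig_strata`: `summaries` (per-stratum output of
#'   [summarize_prevalence()], row count = strata x groups), `enrichment`
#'   (tibble of tested tables and p-values), `distribution_tests` (pairwise
#'   [compare_distributions()] per group and stratum pair).
#' @export
stratified_compare <- function(profiles, annotations, stratifier,
                               seed = 1L) {
  presence <- attr(profiles, "presence")
  if (is.null(presence)) stop("profiles must carry a presence attribute")
  stopifnot(stratifier %in% names(annotations))
  ann <- annotations[match(profiles$sample_id, annotations$sample_id), ]
  stratum <- as.character(ann[[stratifier]])
  groups <- setdiff(names(presence), "sample_id")
  strata <- sort(unique(stratum[!is.na(stratum)]))
  sizes <- table(stratum)
  empty <- setdiff(strata, names(sizes)[sizes > 0])
  if (length(empty) > 0) {
    warning("omitting empty strata: ", paste(empty, collapse = ", "))
    strata <- setdiff(strata, empty)
  }

  contributions <- profiles[, c("sample_id", groups)]
  dominants <- profiles[, c("sample_id", "first_dominant", "second_dominant")]

  summaries <- purrr::map_dfr(strata, function(s) {
    idx <- !is.na(stratum) & stratum == s
    dplyr::mutate(
      summarize_prevalence(presence[idx, ], contributions[idx, ],
                           dominants[idx, ]),
      stratum = s, .before = 1
    )
  })

  tab <- table(profiles$first_dominant, stratum)
  enr <- tibble::tibble(
    comparison = "first_dominant",
    p = enrichment_test(tab, seed = seed)
  )

  dist_tests <- purrr::map_dfr(groups, function(g) {
    purrr::map_dfr(utils::combn(strata, 2, simplify = FALSE), function(pr) {
      ia <- !is.na(stratum) & stratum == pr[1]
      ib <- !is.na(stratum) & stratum == pr[2]
      va <- contributions[[g]][ia]
      vb <- contributions[[g]][ib]
      if (length(va) == 0 || length(vb) == 0) return(NULL)
      dplyr::mutate(compare_distributions(va, vb),
                    group = g, stratum_a = pr[1], stratum_b = pr[2],
                    .before = 1)
    })
  })

  structure(list(summaries = summaries, enrichment = enr,
                 distribution_tests = dist_tests,
                 stratifier = stratifier),
            class = "sig_strata")
}

#' @export
print.sig_strata <- function(x, ...) {
  cat("<sig_strata> stratified by", x$stratifier, "\n")
  print(x$summaries)
  invisible(x)
}
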