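# Prevalence summaries, enrichment tests, distribution comparisons, kernel
# densities and the HRd-status split.

test_that("prevalence percentages reproduce exact division to 2 decimals", {
  fx <- make_presence_fixture(569, c(HRd = 109L, NHEJd = 222L))
  s <- summarize_prevalence(fx$presence, fx$contributions, fx$dominants)
  expect_equal(s$prevalence_pct[s$group == "HRd"], 19.16)
  expect_equal(s$prevalence_pct[s$group == "NHEJd"], 39.02)
  fx0 <- make_presence_fixture(100, c(A = 0L))
  s0 <- summarize_prevalence(fx0$presence, fx0$contributions, fx0$dominants)
  expect_equal(s0$prevalence_pct, 0)
  expect_true(is.na(s0$mean_contribution))
})

test_that("2x2 enrichment equals exhaustive enumeration for all tables with N <= 20", {
  for (N in 2:20) {
    for (r1 in 1:(N - 1)) {
      for (c1 in 1:min(r1, N - 1)) {
        for (k in max(0, r1 + c1 - N):min(r1, c1)) {
          tab <- matrix(c(k, c1 - k, r1 - k, N - r1 - c1 + k), 2)
          if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
          expect_equal(enrichment_test(tab), oracle_fisher_2x2(tab),
                       tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("enrichment test handles documented examples and Monte-Carlo determinism", {
  expect_equal(enrichment_test(matrix(c(1, 9, 9, 1), 2)), 1.093e-3,
               tolerance = 1e-3)
  expect_equal(enrichment_test(matrix(c(5, 5, 5, 5), 2)), 1)
  tab <- matrix(c(8, 2, 3, 5, 1, 7, 2, 2, 6), 3)
  p1 <- enrichment_test(tab, seed = 5)
  p2 <- enrichment_test(tab, seed = 5)
  expect_identical(p1, p2)
  expect_warning(enrichment_test(matrix(c(3, 2, 0, 0, 4, 1), 2)),
                 "zero-margin")
})

test_that("distribution comparison behaves on identical, disjoint and shifted samples", {
  x <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  same <- compare_distributions(x, x)
  expect_equal(same$ks_d, 0)
  expect_equal(same$ks_p, 1)
  a <- seq(0.01, 0.1, length.out = 10)
  b <- seq(0.5, 0.9, length.out = 10)
  disj <- compare_distributions(a, b)
  expect_equal(disj$ks_d, 1)
  shifted <- withr::with_seed(1001, {
    compare_distributions(stats::rnorm(100, 1, 1) + 10,
                          stats::rnorm(100, 2, 1) + 10)
  })
  expect_lt(shifted$mwu_p, 0.01)
  expect_lt(shifted$ks_p, 0.01)
  # zeros are excluded from the KS comparison
  mixed <- compare_distributions(c(rep(0, 50), x), x)
  expect_equal(mixed$ks_d, 0)
  expect_equal(mixed$n_a_nonzero, 5)
})

test_that("Kruskal-Wallis matches the hand-ranked statistic and the MWU identity", {
  kw <- kruskal_wallis(list(1:3, 4:6, 7:9))
  expect_equal(kw$H, 7.2)
  expect_equal(kw$df, 2)
  a <- withr::with_seed(1002, stats::rnorm(30))
  b <- withr::with_seed(1003, stats::rnorm(25, 0.5))
  kw2 <- kruskal_wallis(list(a, b))
  mwu <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                             correct = FALSE))
  expect_equal(kw2$p, mwu$p.value, tolerance = 1e-6)
  degen <- kruskal_wallis(list(rep(1, 5), rep(1, 5)))
  expect_true(degen$degenerate)
  expect_equal(degen$H, 0)
  expect_equal(degen$p, 1)
})

test_that("kernel density integrates to 1 and uses the Silverman bandwidth", {
  x <- withr::with_seed(1004, stats::rnorm(1000))
  d <- kernel_density(x)
  integral <- sum(diff(d$x) * (head(d$density, -1) + tail(d$density, -1)) / 2)
  expect_equal(integral, 1, tolerance = 1e-3)
  h_expected <- 1.06 * stats::sd(x) * 1000^(-1 / 5)
  # recover the bandwidth the curve was built with via stats::density
  dd <- stats::density(x, bw = h_expected, n = 512)
  expect_equal(d$density, dd$y)
  expect_identical(kernel_density(x), kernel_density(x))
  expect_error(kernel_density(rep(0.5, 10)), "degenerate")
})

test_that("HRd-status split partitions every sample into exactly one class", {
  ann <- tibble::tibble(
    sample_id = sprintf("T%02d", 1:6),
    grade = "G3", subtype = "TNBC",
    hrd_score = c(0.9, 0.05, 0.5, NA, 0.05, NA),
    biallelic_hrd_gene = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE)
  )
  out <- split_hrd_status(ann)
  expect_identical(out$hrd_status,
                   c("HRd", "non-HRd", "unassigned", "HRd", "HRd", "unassigned"))
  expect_true(all(table(out$sample_id) == 1))
  rnd <- withr::with_seed(1005, tibble::tibble(
    sample_id = sprintf("R%03d", 1:100),
    hrd_score = ifelse(stats::runif(100) < 0.2, NA, stats::runif(100)),
    biallelic_hrd_gene = stats::runif(100) < 0.3
  ))
  out2 <- split_hrd_status(rnd)
  expect_true(all(out2$hrd_status %in% c("HRd", "non-HRd", "unassigned")))
})

test_that("stratified comparison detects a planted stratum-specific signature", {
  sim <- make_test_cohort(n_samples = 80, burden_mean = 800, seed = 171,
                          hrd_signature = "S1")
  fit <- refit_exposures(sim$catalog, sim$signatures)
  prof <- sample_profiles(fit, sim$catalog)
  ann <- split_hrd_status(sim$truth$annotations)
  res <- stratified_compare(prof, ann, "hrd_status")
  # shape contract: strata x groups rows
  n_strata <- length(unique(res$summaries$stratum))
  n_groups <- length(unique(res$summaries$group))
  expect_equal(nrow(res$summaries), n_strata * n_groups)
  # S1 is enriched where the HRd flag is set (by construction)
  expect_lt(res$enrichment$p, 0.05)
  s1 <- res$summaries[res$summaries$group == "S1", ]
  expect_gt(s1$prevalence_pct[s1$stratum == "HRd"],
            s1$prevalence_pct[s1$stratum == "non-HRd"])
})

test_that("identical strata give enrichment p = 1", {
  prof_tbl <- tibble::tibble(
    sample_id = sprintf("P%02d", 1:40),
    first_dominant = rep(c("A", "B"), 20),
    second_dominant = NA_character_,
    A = rep(c(0.8, 0.2), 20), B = rep(c(0.2, 0.8), 20)
  )
  pres <- tibble::tibble(sample_id = prof_tbl$sample_id,
                         A = rep(c(1L, 0L), 20), B = rep(c(0L, 1L), 20))
  attr(prof_tbl, "presence") <- pres
  ann <- tibble::tibble(sample_id = prof_tbl$sample_id,
                        stratum = rep(c("X", "Y"), each = 2, length.out = 40))
  res <- stratified_compare(prof_tbl, ann, "stratum")
  expect_equal(res$enrichment$p, 1)
})
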