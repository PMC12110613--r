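# KL-NMF factorization, bootstrap extraction and rank selection.

test_that("rank-1 factorization recovers a common profile exactly", {
  base <- withr::with_seed(501, stats::rpois(96, 5))  # integer base profile
  prof <- base / sum(base)
  # rows exactly proportional to the base profile
  counts <- outer(1:15, base)
  tbl <- dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("S%02d", 1:15)),
    tibble::as_tibble(as.data.frame(counts), .name_repair = "minimal") |>
      stats::setNames(channel_labels("SBS96")) |>
      dplyr::mutate(dplyr::across(dplyr::everything(), as.integer))
  )
  catalog <- sigscape:::new_mut_catalog(tbl, "SBS96")
  fit <- nmf_factorize(catalog, 1, seed = 1)
  got <- sig_matrix(fit$signatures)[, 1]
  expect_gt(cosine_similarity(got, prof), 1 - 1e-8)
  V <- t(catalog_matrix(catalog))
  recon <- sig_matrix(fit$signatures) %*%
    t(exposure_abs <- as.matrix(fit$exposures$absolute[, -1]))
  expect_lt(sum(abs(V - recon)) / sum(V), 1e-6)
})

test_that("the KL objective is monotone non-increasing", {
  sim <- make_test_cohort(n_samples = 20, burden_mean = 300)
  for (seed in 1:3) {
    fit <- nmf_factorize(sim$catalog, 3, seed = seed, max_iter = 500,
                         tol = 1e-10)
    expect_true(all(diff(fit$objective_trace) <= 1e-8))
  }
})

test_that("factorization is deterministic for a fixed seed", {
  sim <- make_test_cohort(n_samples = 15, burden_mean = 300)
  f1 <- nmf_factorize(sim$catalog, 2, seed = 7, max_iter = 300, tol = 1e-8)
  f2 <- nmf_factorize(sim$catalog, 2, seed = 7, max_iter = 300, tol = 1e-8)
  expect_identical(sig_matrix(f1$signatures), sig_matrix(f2$signatures))
  expect_identical(f1$objective, f2$objective)
})

test_that("an all-zero catalog is rejected", {
  tbl <- dplyr::bind_cols(
    tibble::tibble(sample_id = c("A", "B")),
    tibble::as_tibble(as.data.frame(matrix(0L, 2, 96)),
                      .name_repair = "minimal") |>
      stats::setNames(channel_labels("SBS96"))
  )
  catalog <- sigscape:::new_mut_catalog(tbl, "SBS96")
  expect_error(nmf_factorize(catalog, 1), "all-zero")
})

test_that("planted signatures are recovered at the true rank", {
  sim <- make_test_cohort(n_samples = 60, burden_mean = 1000, seed = 111)
  best <- NULL
  for (r in 1:5) {
    fit <- nmf_factorize(sim$catalog, 3, seed = r, max_iter = 2000, tol = 1e-7)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  m <- match_to_reference(best$signatures, sim$signatures, min_cosine = 0.8)
  expect_true(all(m$matched))
  expect_true(all(m$cosine >= 0.95))
})

test_that("permuting sample order permutes exposure rows identically", {
  sim <- make_test_cohort(n_samples = 12, burden_mean = 300)
  exp1 <- refit_exposures(sim$catalog, sim$signatures)
  perm <- withr::with_seed(1, sample(nrow(sim$catalog)))
  cat_perm <- sigscape:::new_mut_catalog(
    tibble::as_tibble(sim$catalog)[perm, ], "SBS96")
  exp2 <- refit_exposures(cat_perm, sim$signatures)
  m1 <- sigscape:::exposure_matrix(exp1)
  m2 <- sigscape:::exposure_matrix(exp2)
  expect_equal(m1[rownames(m2), ], m2)
})

test_that("select_rank applies the silhouette threshold rule", {
  mk <- function(ranks, sils) tibble::tibble(rank = ranks, silhouette = sils)
  expect_identical(select_rank(mk(2:4, c(0.95, 0.9, 0.5))), 3L)
  expect_identical(select_rank(mk(2:4, c(0.7, 0.5, 0.4))), 2L)
  expect_identical(select_rank(mk(2:4, c(0.6, 0.85, 0.85))), 4L)
  expect_identical(select_rank(mk(2:4, c(0.79, 0.79, 0.5))), 2L)
})

test_that("degenerate extraction equals a single factorization", {
  sim <- make_test_cohort(n_samples = 15, burden_mean = 300)
  ex <- extract_denovo(sim$catalog, 3, n_restarts = 1, n_bootstraps = 1,
                       seed = 4, max_iter = 500, tol = 1e-7)
  fit <- nmf_factorize(sim$catalog, 3,
                       seed = sigscape:::derive_seed(4, 3 * 1000000L + 1000L + 1L),
                       max_iter = 500, tol = 1e-7)
  expect_equal(sig_matrix(ex$consensus), sig_matrix(fit$signatures))
})

test_that("duplicating every sample leaves consensus signatures unchanged", {
  sim <- make_test_cohort(n_samples = 12, burden_mean = 500, seed = 131)
  tbl <- tibble::as_tibble(sim$catalog)
  dup <- dplyr::mutate(tbl, sample_id = paste0(sample_id, "_dup"))
  cat_dup <- sigscape:::new_mut_catalog(
    dplyr::arrange(dplyr::bind_rows(tbl, dup), sample_id), "SBS96")
  ex1 <- extract_denovo(sim$catalog, 3, n_restarts = 2, n_bootstraps = 1,
                        seed = 5, max_iter = 1500, tol = 1e-7)
  ex2 <- extract_denovo(cat_dup, 3, n_restarts = 2, n_bootstraps = 1,
                        seed = 5, max_iter = 1500, tol = 1e-7)
  m <- sigscape:::cosine_matrix(sig_matrix(ex1$consensus),
                                sig_matrix(ex2$consensus))
  # each consensus signature has a near-identical counterpart
  expect_true(all(apply(m, 1, max) > 0.999))
})
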