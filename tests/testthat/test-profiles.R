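# Per-sample descriptors: grouping, presence, dominance, signature group,
# burden.

fake_exposures <- function(rel, ids) {
  absolute <- rel * 1000
  sigscape:::new_sig_exposures(sprintf("S%02d", seq_len(nrow(rel))), ids,
                               absolute, scheme = "SBS96")
}

test_that("grouping pools member signatures and conserves row sums", {
  rel <- matrix(c(0.10, 0.05, 0.60, 0.25,
                  0.00, 0.00, 1.00, 0.00), 2, byrow = TRUE)
  exp <- fake_exposures(rel, c("SBS2", "SBS13", "SBS3", "SBS18"))
  contrib <- relative_contributions(exp)
  expect_equal(contrib$APOBEC, c(0.15, 0))
  expect_equal(contrib$HRd, c(0.60, 1))
  rel2 <- withr::with_seed(801, {
    m <- matrix(stats::rgamma(8 * 6, 1), 8, 6)
    m / rowSums(m)
  })
  exp2 <- fake_exposures(rel2, c("SBS1", "SBS2", "SBS13", "SBS3", "SBS18", "SBSX"))
  contrib2 <- relative_contributions(exp2)
  expect_equal(rowSums(as.matrix(contrib2[, -1])), rowSums(rel2))
})

test_that("presence uses an inclusive contribution threshold and a count floor", {
  contrib <- tibble::tibble(sample_id = c("a", "b", "c"),
                            G1 = c(0.05, 0.049, 0), G2 = c(0.5, 0.5, 0.5))
  burdens <- tibble::tibble(sample_id = c("a", "b", "c"),
                            tmb = c(1000L, 1000L, 100L))
  pres <- call_presence(contrib, burdens, threshold = 0.05, min_mutations = 10)
  expect_identical(pres$G1, c(1L, 0L, 0L))
  expect_identical(pres$G2, c(1L, 1L, 1L))
  # attributed-count floor: contribution passes but counts do not
  pres2 <- call_presence(contrib, burdens, threshold = 0.05,
                         min_mutations = 60)
  expect_identical(pres2$G2, c(1L, 1L, 0L))
  # brute-force double-threshold oracle on random matrices
  rnd <- withr::with_seed(802, {
    tibble::tibble(sample_id = sprintf("S%02d", 1:30),
                   A = stats::runif(30, 0, 0.2),
                   B = stats::runif(30, 0, 0.2))
  })
  bd <- tibble::tibble(sample_id = rnd$sample_id,
                       tmb = withr::with_seed(803, sample(50:500, 30, TRUE)))
  pres3 <- call_presence(rnd, bd, threshold = 0.05, min_mutations = 10)
  for (g in c("A", "B")) {
    want <- as.integer(rnd[[g]] >= 0.05 & rnd[[g]] * bd$tmb >= 10)
    expect_identical(pres3[[g]], want)
  }
})

test_that("dominant signatures order by contribution with lexicographic ties", {
  contrib <- tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    A = c(0.6, 0.4, 0),
    B = c(0.3, 0.4, 1),
    C = c(0.1, 0.2, 0)
  )
  dom <- dominant_signatures(contrib)
  expect_identical(dom$first_dominant, c("A", "A", "B"))
  expect_identical(dom$second_dominant, c("B", "B", NA))
  # brute-force sort agreement on random contribution rows
  rnd <- withr::with_seed(804, {
    m <- matrix(stats::runif(25 * 4), 25, 4)
    m / rowSums(m)
  })
  tbl <- dplyr::bind_cols(tibble::tibble(sample_id = sprintf("S%02d", 1:25)),
                          stats::setNames(as.data.frame(rnd), c("W", "X", "Y", "Z")))
  dom2 <- dominant_signatures(tbl)
  for (i in 1:25) {
    ord <- order(-rnd[i, ], c("W", "X", "Y", "Z"))
    expect_identical(dom2$first_dominant[i], c("W", "X", "Y", "Z")[ord[1]])
    expect_identical(dom2$second_dominant[i], c("W", "X", "Y", "Z")[ord[2]])
  }
})

test_that("the Others rule applies only when both dominants are clock-like", {
  expect_identical(assign_signature_group("SBS5", "Aging"), "Others")
  expect_identical(assign_signature_group("Aging", NA), "Others")
  expect_identical(assign_signature_group("HRd", "SBS5"), "HRd")
  expect_identical(assign_signature_group("SBS5", "APOBEC"), "APOBEC")
  expect_identical(assign_signature_group("APOBEC", "HRd"), "APOBEC")
})

test_that("tmb equals independent row summation", {
  sim <- make_test_cohort(n_samples = 15, burden_mean = 200)
  got <- tmb(sim$catalog)
  want <- apply(as.matrix(tibble::as_tibble(sim$catalog)[, -1]), 1, sum)
  expect_equal(got$tmb, as.integer(want))
  zero <- sigscape:::new_mut_catalog(
    dplyr::mutate(tibble::as_tibble(sim$catalog),
                  dplyr::across(-sample_id, ~0L)), "SBS96")
  expect_true(all(tmb(zero)$tmb == 0))
})

test_that("presence is invariant to signature order within groups", {
  rel <- withr::with_seed(805, {
    m <- matrix(stats::rgamma(10 * 3, 1), 10, 3)
    m / rowSums(m)
  })
  e1 <- fake_exposures(rel, c("SBS2", "SBS13", "SBS3"))
  e2 <- fake_exposures(rel[, c(2, 1, 3)], c("SBS13", "SBS2", "SBS3"))
  burdens <- tibble::tibble(sample_id = sprintf("S%02d", 1:10), tmb = 500L)
  p1 <- call_presence(relative_contributions(e1), burdens)
  p2 <- call_presence(relative_contributions(e2), burdens)
  expect_identical(p1, p2)
})

test_that("planted presence is recovered with high sensitivity", {
  sim <- make_test_cohort(n_samples = 80, burden_mean = 1000, seed = 151)
  fit <- refit_exposures(sim$catalog, sim$signatures)
  contrib <- relative_contributions(fit)
  pres <- call_presence(contrib, tmb(sim$catalog), threshold = 0.05)
  truth <- sim$truth$presence
  # sensitivity among planted signatures with true contribution >= 0.05
  tp <- 0L; pos <- 0L
  for (s in c("S1", "S2", "S3")) {
    planted <- truth[[s]] == 1L & sim$truth$exposures[[s]] >= 0.05
    pos <- pos + sum(planted)
    tp <- tp + sum(pres[[s]][planted] == 1L)
  }
  expect_gte(tp / pos, 0.95)
})
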