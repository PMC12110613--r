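# Synthetic cohort generator: signatures, presence constraints, burdens,
# record synthesis and round-trips.

test_that("simulated signatures are column-stochastic, distinct and seeded", {
  sigs <- simulate_signatures(scheme = "SBS96", n_signatures = 4, seed = 1101,
                              concentration = 0.1)
  m <- sig_matrix(sigs)
  expect_true(all(abs(colSums(m) - 1) < 1e-8))
  cm <- sigscape:::cosine_matrix(m, m)
  expect_true(all(cm[upper.tri(cm)] < 0.8))
  sigs2 <- simulate_signatures(scheme = "SBS96", n_signatures = 4, seed = 1101,
                               concentration = 0.1)
  expect_identical(as.data.frame(sigs), as.data.frame(sigs2))
})

test_that("infeasible signature separation raises a parameter error", {
  expect_error(
    simulate_signatures(n_channels = 3, n_signatures = 30, concentration = 50,
                        seed = 1, max_draws = 200),
    "cosine")
})

test_that("hard-exclusive pairs never co-occur and seeds reproduce cohorts", {
  sigs <- simulate_signatures(scheme = "SBS96", n_signatures = 4, seed = 1111,
                              concentration = 0.1)
  spec <- cohort_spec(sigs, n_samples = 150, presence_prob = 0.5,
                      exclusive_pairs = list(c("S1", "S2")),
                      cooccur_pairs = list(c("S3", "S4")),
                      seed = 1112)
  sim <- simulate_cohort(spec)
  overlap <- sum(sim$truth$presence$S1 & sim$truth$presence$S2)
  expect_identical(overlap, 0L)
  sim2 <- simulate_cohort(spec)
  expect_identical(as.data.frame(sim$catalog), as.data.frame(sim2$catalog))
  expect_identical(sim$truth$annotations, sim2$truth$annotations)
  # co-occurrence multiplier raises the joint presence rate
  both <- mean(sim$truth$presence$S3 & sim$truth$presence$S4)
  expect_gt(both, 0.25)   # independent Bernoulli(0.5) pairs would give ~0.25
})

test_that("inconsistent pair constraints are rejected with the pair named", {
  sigs <- simulate_signatures(scheme = "SBS96", n_signatures = 3, seed = 1121)
  expect_error(
    cohort_spec(sigs, exclusive_pairs = list(c("S1", "S2")),
                cooccur_pairs = list(c("S2", "S1"))),
    "S1")
})

test_that("exposures of absent signatures are zero and active rows sum to 1", {
  sim <- make_test_cohort(n_samples = 50, burden_mean = 400, seed = 1131)
  expo <- as.matrix(sim$truth$exposures[, -1])
  pres <- as.matrix(sim$truth$presence[, -1])
  expect_true(all(expo[pres == 0L] == 0))
  expect_true(all(abs(rowSums(expo) - 1) < 1e-8))
})

test_that("HRd annotations follow the designated signature's activity", {
  sim <- make_test_cohort(n_samples = 60, burden_mean = 300, seed = 1141,
                          hrd_signature = "S2")
  ann <- sim$truth$annotations
  active <- sim$truth$presence$S2 == 1L
  expect_identical(ann$biallelic_hrd_gene, active)
  expect_true(all(ann$hrd_score[active] >= 0.5))
  expect_true(all(ann$hrd_score[!active] < 0.1))
})

test_that("record synthesis round-trips the catalog for all three schemes", {
  for (scheme in c("SBS96", "DBS78", "ID83")) {
    sigs <- simulate_signatures(scheme = scheme, n_signatures = 3,
                                concentration = 0.1, seed = 1151)
    spec <- cohort_spec(sigs, n_samples = 15, burden_mean = 150, seed = 1152)
    sim <- simulate_cohort(spec)
    rec <- simulate_ssm_records(sim$catalog, seed = 1153)
    back <- build_catalog(rec, scheme, sample_ids = sim$catalog$sample_id)
    expect_identical(as.data.frame(back), as.data.frame(sim$catalog))
  }
})

test_that("records emitted for a channel carry that channel's alleles", {
  labels <- channel_labels("SBS96")
  tbl <- dplyr::bind_cols(
    tibble::tibble(sample_id = "S1"),
    tibble::as_tibble(as.data.frame(matrix(1L, 1, 96)),
                      .name_repair = "minimal") |> stats::setNames(labels)
  )
  catalog <- sigscape:::new_mut_catalog(tbl, "SBS96")
  rec <- simulate_ssm_records(catalog, seed = 1161)
  i <- which(labels == "A[C>A]A")
  expect_identical(rec$ref[i], "C")
  expect_identical(rec$alt[i], "A")
  expect_identical(substr(rec$context5[i], 10, 10), "A")
  expect_identical(substr(rec$context3[i], 1, 1), "A")
})

test_that("record synthesis is byte-deterministic given the seed", {
  sim <- make_test_cohort(n_samples = 8, burden_mean = 100, seed = 1171)
  r1 <- simulate_ssm_records(sim$catalog, seed = 5)
  r2 <- simulate_ssm_records(sim$catalog, seed = 5)
  expect_identical(r1, r2)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_ssm(r1, p1); write_ssm(r2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("refitting with the true signatures recovers planted exposures", {
  sim <- make_test_cohort(n_samples = 60, burden_mean = 1000, seed = 1181)
  fit <- refit_exposures(sim$catalog, sim$signatures)
  for (s in c("S1", "S2", "S3")) {
    r <- stats::cor(fit$relative[[s]], sim$truth$exposures[[s]])
    expect_gte(r, 0.9)
  }
})

test_that("planted exclusivity is recovered by the interaction test", {
  sigs <- simulate_signatures(scheme = "SBS96", n_signatures = 4, seed = 1191,
                              concentration = 0.1)
  spec <- cohort_spec(sigs, n_samples = 100, presence_prob = 0.35,
                      burden_mean = 800,
                      exclusive_pairs = list(c("S1", "S2")), seed = 1192)
  sim <- simulate_cohort(spec)
  res <- interaction_matrix(sim$truth$presence, adjust = "none")
  ab <- res[res$group_a == "S1" & res$group_b == "S2", ]
  expect_identical(ab$direction, "exclusive")
})
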