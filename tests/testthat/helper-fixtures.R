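# Shared fixture builders.

# presence/contribution/dominant fixture with exact per-group counts
make_presence_fixture <- function(N, counts) {
  pres <- tibble::tibble(sample_id = sprintf("S%04d", seq_len(N)))
  contrib <- pres
  for (g in names(counts)) {
    v <- c(rep(1L, counts[[g]]), rep(0L, N - counts[[g]]))
    pres[[g]] <- v
    contrib[[g]] <- ifelse(v == 1L, 0.5, 0)
  }
  dom <- tibble::tibble(sample_id = pres$sample_id,
                        first_dominant = NA_character_,
                        second_dominant = NA_character_)
  list(presence = pres, contributions = contrib, dominants = dom)
}

# synthetic cohort written to disk in the dialects the pipeline consumes
make_pipeline_inputs <- function(dir, n_samples = 25, seed = 1201) {
  sigs <- simulate_signatures(scheme = "SBS96", n_signatures = 3,
                              concentration = 0.1, seed = seed)
  spec <- cohort_spec(sigs, n_samples = n_samples, burden_mean = 400,
                      hrd_signature = "S1", seed = seed + 1)
  sim <- simulate_cohort(spec)
  rec <- simulate_ssm_records(sim$catalog, seed = seed + 2)
  ssm <- file.path(dir, "cohort.ssm.tsv")
  write_ssm(rec, ssm)
  ref <- file.path(dir, "reference_sbs96.tsv")
  write_signatures(sigs, ref)
  ann <- file.path(dir, "annotations.tsv")
  readr::write_tsv(sim$truth$annotations, ann)
  list(ssm = ssm, reference = ref, annotations = ann, sim = sim)
}
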