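# Independent brute-force oracles used to cross-check the channel
# classifiers and the exact tests. These deliberately take different code
# paths from the package: table lookups enumerated per label, naive scanning
# over the reconstructed reference string, and binomial-coefficient sums.

oracle_revcomp <- function(x) {
  vapply(strsplit(chartr("ACGT", "TGCA", x), ""), function(b) {
    paste(rev(b), collapse = "")
  }, character(1))
}

# SBS96 oracle: exhaustive lookup (f5, ref, alt, f3) -> label, built by
# expanding each canonical label into its two strand representations.
sbs_oracle_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    out <- new.env()
    for (lab in channel_labels("SBS96")) {
      f5 <- substr(lab, 1, 1); ref <- substr(lab, 3, 3)
      alt <- substr(lab, 5, 5); f3 <- substr(lab, 7, 7)
      assign(paste(f5, ref, alt, f3), lab, envir = out)
      assign(paste(oracle_revcomp(f3), oracle_revcomp(ref),
                   oracle_revcomp(alt), oracle_revcomp(f5)), lab, envir = out)
    }
    tab <<- out
    tab
  }
})

oracle_classify_sbs <- function(ref, alt, context5, context3) {
  tab <- sbs_oracle_table()
  vapply(seq_along(ref), function(i) {
    f5 <- substr(context5[i], nchar(context5[i]), nchar(context5[i]))
    f3 <- substr(context3[i], 1, 1)
    get(paste(f5, ref[i], alt[i], f3), envir = tab)
  }, character(1))
}

# DBS78 oracle: exhaustive lookup over both strand representations of every
# channel.
dbs_oracle_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    out <- new.env()
    for (lab in channel_labels("DBS78")) {
      ref <- substr(lab, 1, 2); alt <- substr(lab, 4, 5)
      assign(paste(ref, alt), lab, envir = out)
      assign(paste(oracle_revcomp(ref), oracle_revcomp(alt)), lab, envir = out)
    }
    tab <<- out
    tab
  }
})

oracle_classify_dbs <- function(ref, alt) {
  tab <- dbs_oracle_table()
  vapply(seq_along(ref), function(i) {
    get(paste(ref[i], alt[i]), envir = tab)
  }, character(1))
}

# ID83 oracle: naive scanning over the reconstructed reference sequence with
# explicit index arithmetic (no shared helpers with the package).
oracle_classify_indel <- function(ref, alt, context5, context3) {
  vapply(seq_along(ref), function(i) {
    is_del <- alt[i] == "-"
    ev <- if (is_del) ref[i] else alt[i]
    len <- nchar(ev)
    chars <- strsplit(ev, "")[[1]]
    if (is_del) {
      seqfull <- paste0(context5[i], ev, context3[i])
      ev_start <- nchar(context5[i]) + 1L
      ev_end <- ev_start + len - 1L
    } else {
      seqfull <- paste0(context5[i], context3[i])
      ins_after <- nchar(context5[i])
    }
    s <- strsplit(seqfull, "")[[1]]
    if (len == 1L) {
      b <- chars[1]
      if (is_del) {
        run <- 1L
        j <- ev_start - 1L
        while (j >= 1 && s[j] == b) { run <- run + 1L; j <- j - 1L }
        j <- ev_end + 1L
        while (j <= length(s) && s[j] == b) { run <- run + 1L; j <- j + 1L }
        pyr <- if (b %in% c("C", "T")) b else chartr("AG", "TC", b)
        paste0("1:Del:", pyr, ":", min(run, 6L) - 1L)
      } else {
        run <- 0L
        j <- ins_after
        while (j >= 1 && s[j] == b) { run <- run + 1L; j <- j - 1L }
        j <- ins_after + 1L
        while (j <= length(s) && s[j] == b) { run <- run + 1L; j <- j + 1L }
        pyr <- if (b %in% c("C", "T")) b else chartr("AG", "TC", b)
        paste0("1:Ins:", pyr, ":", min(run, 5L))
      }
    } else {
      get_chunk <- function(from, to) {
        if (from < 1 || to > length(s)) return(NULL)
        paste(s[from:to], collapse = "")
      }
      if (is_del) {
        copies <- 1L
        # right of event
        j <- ev_end + 1L
        while (!is.null(ch <- get_chunk(j, j + len - 1L)) && ch == ev) {
          copies <- copies + 1L; j <- j + len
        }
        # left of event
        j <- ev_start - len
        while (j >= 1 && get_chunk(j, j + len - 1L) == ev) {
          copies <- copies + 1L; j <- j - len
        }
        if (copies == 1L) {
          hom_r <- 0L
          while (hom_r < len &&
                 ev_end + hom_r + 1L <= length(s) &&
                 s[ev_end + hom_r + 1L] == chars[hom_r + 1L]) {
            hom_r <- hom_r + 1L
          }
          hom_l <- 0L
          while (hom_l < len &&
                 ev_start - hom_l - 1L >= 1 &&
                 s[ev_start - hom_l - 1L] == chars[len - hom_l]) {
            hom_l <- hom_l + 1L
          }
          hom <- max(hom_r, hom_l)
          if (hom >= 1L) {
            return(paste0(min(len, 5L), ":Del:M:", min(hom, 5L)))
          }
        }
        paste0(min(len, 5L), ":Del:R:", min(copies, 6L) - 1L)
      } else {
        copies <- 0L
        j <- ins_after + 1L
        while (!is.null(ch <- get_chunk(j, j + len - 1L)) && ch == ev) {
          copies <- copies + 1L; j <- j + len
        }
        j <- ins_after - len + 1L
        while (j >= 1 && get_chunk(j, j + len - 1L) == ev) {
          copies <- copies + 1L; j <- j - len
        }
        paste0(min(len, 5L), ":Ins:R:", min(copies, 5L))
      }
    }
  }, character(1))
}

# exact hypergeometric tails by binomial-coefficient sums
oracle_hypergeom_tails <- function(N, n_a, n_b, k) {
  lo <- max(0, n_a + n_b - N)
  hi <- min(n_a, n_b)
  probs <- choose(n_a, lo:hi) * choose(N - n_a, n_b - (lo:hi)) / choose(N, n_b)
  ks <- lo:hi
  c(p_co = sum(probs[ks >= k]), p_ex = sum(probs[ks <= k]))
}

# exact two-sided Fisher p for a 2x2 table by enumeration of all tables with
# the observed margins
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  lo <- max(0, r1 + c1 - N); hi <- min(r1, c1)
  probs <- choose(r1, lo:hi) * choose(N - r1, c1 - (lo:hi)) / choose(N, c1)
  obs <- probs[tab[1, 1] - lo + 1]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# random record generators -------------------------------------------------

random_snv_records <- function(n, seed) {
  withr::with_seed(seed, {
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                  character(1))
    tibble::tibble(
      sample_id = sample(sprintf("S%02d", 1:8), n, replace = TRUE),
      chromosome = "chrS1", position = seq_len(n) * 10L,
      ref = ref, alt = unname(alt), kind = "SNV",
      context5 = replicate(n, paste(sample(c("A", "C", "G", "T"), 10,
                                           replace = TRUE), collapse = "")),
      context3 = replicate(n, paste(sample(c("A", "C", "G", "T"), 10,
                                           replace = TRUE), collapse = ""))
    )
  })
}

random_dnv_records <- function(n, seed) {
  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    ref <- paste0(sample(bases, n, TRUE), sample(bases, n, TRUE))
    alt <- vapply(ref, function(r) {
      paste0(sample(setdiff(bases, substr(r, 1, 1)), 1),
             sample(setdiff(bases, substr(r, 2, 2)), 1))
    }, character(1))
    tibble::tibble(
      sample_id = sample(sprintf("S%02d", 1:8), n, replace = TRUE),
      chromosome = "chrS1", position = seq_len(n) * 10L,
      ref = ref, alt = unname(alt), kind = "DNV",
      context5 = replicate(n, paste(sample(bases, 10, TRUE), collapse = "")),
      context3 = replicate(n, paste(sample(bases, 10, TRUE), collapse = ""))
    )
  })
}

# random indels embedded in random sequence; extra tandem copies / homology
# are planted with moderate probability so high bins get exercised
random_indel_records <- function(n, seed) {
  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      len <- sample(1:6, 1, prob = c(0.4, 0.15, 0.15, 0.1, 0.1, 0.1))
      ev <- paste(sample(bases, len, TRUE), collapse = "")
      is_del <- stats::runif(1) < 0.5
      extra <- sample(0:6, 1, prob = c(0.35, 0.2, 0.15, 0.1, 0.08, 0.07, 0.05))
      ctx3 <- paste0(strrep(ev, extra),
                     paste(sample(bases, max(10, 5 * len), TRUE), collapse = ""))
      ctx5 <- paste(sample(bases, 12, TRUE), collapse = "")
      if (stats::runif(1) < 0.3) {  # plant 5' copies too
        ctx5 <- paste0(paste(sample(bases, 12, TRUE), collapse = ""),
                       strrep(ev, sample(0:2, 1)))
      }
      tibble::tibble(
        sample_id = sample(sprintf("S%02d", 1:8), 1),
        chromosome = "chrS1", position = i * 50L,
        ref = if (is_del) ev else "-", alt = if (is_del) "-" else ev,
        kind = if (is_del) "DEL" else "INS",
        context5 = ctx5, context3 = ctx3
      )
    })
    dplyr::bind_rows(rows)
  })
}

# small planted cohort reused across tests
make_test_cohort <- function(n_samples = 40, burden_mean = 500, seed = 101,
                             n_signatures = 3, scheme = "SBS96", ...) {
  sigs <- simulate_signatures(scheme = scheme, n_signatures = n_signatures,
                              concentration = 0.1, seed = seed)
  spec <- cohort_spec(sigs, n_samples = n_samples, burden_mean = burden_mean,
                      seed = seed + 1, ...)
  c(simulate_cohort(spec), list(signatures = sigs))
}
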