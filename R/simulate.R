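# Synthetic cohort generator: signature profiles, presence structure with
# planted co-occurrence / exclusivity, Dirichlet exposures, negative-binomial
# burdens, multinomial channel counts, annotations, and concrete SSM records
# whose alleles and flanking context classify back into their source channel.

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate a synthetic signature set
#'
#' Columns are drawn from a symmetric Dirichlet over the channels; pairwise
#' cosine similarity below `max_cosine` is enforced by rejection so planted
#' signatures remain identifiable downstream.
#'
#' @param n_channels Number of channels (ignored when `scheme` is given).
#' @param n_signatures Number of signatures.
#' @param concentration Symmetric Dirichlet concentration; small values
#'   (e.g. 0.1) give sparse, signature-like profiles.
#' @param seed Integer seed.
#' @param scheme Optional channel scheme supplying canonical channel labels.
#' @param max_cosine Maximum allowed pairwise cosine similarity.
#' @param max_draws Rejection cap; exceeding it raises a parameter error.
#' @return A `sig_set` with signatures `S1..Sk`.
#' @export
simulate_signatures <- function(n_channels = 96L, n_signatures = 3L,
                                concentration = 0.1, seed = 1L,
                                scheme = NULL, max_cosine = 0.8,
                                max_draws = 1e4) {
  stopifnot(n_signatures >= 1L)
  if (!is.null(scheme)) {
    labels <- channel_labels(scheme)
    n_channels <- length(labels)
  } else {
    labels <- paste0("ch", seq_len(n_channels))
  }
  cols <- withr::with_seed(seed, {
    out <- list()
    draws <- 0L
    while (length(out) < n_signatures) {
      draws <- draws + 1L
      if (draws > max_draws)
        stop("could not draw ", n_signatures,
             " signatures with pairwise cosine < ", max_cosine,
             "; lower the concentration or the signature count")
      cand <- rdirichlet1(rep(concentration, n_channels))
      ok <- all(vapply(out, function(x) cosine_similarity(x, cand) < max_cosine,
                       logical(1)))
      if (ok) out[[length(out) + 1L]] <- cand
    }
    out
  })
  m <- do.call(cbind, cols)
  rownames(m) <- labels
  colnames(m) <- paste0("S", seq_len(n_signatures))
  profiles <- dplyr::bind_cols(
    tibble::tibble(channel = labels),
    tibble::as_tibble(as.data.frame(m), .name_repair = "minimal")
  )
  out <- structure(profiles, class = c("sig_set", class(tibble::tibble())))
  out <- set_attr(out, "scheme", if (is.null(scheme)) NA_character_ else scheme)
  out <- set_attr(out, "provenance", "reference")
  # validate column stochasticity through the constructor when labels are canonical
  if (!is.null(scheme)) out <- sig_set(profiles, scheme, "reference")
  out
}

#' Specify a synthetic cohort
#'
#' Collects and validates every parameter of the generator: per-signature
#' marginal presence probabilities, pairwise presence constraints (hard
#' exclusivity, or a co-occurrence odds multiplier), Dirichlet exposure
#' concentration over the active set, a negative-binomial burden model,
#' a grade label distribution, and the rule linking a designated HRd
#' signature to the annotation flag and score.
#'
#' @param signatures A `sig_set` of the planted signatures.
#' @param n_samples Cohort size.
#' @param presence_prob Marginal presence probability per signature; scalar
#'   or named vector over the signature ids.
#' @param exposure_concentration Dirichlet concentration over the active set.
#' @param burden_mean,burden_dispersion Negative-binomial mutation burden
#'   mean and dispersion (size); variance is `mu + mu^2 / size`.
#' @param exclusive_pairs List of length-2 character vectors: pairs that are
#'   never present together.
#' @param cooccur_pairs List of length-2 character vectors: pairs whose
#'   joint presence odds are multiplied by `cooccur_odds`.
#' @param cooccur_odds Odds multiplier (> 1) for `cooccur_pairs`.
#' @param grade_probs Named probabilities for the grade labels.
#' @param hrd_signature Optional signature id treated as the HRd process:
#'   samples where it is active get `biallelic_hrd_gene = TRUE` and a high
#'   HRd score, inactive samples a score below 0.1.
#' @param seed Integer seed.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(signatures, n_samples = 100L, presence_prob = 0.4,
                        exposure_concentration = 1,
                        burden_mean = 1000, burden_dispersion = 2,
                        exclusive_pairs = list(), cooccur_pairs = list(),
                        cooccur_odds = 4,
                        grade_probs = c(G1 = 0.10, G2 = 0.45, G3 = 0.45),
                        hrd_signature = NULL, seed = 1L) {
  ids <- signature_ids(signatures)
  if (length(presence_prob) == 1L)
    presence_prob <- stats::setNames(rep(presence_prob, length(ids)), ids)
  stopifnot(all(names(presence_prob) %in% ids),
            all(presence_prob >= 0 & presence_prob <= 1),
            burden_mean > 0, burden_dispersion > 0, cooccur_odds > 0,
            abs(sum(grade_probs) - 1) < 1e-8)
  norm_pair <- function(p) sort(as.character(p))
  ex <- lapply(exclusive_pairs, norm_pair)
  co <- lapply(cooccur_pairs, norm_pair)
  for (p in c(ex, co)) {
    if (!all(p %in% ids)) stop("constraint names unknown signature: ",
                               paste(p, collapse = ", "))
  }
  both <- intersect(vapply(ex, paste, character(1), collapse = "|"),
                    vapply(co, paste, character(1), collapse = "|"))
  if (length(both) > 0)
    stop("inconsistent constraints: pair(s) both exclusive and co-occurring: ",
         paste(both, collapse = "; "))
  if (!is.null(hrd_signature)) stopifnot(hrd_signature %in% ids)
  structure(list(
    signatures = signatures, n_samples = as.integer(n_samples),
    presence_prob = presence_prob[ids],
    exposure_concentration = exposure_concentration,
    burden_mean = burden_mean, burden_dispersion = burden_dispersion,
    exclusive_pairs = ex, cooccur_pairs = co, cooccur_odds = cooccur_odds,
    grade_probs = grade_probs, hrd_signature = hrd_signature,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

sample_presence_vector <- function(spec, max_attempts = 1e4) {
  ids <- names(spec$presence_prob)
  n_co <- length(spec$cooccur_pairs)
  for (attempt in seq_len(max_attempts)) {
    pres <- stats::rbinom(length(ids), 1L, spec$presence_prob) == 1L
    names(pres) <- ids
    ok <- TRUE
    for (p in spec$exclusive_pairs) {
      if (pres[p[1]] && pres[p[2]]) { ok <- FALSE; break }
    }
    if (!ok) next
    if (n_co > 0) {
      both <- vapply(spec$cooccur_pairs,
                     function(p) pres[p[1]] && pres[p[2]], logical(1))
      accept_prob <- spec$cooccur_odds^(sum(both) - n_co)
      if (stats::runif(1) > accept_prob) next
    }
    if (!any(pres)) next
    return(pres)
  }
  stop("presence constraints could not be satisfied in ", max_attempts,
       " attempts; check the exclusive/co-occurring pair set")
}

#' Simulate a mutation catalog with known ground truth
#'
#' Per sample: an active signature set is drawn from the presence model
#' (rejection sampling exactly honors hard-exclusive pairs and the
#' co-occurrence odds multiplier; at least one signature is always active);
#' relative exposures are Dirichlet over the active set; the burden is
#' negative-binomial; and channel counts are multinomial from the mixed
#' profile. Annotations carry grade labels and, when an HRd signature is
#' designated, the bi-allelic flag and HRd score tied to its activity.
#'
#' @param spec A [cohort_spec()].
#' @return List with `catalog` (a `mut_catalog` when the signature set has a
#'   canonical scheme, otherwise a plain counts tibble) and `truth` (a
#'   `cohort_truth` list: `presence`, `exposures` relative tibble, `burdens`,
#'   `annotations`).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  P <- sig_matrix(spec$signatures)
  ids <- colnames(P)
  n <- spec$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))
  withr::with_seed(spec$seed, {
    presence <- matrix(0L, n, length(ids), dimnames = list(NULL, ids))
    expo <- matrix(0, n, length(ids), dimnames = list(NULL, ids))
    burdens <- integer(n)
    counts <- matrix(0L, n, nrow(P))
    for (i in seq_len(n)) {
      pres <- sample_presence_vector(spec)
      presence[i, ] <- as.integer(pres)
      active <- which(pres)
      e <- rdirichlet1(rep(spec$exposure_concentration, length(active)))
      expo[i, active] <- e
      burdens[i] <- stats::rnbinom(1, size = spec$burden_dispersion,
                                   mu = spec$burden_mean)
      if (burdens[i] > 0) {
        mix <- as.vector(P[, active, drop = FALSE] %*% e)
        counts[i, ] <- as.vector(stats::rmultinom(1, burdens[i], mix))
      }
    }
    grade <- sample(names(spec$grade_probs), n, replace = TRUE,
                    prob = spec$grade_probs)
    if (!is.null(spec$hrd_signature)) {
      hrd_active <- presence[, spec$hrd_signature] == 1L
      biallelic <- hrd_active
      hrd_score <- ifelse(hrd_active, stats::runif(n, 0.5, 1),
                          stats::runif(n, 0, 0.0999))
    } else {
      biallelic <- rep(FALSE, n)
      hrd_score <- stats::runif(n, 0, 0.0999)
    }
  })
  scheme <- scheme_of(spec$signatures)
  counts_tbl <- tibble::as_tibble(as.data.frame(counts), .name_repair = "minimal")
  names(counts_tbl) <- rownames(P)
  counts_tbl <- dplyr::mutate(counts_tbl,
                              dplyr::across(dplyr::everything(), as.integer))
  counts_tbl <- dplyr::bind_cols(tibble::tibble(sample_id = sample_ids),
                                 counts_tbl)
  catalog <- if (!is.null(scheme) && !is.na(scheme)) {
    new_mut_catalog(counts_tbl, scheme)
  } else {
    counts_tbl
  }
  truth <- structure(list(
    presence = dplyr::bind_cols(tibble::tibble(sample_id = sample_ids),
                                tibble::as_tibble(as.data.frame(presence),
                                                  .name_repair = "minimal")),
    exposures = dplyr::bind_cols(tibble::tibble(sample_id = sample_ids),
                                 tibble::as_tibble(as.data.frame(expo),
                                                   .name_repair = "minimal")),
    burdens = tibble::tibble(sample_id = sample_ids, tmb = burdens),
    annotations = tibble::tibble(
      sample_id = sample_ids, grade = grade, subtype = "TNBC",
      hrd_score = hrd_score, biallelic_hrd_gene = biallelic
    )
  ), class = "cohort_truth")
  list(catalog = catalog, truth = truth)
}

# --- concrete record synthesis --------------------------------------------

rand_bases <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

base_not <- function(excluded) {
  sample(setdiff(DNA_BASES, excluded), 1)
}

# repeat units used for >=2 bp indel channels; non-periodic by construction
indel_unit <- function(len) {
  paste(rep_len(c("A", "C", "G", "T"), len), collapse = "")
}

# Build (ref, alt, context5, context3) whose classification is exactly
# `channel`. Pads contexts to the ID83 scan-window requirements.
contexts_for_channel <- function(channel, scheme) {
  if (scheme == "SBS96") {
    f5 <- substr(channel, 1, 1)
    ref <- substr(channel, 3, 3)
    alt <- substr(channel, 5, 5)
    f3 <- substr(channel, 7, 7)
    return(list(ref = ref, alt = alt,
                context5 = paste0(rand_bases(9), f5),
                context3 = paste0(f3, rand_bases(9))))
  }
  if (scheme == "DBS78") {
    ref <- substr(channel, 1, 2)
    alt <- substr(channel, 4, 5)
    return(list(ref = ref, alt = alt,
                context5 = rand_bases(10), context3 = rand_bases(10)))
  }
  # ID83
  parts <- strsplit(channel, ":", fixed = TRUE)[[1]]
  len_lab <- as.integer(parts[1])
  op <- parts[2]
  sub <- parts[3]
  bin <- as.integer(parts[4])
  if (sub %in% c("C", "T")) {          # 1 bp homopolymer channels
    b <- sub
    run_ref <- if (op == "Del") bin else bin   # pre-existing copies in ref
    # deletions: total run = bin + 1 (includes the deleted base)
    extra3 <- run_ref
    brk3 <- base_not(b)
    brk5 <- base_not(b)
    ctx3 <- paste0(strrep(b, extra3), brk3, rand_bases(10))
    ctx5 <- paste0(rand_bases(10), brk5)
    if (op == "Del") {
      list(ref = b, alt = "-", context5 = ctx5, context3 = ctx3)
    } else {
      list(ref = "-", alt = b, context5 = ctx5, context3 = ctx3)
    }
  } else if (sub == "R") {             # >=2 bp repeat channels
    len <- len_lab                      # use the minimal length of the bin
    unit <- indel_unit(len)
    first <- substr(unit, 1, 1)
    last <- substr(unit, len, len)
    extra3 <- if (op == "Del") bin else bin  # full copies placed 3'
    brk3 <- base_not(first)
    brk5 <- base_not(last)
    pad <- max(0L, 5L * len - (extra3 * len + 1L)) + 5L
    ctx3 <- paste0(strrep(unit, extra3), brk3, rand_bases(pad + 10L))
    ctx5 <- paste0(rand_bases(10), brk5)
    if (op == "Del") {
      list(ref = unit, alt = "-", context5 = ctx5, context3 = ctx3)
    } else {
      list(ref = "-", alt = unit, context5 = ctx5, context3 = ctx3)
    }
  } else {                              # microhomology deletions
    hom <- bin
    len <- if (len_lab == 5L && hom == 5L) 6L else len_lab
    unit <- indel_unit(len)
    first <- substr(unit, 1, 1)
    last <- substr(unit, len, len)
    brk3 <- base_not(substr(unit, hom + 1L, hom + 1L))
    brk5 <- base_not(last)
    pad <- 5L * len
    ctx3 <- paste0(substr(unit, 1, hom), brk3, rand_bases(pad))
    ctx5 <- paste0(rand_bases(10), brk5)
    list(ref = unit, alt = "-", context5 = ctx5, context3 = ctx3)
  }
}

#' Synthesize concrete SSM records realizing a catalog
#'
#' For every counted channel event a mutation record is generated whose
#' alleles and flanking context classify back into exactly that channel, so
#' `build_catalog(simulate_ssm_records(catalog))` reproduces the catalog.
#' Chromosome names are synthetic (`"chrS1"`) and flanking sequence is
#' generated, not drawn from a real genome.
#'
#' @param catalog A `mut_catalog`.
#' @param seed Integer seed (contexts contain random filler bases).
#' @return Tibble of mutation records in the layout of [read_ssm()].
#' @export
simulate_ssm_records <- function(catalog, seed = 1L) {
  scheme <- scheme_of(catalog)
  labels <- channel_labels(scheme)
  m <- catalog_matrix(catalog)
  withr::with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(m))) {
      sid <- catalog$sample_id[i]
      pos <- 0L
      for (j in seq_along(labels)) {
        cnt <- m[i, j]
        if (cnt == 0) next
        for (r in seq_len(cnt)) {
          pos <- pos + 1000L
          ctx <- contexts_for_channel(labels[j], scheme)
          kind <- if (ctx$ref == "-") "INS"
                  else if (ctx$alt == "-") "DEL"
                  else if (nchar(ctx$ref) == 1L) "SNV"
                  else "DNV"
          rows[[length(rows) + 1L]] <- tibble::tibble(
            sample_id = sid, chromosome = "chrS1", position = pos,
            ref = ctx$ref, alt = ctx$alt, kind = kind,
            context5 = ctx$context5, context3 = ctx$context3
          )
        }
      }
    }
  })
  if (length(rows) == 0L) {
    return(tibble::tibble(
      sample_id = character(0), chromosome = character(0),
      position = integer(0), ref = character(0), alt = character(0),
      kind = character(0), context5 = character(0), context3 = character(0)
    ))
  }
  dplyr::bind_rows(rows)
}
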