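# Signature set container (channels x signatures, column-stochastic) and the
# reference-matching / decomposition operations.

#' Construct a signature set
#'
#' A signature set holds column-stochastic mutational signature profiles:
#' a `channel` column in the scheme's canonical order plus one numeric column
#' per signature, each summing to 1 (checked to 1e-8).
#'
#' @param profiles Tibble or data frame with a `channel` column and one
#'   column per signature, or a channels x signatures matrix with channel row
#'   names.
#' @param scheme Channel scheme; when `NULL` inferred from the row count.
#' @param provenance One of `"denovo"`, `"reference"`, `"decomposed"`.
#' @param normalize Renormalize columns to sum to 1 instead of failing.
#' @return A `sig_set` tibble.
#' @export
sig_set <- function(profiles, scheme = NULL,
                    provenance = c("reference", "denovo", "decomposed"),
                    normalize = FALSE) {
  provenance <- match.arg(provenance)
  if (is.matrix(profiles)) {
    profiles <- dplyr::bind_cols(
      tibble::tibble(channel = rownames(profiles)),
      tibble::as_tibble(as.data.frame(profiles), .name_repair = "minimal")
    )
  }
  profiles <- tibble::as_tibble(profiles)
  if (is.null(scheme)) {
    scheme <- switch(as.character(nrow(profiles)),
      "96" = "SBS96", "78" = "DBS78", "83" = "ID83",
      stop("cannot infer channel scheme from ", nrow(profiles), " rows"))
  }
  labels <- channel_labels(scheme)
  if (!"channel" %in% names(profiles)) names(profiles)[1] <- "channel"
  if (!setequal(profiles$channel, labels))
    stop("channel labels do not match the ", scheme, " canonical list")
  profiles <- profiles[match(labels, profiles$channel), , drop = FALSE]
  sig_cols <- setdiff(names(profiles), "channel")
  if (length(sig_cols) == 0L) stop("a signature set needs at least one signature")
  m <- as.matrix(profiles[, sig_cols, drop = FALSE])
  if (any(m < 0)) stop("signature profiles must be non-negative")
  cs <- colSums(m)
  if (normalize) {
    if (any(cs <= 0)) stop("cannot normalize an all-zero signature column")
    m <- sweep(m, 2, cs, "/")
    profiles[sig_cols] <- tibble::as_tibble(as.data.frame(m), .name_repair = "minimal")
  } else if (any(abs(cs - 1) > 1e-8)) {
    stop("signature columns must sum to 1 (within 1e-8); use normalize = TRUE")
  }
  structure(profiles, class = c("sig_set", class(tibble::tibble()))) |>
    set_attr("scheme", scheme) |>
    set_attr("provenance", provenance)
}

#' Signature ids of a set
#' @param signatures A `sig_set`.
#' @return Character vector of signature ids.
#' @export
signature_ids <- function(signatures) setdiff(names(signatures), "channel")

#' Profiles matrix of a signature set
#' @param signatures A `sig_set`.
#' @return Numeric matrix, channels x signatures, channel row names.
#' @export
sig_matrix <- function(signatures) {
  m <- as.matrix(signatures[, signature_ids(signatures), drop = FALSE])
  rownames(m) <- signatures$channel
  m
}

#' Read / write reference signature tables
#'
#' COSMIC layout: first column the channel label, one column per signature.
#'
#' @param path TSV file.
#' @param scheme Channel scheme; inferred from the row count when `NULL`.
#' @param normalize Renormalize columns that do not sum exactly to 1.
#' @return `read_signatures()` returns a `sig_set`.
#' @export
read_signatures <- function(path, scheme = NULL, normalize = TRUE) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tbl)[1] <- "channel"
  sig_set(tbl, scheme = scheme, provenance = "reference", normalize = normalize)
}

#' @rdname read_signatures
#' @param signatures A `sig_set` to write.
#' @export
write_signatures <- function(signatures, path) {
  readr::write_tsv(tibble::as_tibble(signatures), path, progress = FALSE)
  invisible(path)
}

#' Cosine similarity between two profiles
#'
#' @param a,b Non-negative numeric vectors over the same channel ordering.
#' @return Similarity in `[0, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("cosine similarity is undefined for a zero vector")
  sum(a * b) / (na * nb)
}

cosine_matrix <- function(A, B) {
  An <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  Bn <- sweep(B, 2, sqrt(colSums(B^2)), "/")
  crossprod(An, Bn)
}

#' Match de novo signatures to a reference set
#'
#' Greedy one-to-one assignment in decreasing cosine-similarity order. Pairs
#' below `min_cosine` are left unmatched and flagged for decomposition.
#'
#' @param denovo,reference `sig_set` objects over the same channel scheme.
#' @param min_cosine Minimum cosine similarity to accept a match.
#' @return Tibble with `denovo_id`, `reference_id` (NA when unmatched),
#'   `cosine` and `matched`.
#' @export
match_to_reference <- function(denovo, reference, min_cosine = 0.85) {
  if (!identical(scheme_of(denovo), scheme_of(reference)))
    stop("channel scheme mismatch between de novo and reference sets")
  D <- sig_matrix(denovo)
  R <- sig_matrix(reference)
  sim <- cosine_matrix(D, R)
  res <- tibble::tibble(
    denovo_id = signature_ids(denovo),
    reference_id = NA_character_,
    cosine = NA_real_,
    matched = FALSE
  )
  free_d <- seq_len(nrow(sim))
  free_r <- seq_len(ncol(sim))
  while (length(free_d) > 0L && length(free_r) > 0L) {
    sub <- sim[free_d, free_r, drop = FALSE]
    best <- arrayInd(which.max(sub), dim(sub))
    val <- sub[best]
    if (val < min_cosine) break
    di <- free_d[best[1]]
    ri <- free_r[best[2]]
    res$reference_id[di] <- signature_ids(reference)[ri]
    res$cosine[di] <- val
    res$matched[di] <- TRUE
    free_d <- setdiff(free_d, di)
    free_r <- setdiff(free_r, ri)
  }
  # record the best achievable cosine for unmatched signatures
  for (di in which(!res$matched)) {
    res$cosine[di] <- max(sim[di, ])
  }
  res
}

nnls_fit <- function(A, b) {
  fit <- pracma::lsqnonneg(A, b)
  fit$x
}

#' Decompose a profile into reference components
#'
#' Non-negative least-squares fit of a single profile by the reference
#' columns; components with relative weight below `prune_threshold` are
#' removed and the remainder refit; the returned weights are renormalized to
#' sum to 1.
#'
#' @param profile Numeric column-stochastic profile over the reference's
#'   channel ordering.
#' @param reference A `sig_set`.
#' @param prune_threshold Minimum relative weight to keep a component.
#' @return Named numeric vector of weights over the reference signatures
#'   (zero for pruned components), summing to 1.
#' @export
decompose_to_reference <- function(profile, reference, prune_threshold = 0.01) {
  R <- sig_matrix(reference)
  stopifnot(length(profile) == nrow(R))
  ids <- signature_ids(reference)
  active <- seq_along(ids)
  repeat {
    w <- nnls_fit(R[, active, drop = FALSE], profile)
    rel <- if (sum(w) > 0) w / sum(w) else w
    low <- which(rel < prune_threshold)
    if (length(low) == 0L || length(active) == 1L) break
    active <- active[-low]
    if (length(active) == 0L) break
  }
  out <- stats::setNames(numeric(length(ids)), ids)
  if (length(active) > 0L && sum(w) > 0) out[active] <- w / sum(w)
  out
}
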