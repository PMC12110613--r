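# Exposure container and NNLS refitting of catalogs against a reference
# signature set.

new_sig_exposures <- function(sample_ids, sig_ids, absolute, scheme,
                              flagged = character(0)) {
  rel <- absolute
  rs <- rowSums(absolute)
  pos <- rs > 0
  rel[pos, ] <- absolute[pos, , drop = FALSE] / rs[pos]
  rel[!pos, ] <- 0
  as_tbl <- function(m) {
    out <- tibble::as_tibble(as.data.frame(m), .name_repair = "minimal")
    names(out) <- sig_ids
    dplyr::bind_cols(tibble::tibble(sample_id = sample_ids), out)
  }
  structure(list(
    absolute = as_tbl(absolute),
    relative = as_tbl(rel),
    sample_ids = sample_ids,
    signature_ids = sig_ids,
    scheme = scheme,
    flagged = flagged
  ), class = "sig_exposures")
}

#' @export
print.sig_exposures <- function(x, ...) {
  cat("<sig_exposures> ", length(x$sample_ids), " samples x ",
      length(x$signature_ids), " signatures (", x$scheme, ")\n", sep = "")
  if (length(x$flagged) > 0)
    cat("zero-burden samples:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

exposure_matrix <- function(exposures, which = c("relative", "absolute")) {
  which <- match.arg(which)
  m <- as.matrix(exposures[[which]][, exposures$signature_ids, drop = FALSE])
  rownames(m) <- exposures$sample_ids
  m
}

#' Refit signature exposures by non-negative least squares
#'
#' For each sample, the channel count vector is fit on the reference profiles
#' by NNLS; signatures with relative contribution below `prune_threshold` are
#' zeroed and the remainder refit until stable. Absolute exposures are scaled
#' so that each sample's row sum equals its mutation burden; relative
#' exposures are absolute divided by burden. Zero-burden samples get an
#' all-zero row and are flagged.
#'
#' @param catalog A `mut_catalog`.
#' @param reference A `sig_set` over the same channel scheme.
#' @param prune_threshold Minimum relative contribution to keep a signature
#'   active in a sample.
#' @return A `sig_exposures` object with `absolute` and `relative` tibbles.
#' @export
refit_exposures <- function(catalog, reference, prune_threshold = 0.01) {
  if (!identical(scheme_of(catalog), scheme_of(reference)))
    stop("channel scheme mismatch between catalog and reference")
  R <- sig_matrix(reference)
  ids <- signature_ids(reference)
  V <- catalog_matrix(catalog)
  n <- nrow(V)
  absolute <- matrix(0, n, length(ids), dimnames = list(NULL, ids))
  flagged <- character(0)
  for (i in seq_len(n)) {
    y <- V[i, ]
    burden <- sum(y)
    if (burden == 0) {
      flagged <- c(flagged, catalog$sample_id[i])
      next
    }
    active <- seq_along(ids)
    repeat {
      w <- nnls_fit(R[, active, drop = FALSE], y)
      if (sum(w) == 0) break
      rel <- w / sum(w)
      low <- which(rel < prune_threshold)
      if (length(low) == 0L || length(low) == length(active)) break
      active <- active[-low]
    }
    if (sum(w) > 0) {
      absolute[i, active] <- w * burden / sum(w)
    }
  }
  new_sig_exposures(catalog$sample_id, ids, absolute,
                    scheme = scheme_of(catalog), flagged = flagged)
}

#' Read / write exposure tables
#'
#' @param exposures A `sig_exposures`.
#' @param path_absolute,path_relative Output TSV paths (either may be NULL).
#' @return Invisibly, the paths written.
#' @export
write_exposures <- function(exposures, path_absolute = NULL,
                            path_relative = NULL) {
  if (!is.null(path_absolute))
    readr::write_tsv(exposures$absolute, path_absolute, progress = FALSE)
  if (!is.null(path_relative))
    readr::write_tsv(exposures$relative, path_relative, progress = FALSE)
  invisible(c(path_absolute, path_relative))
}
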