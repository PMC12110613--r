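# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a KL-NMF fit
#'
#' @param x A `sig_nmf`.
#' @param ... Unused.
#' @return Long tibble of exposures: `sample_id`, `signature`, `absolute`,
#'   `relative`.
#' @method tidy sig_nmf
#' @export
tidy.sig_nmf <- function(x, ...) {
  tidy.sig_exposures(x$exposures)
}

#' @rdname tidy.sig_nmf
#' @method glance sig_nmf
#' @export
glance.sig_nmf <- function(x, ...) {
  tibble::tibble(
    rank = x$rank, objective = x$objective, iterations = x$iterations,
    converged = x$converged, seed = x$seed
  )
}

#' Tidy an exposure matrix
#'
#' @param x A `sig_exposures`.
#' @param ... Unused.
#' @return Long tibble: `sample_id`, `signature`, `absolute`, `relative`.
#' @method tidy sig_exposures
#' @export
tidy.sig_exposures <- function(x, ...) {
  abs_long <- tidyr::pivot_longer(x$absolute, -"sample_id",
                                  names_to = "signature",
                                  values_to = "absolute")
  rel_long <- tidyr::pivot_longer(x$relative, -"sample_id",
                                  names_to = "signature",
                                  values_to = "relative")
  dplyr::left_join(abs_long, rel_long, by = c("sample_id", "signature"))
}

#' @rdname tidy.sig_exposures
#' @method glance sig_exposures
#' @export
glance.sig_exposures <- function(x, ...) {
  tibble::tibble(
    n_samples = length(x$sample_ids),
    n_signatures = length(x$signature_ids),
    scheme = x$scheme,
    n_zero_burden = length(x$flagged)
  )
}

#' Tidy a de novo extraction report
#'
#' @param x A `sig_extraction`.
#' @param ... Unused.
#' @return The per-rank stability table (`rank`, `silhouette`,
#'   `recon_error`).
#' @method tidy sig_extraction
#' @export
tidy.sig_extraction <- function(x, ...) x$rank_stats

#' @rdname tidy.sig_extraction
#' @method glance sig_extraction
#' @export
glance.sig_extraction <- function(x, ...) {
  sel <- x$rank_stats[x$rank_stats$rank == x$selected_rank, ]
  tibble::tibble(
    selected_rank = x$selected_rank,
    silhouette = sel$silhouette,
    recon_error = sel$recon_error,
    n_matched = if (is.null(x$matches)) NA_integer_ else sum(x$matches$matched)
  )
}
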