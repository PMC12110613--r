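# Mutation catalog container: one row per sample, one column per channel of a
# fixed scheme, stored as a tibble so catalogs compose with dplyr verbs.

new_mut_catalog <- function(tbl, scheme) {
  labels <- channel_labels(scheme)
  stopifnot(identical(names(tbl), c("sample_id", labels)))
  structure(tbl, class = c("mut_catalog", class(tibble::tibble()))) |>
    set_attr("scheme", scheme)
}

set_attr <- function(x, name, value) {
  attr(x, name) <- value
  x
}

#' Channel scheme of a catalog or signature set
#'
#' @param x A `mut_catalog` or `sig_set` object.
#' @return The scheme string, e.g. `"SBS96"`.
#' @export
scheme_of <- function(x) attr(x, "scheme")

#' Build a mutation catalog from classified records
#'
#' Counts the records of each sample falling into each channel of the chosen
#' scheme. Records of mutation kinds that do not belong to the scheme are
#' ignored; samples are ordered alphabetically and every canonical channel is
#' present as a column (zero where unobserved). Row sums equal the number of
#' classified records per sample (the sample's mutation burden for the
#' scheme).
#'
#' @param records Tibble of mutation records.
#' @param scheme Channel scheme (`"SBS96"`, `"DBS78"` or `"ID83"`).
#' @param sample_ids Optional character vector of sample ids to include as
#'   rows (all-zero when absent from `records`); defaults to the samples
#'   observed in `records`.
#' @return A `mut_catalog` tibble: `sample_id` plus one integer column per
#'   channel in canonical order.
#' @export
build_catalog <- function(records, scheme = c("SBS96", "DBS78", "ID83"),
                          sample_ids = NULL) {
  scheme <- match.arg(scheme)
  if (nrow(records) == 0L && is.null(sample_ids))
    stop("no records supplied and no sample_ids to tabulate")
  classified <- classify_mutations(records, scheme)
  labels <- channel_labels(scheme)
  ids <- sort(unique(c(classified$sample_id, sample_ids)))
  counts <- table(
    factor(classified$sample_id, levels = ids),
    factor(classified$channel, levels = labels)
  )
  tbl <- tibble::as_tibble(as.data.frame.matrix(counts), .name_repair = "minimal")
  tbl <- dplyr::mutate(tbl, dplyr::across(dplyr::everything(), as.integer))
  tbl <- dplyr::bind_cols(tibble::tibble(sample_id = ids), tbl)
  new_mut_catalog(tbl, scheme)
}

#' Extract the counts matrix of a catalog
#'
#' @param catalog A `mut_catalog`.
#' @return Integer matrix, samples x channels, with sample ids as row names.
#' @export
catalog_matrix <- function(catalog) {
  m <- as.matrix(catalog[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- catalog$sample_id
  m
}

#' Tumor mutational burden per sample
#'
#' Row sums of a catalog: the number of classified mutations of the
#' catalog's scheme per sample.
#'
#' @param catalog A `mut_catalog`.
#' @return Tibble with `sample_id` and `tmb`.
#' @export
tmb <- function(catalog) {
  tibble::tibble(
    sample_id = catalog$sample_id,
    tmb = as.integer(rowSums(catalog_matrix(catalog)))
  )
}

#' Read / write a catalog in COSMIC layout
#'
#' The on-disk layout is the one used by COSMIC-style signature tables:
#' first column the channel label (canonical order), one column per sample.
#'
#' @param path TSV file path.
#' @param scheme Channel scheme; inferred from the number of rows when `NULL`.
#' @return `read_catalog()` returns a `mut_catalog`; `write_catalog()` its
#'   `path`, invisibly.
#' @export
read_catalog <- function(path, scheme = NULL) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (is.null(scheme)) {
    scheme <- switch(as.character(nrow(tbl)),
      "96" = "SBS96", "78" = "DBS78", "83" = "ID83",
      stop("cannot infer channel scheme from ", nrow(tbl), " rows"))
  }
  labels <- channel_labels(scheme)
  chan <- tbl[[1]]
  if (!setequal(chan, labels))
    stop("channel labels do not match the ", scheme, " canonical list")
  tbl <- tbl[match(labels, chan), , drop = FALSE]
  samples <- names(tbl)[-1]
  m <- t(as.matrix(tbl[, -1, drop = FALSE]))
  out <- tibble::as_tibble(as.data.frame(m), .name_repair = "minimal")
  names(out) <- labels
  out <- dplyr::mutate(out, dplyr::across(dplyr::everything(), as.integer))
  out <- dplyr::bind_cols(tibble::tibble(sample_id = samples), out)
  out <- dplyr::arrange(out, .data$sample_id)
  new_mut_catalog(out, scheme)
}

#' @rdname read_catalog
#' @param catalog A `mut_catalog` to write.
#' @export
write_catalog <- function(catalog, path) {
  labels <- channel_labels(scheme_of(catalog))
  m <- t(catalog_matrix(catalog))
  out <- dplyr::bind_cols(
    tibble::tibble(MutationType = labels),
    tibble::as_tibble(as.data.frame(m), .name_repair = "minimal")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @export
print.mut_catalog <- function(x, ...) {
  cat("<mut_catalog> ", scheme_of(x), ": ", nrow(x), " samples x ",
      ncol(x) - 1L, " channels\n", sep = "")
  NextMethod()
}
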