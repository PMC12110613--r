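# ggplot2 graphics for catalogs, signatures, exposures and interactions.

sbs_class_of <- function(channel) substr(channel, 3, 5)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot signature profiles
#'
#' Bar profile per signature; SBS96 channels are colored by substitution
#' class.
#'
#' @param object A `sig_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sig_set
#' @export
autoplot.sig_set <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"channel",
                              names_to = "signature", values_to = "probability")
  long$channel <- factor(long$channel, levels = object$channel)
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = .data$channel, y = .data$probability))
  if (identical(scheme_of(object), "SBS96")) {
    long$class <- sbs_class_of(as.character(long$channel))
    p <- ggplot2::ggplot(long,
                         ggplot2::aes(x = .data$channel, y = .data$probability,
                                      fill = .data$class))
  }
  p +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~signature, ncol = 1, scales = "free_y") +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 4)) +
    ggplot2::labs(x = NULL, y = "probability")
}

#' Plot relative signature contributions per sample
#'
#' Stacked bars of relative exposures (samples ordered as given).
#'
#' @param object A `sig_exposures`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sig_exposures
#' @export
autoplot.sig_exposures <- function(object, ...) {
  long <- tidyr::pivot_longer(object$relative, -"sample_id",
                              names_to = "signature",
                              values_to = "contribution")
  long$sample_id <- factor(long$sample_id, levels = object$sample_ids)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id,
                                     y = .data$contribution,
                                     fill = .data$signature)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank()) +
    ggplot2::labs(x = "sample", y = "relative contribution")
}

#' Interaction heatmap (co-occurrence red, exclusivity blue)
#'
#' Symmetric matrix of signature pairs: red cells are significantly
#' co-occurring, blue cells mutually exclusive, intensity is `-log10(q)`;
#' non-significant and untestable pairs are blank.
#'
#' @param object A `sig_interactions` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sig_interactions
#' @export
autoplot.sig_interactions <- function(object, ...) {
  groups <- sort(unique(c(object$group_a, object$group_b)))
  res <- tibble::as_tibble(object)
  sym <- dplyr::bind_rows(
    res,
    dplyr::rename(res, group_a = "group_b", group_b = "group_a")
  )
  sym$signal <- dplyr::case_when(
    sym$direction == "co-occurring" ~ -log10(pmax(sym$q, 1e-300)),
    sym$direction == "exclusive"    ~ log10(pmax(sym$q, 1e-300)),
    TRUE                            ~ NA_real_
  )
  sym$group_a <- factor(sym$group_a, levels = groups)
  sym$group_b <- factor(sym$group_b, levels = groups)
  ggplot2::ggplot(sym, ggplot2::aes(x = .data$group_a, y = .data$group_b,
                                    fill = .data$signal)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  midpoint = 0, na.value = "white",
                                  name = expression(-log[10](q))) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Render the interaction heatmap to a figure file
#'
#' @param results A `sig_interactions` tibble.
#' @param path Output figure file (extension selects the device, e.g.
#'   `.pdf` or `.png`).
#' @param width,height Figure size in inches.
#' @return The ggplot object, invisibly; the file is written when `path` is
#'   given.
#' @export
render_interaction_heatmap <- function(results, path = NULL,
                                       width = 6, height = 5) {
  stopifnot(nrow(results) > 0)
  p <- autoplot.sig_interactions(results)
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = width, height = height)
  }
  invisible(p)
}

#' Kernel density curves of group contributions
#'
#' One density curve per signature group, computed on samples with nonzero
#' contribution (the distribution of the signature where it is observed).
#'
#' @param contributions Tibble from [relative_contributions()].
#' @param groups Groups to draw; defaults to every group with at least two
#'   distinct nonzero values.
#' @return A ggplot object.
#' @export
plot_density_curves <- function(contributions, groups = NULL) {
  all_groups <- setdiff(names(contributions), "sample_id")
  if (is.null(groups)) {
    groups <- all_groups[vapply(all_groups, function(g) {
      v <- contributions[[g]]
      length(unique(v[v > 0])) >= 2L
    }, logical(1))]
  }
  curves <- purrr::map_dfr(groups, function(g) {
    v <- contributions[[g]]
    dplyr::mutate(kernel_density(v[v > 0]), group = g)
  })
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$x, y = .data$density,
                                       color = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::labs(x = "relative contribution", y = "density")
}
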