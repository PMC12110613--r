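# Per-sample signature descriptors: etiology grouping of signatures,
# relative contributions, presence calls, dominant signatures and the sample
# signature group.

#' Default etiology grouping of signatures
#'
#' Maps signature ids to etiology group labels: APOBEC (SBS2, SBS13),
#' HRd (SBS3), HRd-ID (ID6), MMRd (SBS26, SBS44, DBS7), BERd (SBS30, SBS36),
#' ROS (SBS18), NHEJd (ID8), Aging (SBS1), SBS5, cAID (SBS85), ncAID (SBS9).
#' Signatures without a group map to themselves.
#'
#' @return Tibble with columns `signature` and `group`.
#' @export
default_signature_groups <- function() {
  groups <- list(
    APOBEC   = c("SBS2", "SBS13"),
    HRd      = "SBS3",
    `HRd-ID` = "ID6",
    MMRd     = c("SBS26", "SBS44", "DBS7"),
    BERd     = c("SBS30", "SBS36"),
    ROS      = "SBS18",
    NHEJd    = "ID8",
    Aging    = "SBS1",
    SBS5     = "SBS5",
    cAID     = "SBS85",
    ncAID    = "SBS9"
  )
  tibble::tibble(
    signature = unlist(groups, use.names = FALSE),
    group = rep(names(groups), lengths(groups))
  )
}

complete_grouping <- function(signatures, grouping) {
  missing <- setdiff(signatures, grouping$signature)
  dplyr::bind_rows(
    grouping,
    tibble::tibble(signature = missing, group = missing)
  )
}

#' Relative contributions pooled by signature group
#'
#' Sums the relative exposures of each group's member signatures per sample.
#' Rows of samples with positive burden keep their row sum (1).
#'
#' @param exposures A `sig_exposures`.
#' @param grouping Tibble with `signature` and `group` columns; defaults to
#'   [default_signature_groups()]. Ungrouped signatures map to themselves.
#' @return Tibble: `sample_id` plus one numeric column per group.
#' @export
relative_contributions <- function(exposures, grouping = default_signature_groups()) {
  grouping <- complete_grouping(exposures$signature_ids, grouping)
  long <- tidyr::pivot_longer(exposures$relative, -"sample_id",
                              names_to = "signature", values_to = "contribution")
  long <- dplyr::left_join(long, grouping, by = "signature")
  out <- long |>
    dplyr::group_by(.data$sample_id, .data$group) |>
    dplyr::summarise(contribution = sum(.data$contribution), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group", values_from = "contribution")
  # deterministic ordering: samples as in the exposures, groups alphabetical
  out <- out[match(exposures$sample_ids, out$sample_id),
             c("sample_id", sort(setdiff(names(out), "sample_id")))]
  out
}

#' Call signature-group presence
#'
#' A group is present in a sample when its relative contribution is at or
#' above `threshold` (inclusive) and the attributed mutation count
#' (contribution x burden) is at least `min_mutations`.
#'
#' @param contributions Tibble from [relative_contributions()].
#' @param burdens Tibble with `sample_id` and `tmb`, as from [tmb()].
#' @param threshold Relative-contribution detection floor, in (0, 1).
#' @param min_mutations Minimum attributed mutations.
#' @return Tibble: `sample_id` plus one 0/1 integer column per group.
#' @export
call_presence <- function(contributions, burdens, threshold = 0.05,
                          min_mutations = 10L) {
  stopifnot(threshold > 0, threshold < 1)
  b <- burdens$tmb[match(contributions$sample_id, burdens$sample_id)]
  if (anyNA(b)) stop("burdens are missing for some samples")
  groups <- setdiff(names(contributions), "sample_id")
  out <- contributions
  for (g in groups) {
    out[[g]] <- as.integer(contributions[[g]] >= threshold &
                             contributions[[g]] * b >= min_mutations)
  }
  out
}

#' First and second dominant signature groups per sample
#'
#' The first dominant group has the maximal relative contribution, the
#' second the next largest; ties are broken lexicographically by group label.
#' The second dominant is `NA` when fewer than two groups have nonzero
#' contribution; samples with no nonzero group (zero burden) get `NA` for
#' both and are flagged in the `flagged` attribute.
#'
#' @param contributions Tibble from [relative_contributions()].
#' @return Tibble with `sample_id`, `first_dominant`, `second_dominant`.
#' @export
dominant_signatures <- function(contributions) {
  groups <- sort(setdiff(names(contributions), "sample_id"))
  m <- as.matrix(contributions[, groups, drop = FALSE])
  first <- second <- rep(NA_character_, nrow(m))
  for (i in seq_len(nrow(m))) {
    v <- m[i, ]
    ord <- order(-v, groups)   # ties -> lexicographic by label
    nz <- sum(v > 0)
    if (nz >= 1L) first[i] <- groups[ord[1]]
    if (nz >= 2L) second[i] <- groups[ord[2]]
  }
  out <- tibble::tibble(
    sample_id = contributions$sample_id,
    first_dominant = first,
    second_dominant = second
  )
  attr(out, "flagged") <- contributions$sample_id[is.na(first)]
  out
}

#' Assign the sample signature group from its dominant signatures
#'
#' A sample is labeled `"Others"` only when no non-clock-like group (neither
#' Aging/SBS1 nor SBS5) is among its dominant signatures; otherwise the
#' strongest non-clock-like dominant names the group.
#'
#' @param first,second Character vectors of first / second dominant group
#'   labels (`second` may be `NA`).
#' @return Character vector of sample signature-group labels.
#' @examples
#' assign_signature_group("SBS5", "Aging")   # "Others"
#' assign_signature_group("HRd", "SBS5")     # "HRd"
#' assign_signature_group("SBS5", "APOBEC")  # "APOBEC"
#' @export
assign_signature_group <- function(first, second) {
  clock <- c("Aging", "SBS5")
  dplyr::case_when(
    is.na(first)                                   ~ NA_character_,
    !first %in% clock                              ~ first,
    !is.na(second) & !second %in% clock            ~ second,
    TRUE                                           ~ "Others"
  )
}

#' Per-sample signature profile table
#'
#' Convenience orchestrator combining contributions, presence calls,
#' dominant signatures, the sample signature group and mutation burden into
#' one tibble.
#'
#' @param exposures A `sig_exposures`.
#' @param catalog The `mut_catalog` the exposures were fit on (for burdens).
#' @param grouping Signature grouping tibble.
#' @param threshold,min_mutations Passed to [call_presence()].
#' @return Tibble with one row per sample: `sample_id`, `tmb`,
#'   `first_dominant`, `second_dominant`, `signature_group`, plus the group
#'   contribution columns. The presence matrix is attached as the
#'   `presence` attribute.
#' @export
sample_profiles <- function(exposures, catalog,
                            grouping = default_signature_groups(),
                            threshold = 0.05, min_mutations = 10L) {
  contributions <- relative_contributions(exposures, grouping)
  burdens <- tmb(catalog)
  presence <- call_presence(contributions, burdens, threshold, min_mutations)
  dominants <- dominant_signatures(contributions)
  out <- dominants |>
    dplyr::mutate(signature_group = assign_signature_group(
      .data$first_dominant, .data$second_dominant)) |>
    dplyr::left_join(burdens, by = "sample_id") |>
    dplyr::left_join(contributions, by = "sample_id")
  attr(out, "presence") <- presence
  out
}
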