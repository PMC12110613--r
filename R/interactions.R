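# Pairwise co-occurrence / mutual-exclusivity analysis of signature presence
# via the exact hypergeometric test.

#' Exact hypergeometric tail probabilities for a presence overlap
#'
#' With `X ~ hypergeometric(N, n_a, n_b)` (the overlap of two independent
#' presence sets of sizes `n_a`, `n_b` drawn from `N` samples), returns the
#' co-occurrence tail `p_co = P(X >= k)` and the exclusivity tail
#' `p_ex = P(X <= k)`. The observed mass `P(X = k)` is included in both
#' tails, so `p_co + p_ex >= 1`.
#'
#' @param N Cohort size.
#' @param n_a,n_b Marginal presence counts.
#' @param k Observed overlap, in `[max(0, n_a + n_b - N), min(n_a, n_b)]`.
#' @return Tibble with `p_co` and `p_ex` (NA with an `untestable` flag when a
#'   margin is zero).
#' @examples
#' hypergeom_tails(10, 5, 5, 5)  # p_co = 1/252
#' @export
hypergeom_tails <- function(N, n_a, n_b, k) {
  len <- max(length(N), length(n_a), length(n_b), length(k))
  N <- rep_len(N, len); n_a <- rep_len(n_a, len)
  n_b <- rep_len(n_b, len); k <- rep_len(k, len)
  if (any(n_a < 0 | n_b < 0 | n_a > N | n_b > N))
    stop("margins must satisfy 0 <= n_a, n_b <= N")
  if (any(k < pmax(0, n_a + n_b - N) | k > pmin(n_a, n_b)))
    stop("overlap k outside its feasible range")
  untestable <- n_a == 0 | n_b == 0
  p_co <- ifelse(untestable, NA_real_,
                 stats::phyper(k - 1, n_a, N - n_a, n_b, lower.tail = FALSE))
  p_ex <- ifelse(untestable, NA_real_,
                 stats::phyper(k, n_a, N - n_a, n_b))
  tibble::tibble(p_co = p_co, p_ex = p_ex, untestable = untestable)
}

#' Adjust p-values for multiple testing
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` (Benjamini-Hochberg step-up) or `"none"`
#'   (pass-through).
#' @return Adjusted q-values, order preserving.
#' @export
adjust_pvalues <- function(p, method = c("BH", "none")) {
  method <- match.arg(method)
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  stats::p.adjust(p, method = if (method == "none") "none" else "BH")
}

#' Pairwise signature interaction tests
#'
#' Tests every unordered pair of presence columns with the exact
#' hypergeometric test. The smaller one-sided tail defines the candidate
#' direction; significance is judged on the two-tailed p-value
#' `p_two = min(1, 2 * min(p_co, p_ex))` adjusted across all testable pairs,
#' and the direction is set when `q <= alpha`. Pairs with a zero margin are
#' reported as untestable rather than given p = 1.
#'
#' @param presence Tibble: `sample_id` plus one 0/1 column per group.
#' @param alpha Significance level on the adjusted two-tailed p-value.
#' @param adjust Multiple-testing adjustment (`"BH"` or `"none"`).
#' @return A `sig_interactions` tibble with one row per pair: `group_a`,
#'   `group_b`, `n`, `n_a`, `n_b`, `k`, `p_co`, `p_ex`, `p_two`, `q`,
#'   `direction` (`"co-occurring"`, `"exclusive"`, `"none"`) and `testable`.
#' @export
interaction_matrix <- function(presence, alpha = 0.05,
                               adjust = c("BH", "none")) {
  adjust <- match.arg(adjust)
  groups <- setdiff(names(presence), "sample_id")
  if (length(groups) < 2L) stop("at least two presence columns are required")
  m <- as.matrix(presence[, groups, drop = FALSE])
  if (!all(m %in% c(0, 1))) stop("presence entries must be 0/1")
  N <- nrow(m)
  pairs <- utils::combn(groups, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    n_a <- sum(m[, a]); n_b <- sum(m[, b]); k <- sum(m[, a] & m[, b])
    tails <- hypergeom_tails(N, n_a, n_b, k)
    tibble::tibble(
      group_a = a, group_b = b, n = N, n_a = n_a, n_b = n_b, k = k,
      p_co = tails$p_co, p_ex = tails$p_ex,
      testable = !tails$untestable
    )
  })
  res$p_two <- pmin(1, 2 * pmin(res$p_co, res$p_ex))
  res$q <- NA_real_
  res$q[res$testable] <- adjust_pvalues(res$p_two[res$testable], adjust)
  res$direction <- dplyr::case_when(
    !res$testable | res$q > alpha         ~ "none",
    res$p_co < res$p_ex                   ~ "co-occurring",
    res$p_ex < res$p_co                   ~ "exclusive",
    TRUE                                  ~ "none"
  )
  structure(res, class = c("sig_interactions", class(tibble::tibble())),
            alpha = alpha, adjust = adjust)
}

#' Permutation / enumeration oracle for a presence pair
#'
#' Recomputes the overlap null distribution of one pair by uniformly
#' re-placing the `n_b` present samples of the second group among the `N`
#' samples while holding the first group fixed. For small cohorts
#' (`choose(N, n_b) <= exhaustive_limit`) every placement is enumerated and
#' the tails are exact; otherwise `n_perm` seeded random placements give an
#' empirical two-tail estimate (with the +1 continuity correction).
#'
#' @param presence Presence tibble.
#' @param pair Character vector of the two group names.
#' @param n_perm Number of random placements when sampling.
#' @param seed Integer seed.
#' @param exhaustive_limit Maximum number of placements enumerated exactly.
#' @return Tibble with `p_co`, `p_ex`, `p_two` and `method`
#'   (`"exhaustive"` or `"sampling"`).
#' @export
permutation_oracle <- function(presence, pair, n_perm = 1e5, seed = 1L,
                               exhaustive_limit = 1e4) {
  stopifnot(length(pair) == 2L, all(pair %in% names(presence)))
  a <- presence[[pair[1]]]
  b <- presence[[pair[2]]]
  N <- length(a)
  n_b <- sum(b)
  k_obs <- sum(a & b)
  if (sum(a) == 0 || n_b == 0) stop("pair must have nonzero margins")
  if (choose(N, n_b) <= exhaustive_limit) {
    placements <- utils::combn(N, n_b)
    overlaps <- apply(placements, 2, function(idx) sum(a[idx]))
    p_co <- mean(overlaps >= k_obs)
    p_ex <- mean(overlaps <= k_obs)
    method <- "exhaustive"
  } else {
    overlaps <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(i) sum(a[sample.int(N, n_b)]), numeric(1))
    })
    # add-one correction keeps the estimate a valid p-value
    p_co <- (sum(overlaps >= k_obs) + 1) / (n_perm + 1)
    p_ex <- (sum(overlaps <= k_obs) + 1) / (n_perm + 1)
    method <- "sampling"
  }
  tibble::tibble(p_co = p_co, p_ex = p_ex,
                 p_two = min(1, 2 * min(p_co, p_ex)), method = method)
}
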