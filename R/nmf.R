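# De novo signature extraction: Kullback-Leibler NMF by multiplicative
# updates, bootstrap stability analysis, consensus clustering and
# silhouette-based rank selection.

# Deterministic sub-seed derivation: one user seed fans out to every RNG use
# through a Lehmer-style counter, keeping derived seeds below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed %% 2147483647L) * 48271 + k) %% 2147483647)
}

kl_divergence <- function(V, WH, eps = 1e-12) {
  pos <- V > 0
  sum(V[pos] * log(V[pos] / pmax(WH[pos], eps))) - sum(V) + sum(WH)
}

#' Factorize a mutation catalog by KL non-negative matrix factorization
#'
#' Minimizes the generalized Kullback-Leibler divergence (Poisson likelihood)
#' between the catalog counts and the product of signature profiles and
#' exposures, by multiplicative updates. Profiles are column-normalized with
#' the norm absorbed into the exposures; the objective is non-increasing over
#' iterations and the result is deterministic for a fixed seed.
#'
#' @param catalog A `mut_catalog` with at least one nonzero row.
#' @param rank Number of signatures, between 1 and `min(samples, channels)`.
#' @param seed Integer seed for the random uniform initialization.
#' @param max_iter Maximum multiplicative-update iterations.
#' @param tol Stop when the relative objective change over a check interval
#'   falls below this value.
#' @return A `sig_nmf` object: list with `signatures` (a [sig_set()]),
#'   `exposures` (a `sig_exposures`), `objective` (final KL divergence),
#'   `objective_trace`, `iterations`, `converged`, `rank`, `seed`.
#' @export
nmf_factorize <- function(catalog, rank, seed = 1L, max_iter = 10000L,
                          tol = 1e-9) {
  V <- t(catalog_matrix(catalog))  # channels x samples
  if (sum(V) == 0) stop("degenerate input: all-zero catalog")
  if (rank < 1L || rank > min(dim(V)))
    stop("rank must be between 1 and min(samples, channels)")
  m <- nrow(V); n <- ncol(V)
  eps <- 1e-12
  init <- withr::with_seed(seed, list(
    W = matrix(stats::runif(m * rank, 0.1, 1), m, rank),
    H = matrix(stats::runif(rank * n, 0.1, 1), rank, n)
  ))
  W <- init$W; H <- init$H
  trace <- numeric(0)
  obj_prev <- Inf
  converged <- FALSE
  it <- 0L
  check_every <- 10L
  while (it < max_iter) {
    it <- it + 1L
    WH <- W %*% H
    H <- H * (crossprod(W, V / pmax(WH, eps))) / pmax(colSums(W), eps)
    WH <- W %*% H
    W <- W * ((V / pmax(WH, eps)) %*% t(H)) /
      matrix(pmax(rowSums(H), eps), m, rank, byrow = TRUE)
    if (it %% check_every == 0L || it == max_iter) {
      obj <- kl_divergence(V, W %*% H, eps)
      trace <- c(trace, obj)
      if (is.finite(obj_prev) &&
          abs(obj_prev - obj) <= tol * max(abs(obj_prev), 1)) {
        converged <- TRUE
        break
      }
      obj_prev <- obj
    }
  }
  norms <- colSums(W)
  norms[norms == 0] <- 1
  W <- sweep(W, 2, norms, "/")
  H <- H * norms
  ids <- paste0(sub("[0-9]+$", "", scheme_of(catalog)), LETTERS[seq_len(rank)])
  rownames(W) <- channel_labels(scheme_of(catalog))
  colnames(W) <- ids
  signatures <- sig_set(W, scheme = scheme_of(catalog), provenance = "denovo",
                        normalize = TRUE)
  abs_exp <- t(H)
  colnames(abs_exp) <- ids
  exposures <- new_sig_exposures(catalog$sample_id, ids, abs_exp,
                                 scheme = scheme_of(catalog))
  structure(list(
    signatures = signatures,
    exposures = exposures,
    objective = kl_divergence(V, sweep(W, 2, norms, "*") %*% sweep(H, 1, norms, "/"), eps),
    objective_trace = trace,
    iterations = it,
    converged = converged,
    rank = rank,
    seed = seed
  ), class = "sig_nmf")
}

#' @export
print.sig_nmf <- function(x, ...) {
  cat("<sig_nmf> rank", x$rank, "| KL objective", format(x$objective),
      "|", x$iterations, "iterations",
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  invisible(x)
}

# mean silhouette width under cosine distance; for a single cluster the
# neighbor-cluster term is undefined and cohesion to the medoid is reported
# instead (1 = perfectly tight).
cosine_silhouette <- function(D, clusters) {
  k <- length(unique(clusters))
  n <- length(clusters)
  if (k == 1L) {
    med <- which.min(colSums(D))
    return(1 - 2 * mean(D[, med]))
  }
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- clusters == clusters[i]
    a <- if (sum(own) > 1L) sum(D[i, own]) / (sum(own) - 1L) else 0
    b <- min(vapply(setdiff(unique(clusters), clusters[i]), function(cl) {
      mean(D[i, clusters == cl])
    }, numeric(1)))
    s[i] <- if (sum(own) > 1L) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# One-to-one consensus clustering of pooled factorization solutions: every
# solution contributes exactly one signature to each of the `rank` clusters
# (greedy cosine matching to running centroids, iterated to a fixed point).
# The constraint concentrates run-to-run instability into its own cluster,
# which is what makes the silhouette drop once the rank exceeds the number
# of reproducible signatures.
consensus_cluster <- function(P, rank, n_solutions, max_iter = 100L) {
  sol <- rep(seq_len(n_solutions), each = rank)
  centroids <- P[, seq_len(rank), drop = FALSE]
  cl <- integer(ncol(P))
  for (it in seq_len(max_iter)) {
    old <- cl
    for (s in seq_len(n_solutions)) {
      idx <- which(sol == s)
      sim <- cosine_matrix(P[, idx, drop = FALSE], centroids)
      free_i <- seq_len(rank)
      free_c <- seq_len(rank)
      while (length(free_i) > 0L) {
        sub <- sim[free_i, free_c, drop = FALSE]
        best <- arrayInd(which.max(sub), dim(sub))
        cl[idx[free_i[best[1]]]] <- free_c[best[2]]
        free_i <- free_i[-best[1]]
        free_c <- free_c[-best[2]]
      }
    }
    for (k in seq_len(rank)) {
      m <- rowMeans(P[, cl == k, drop = FALSE])
      centroids[, k] <- m / sum(m)
    }
    if (identical(cl, old)) break
  }
  cl
}

bootstrap_catalog <- function(catalog, seed) {
  m <- catalog_matrix(catalog)
  withr::with_seed(seed, {
    for (i in seq_len(nrow(m))) {
      burden <- sum(m[i, ])
      if (burden > 0) {
        m[i, ] <- as.vector(stats::rmultinom(1, burden, m[i, ] / burden))
      }
    }
  })
  tbl <- dplyr::bind_cols(
    tibble::tibble(sample_id = catalog$sample_id),
    tibble::as_tibble(as.data.frame(m), .name_repair = "minimal")
  )
  names(tbl) <- c("sample_id", channel_labels(scheme_of(catalog)))
  new_mut_catalog(tbl, scheme_of(catalog))
}

#' De novo signature extraction with bootstrap stability
#'
#' For each candidate rank, per-sample multinomial bootstrap replicates of
#' the catalog (replicate 1 is the original catalog) are each factorized with
#' multiple random restarts; every solution's signatures are pooled and
#' partitioned into `rank` clusters by cosine distance under the constraint
#' that each solution contributes exactly one signature per cluster.
#' Consensus signatures are the normalized cluster medoids and stability is
#' the mean silhouette width under cosine distance. The final rank is chosen
#' by [select_rank()].
#'
#' @param catalog A `mut_catalog`.
#' @param rank_range Integer vector of candidate ranks.
#' @param n_restarts Random restarts per factorization.
#' @param n_bootstraps Bootstrap replicates per rank.
#' @param seed Integer seed; all randomness derives from it.
#' @param reference Optional `sig_set`; when given, consensus signatures are
#'   matched to it with [match_to_reference()].
#' @param min_cosine Matching threshold passed to [match_to_reference()].
#' @param max_iter,tol Passed to [nmf_factorize()].
#' @return A `sig_extraction` object: list with `rank_stats` (tibble of rank,
#'   silhouette, mean reconstruction error), `selected_rank`, `consensus`
#'   (a `sig_set` at the selected rank), `consensus_by_rank`, and `matches`
#'   (tibble or NULL).
#' @export
extract_denovo <- function(catalog, rank_range, n_restarts = 20L,
                           n_bootstraps = 30L, seed = 1L, reference = NULL,
                           min_cosine = 0.85, max_iter = 10000L, tol = 1e-9) {
  rank_range <- sort(unique(as.integer(rank_range)))
  if (length(rank_range) == 0L) stop("rank_range must contain at least one rank")
  if (n_bootstraps < 1L) stop("n_bootstraps must be >= 1")
  stats_list <- list()
  consensus_by_rank <- list()
  for (rank in rank_range) {
    pool <- list()
    errors <- numeric(0)
    for (b in seq_len(n_bootstraps)) {
      boot_cat <- if (b == 1L) catalog else {
        bootstrap_catalog(catalog, derive_seed(seed, rank * 100000L + b))
      }
      for (r in seq_len(n_restarts)) {
        fit <- nmf_factorize(
          boot_cat, rank,
          seed = derive_seed(seed, rank * 1000000L + b * 1000L + r),
          max_iter = max_iter, tol = tol)
        pool[[length(pool) + 1L]] <- sig_matrix(fit$signatures)
        errors <- c(errors, fit$objective)
      }
    }
    P <- do.call(cbind, pool)
    clusters <- if (rank == 1L) rep(1L, ncol(P)) else {
      consensus_cluster(P, rank, length(pool))
    }
    D <- 1 - cosine_matrix(P, P)
    sil <- cosine_silhouette(D, clusters)
    medoids <- vapply(sort(unique(clusters)), function(cl) {
      members <- which(clusters == cl)
      members[which.min(colSums(D[members, members, drop = FALSE]))]
    }, integer(1))
    cons <- P[, medoids, drop = FALSE]
    cons <- sweep(cons, 2, colSums(cons), "/")
    colnames(cons) <- paste0(sub("[0-9]+$", "", scheme_of(catalog)),
                             LETTERS[seq_len(rank)])
    rownames(cons) <- channel_labels(scheme_of(catalog))
    consensus_by_rank[[as.character(rank)]] <-
      sig_set(cons, scheme = scheme_of(catalog), provenance = "denovo",
              normalize = TRUE)
    stats_list[[as.character(rank)]] <- tibble::tibble(
      rank = rank, silhouette = sil, recon_error = mean(errors)
    )
  }
  rank_stats <- dplyr::bind_rows(stats_list)
  selected <- select_rank(rank_stats)
  consensus <- consensus_by_rank[[as.character(selected)]]
  matches <- NULL
  if (!is.null(reference)) {
    matches <- match_to_reference(consensus, reference, min_cosine = min_cosine)
  }
  structure(list(
    rank_stats = rank_stats,
    selected_rank = selected,
    consensus = consensus,
    consensus_by_rank = consensus_by_rank,
    matches = matches,
    seed = seed
  ), class = "sig_extraction")
}

#' Select the factorization rank from stability statistics
#'
#' Returns the largest rank with mean silhouette at or above `threshold`;
#' when none qualifies, the rank maximizing the silhouette (ties broken
#' toward the smaller rank).
#'
#' @param rank_stats Tibble with columns `rank` and `silhouette`.
#' @param threshold Silhouette stability threshold.
#' @return The selected rank (integer).
#' @export
select_rank <- function(rank_stats, threshold = 0.8) {
  stopifnot(nrow(rank_stats) >= 1L)
  ok <- rank_stats$silhouette >= threshold
  if (any(ok)) return(max(rank_stats$rank[ok]))
  best <- max(rank_stats$silhouette)
  min(rank_stats$rank[rank_stats$silhouette == best])
}

#' @export
print.sig_extraction <- function(x, ...) {
  cat("<sig_extraction> selected rank", x$selected_rank, "\n")
  print(x$rank_stats)
  invisible(x)
}
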