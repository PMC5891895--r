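#' Channel adjacency from sensor positions
#'
#' Channels are neighbors when their Euclidean distance does not exceed a
#' threshold. When no threshold is supplied it is set to the median
#' `target_degree`-th nearest-neighbor distance, which yields a median
#' neighbor count close to `target_degree` (dense-array convention).
#'
#' @param positions matrix n x 3, row-named by channel.
#' @param threshold distance threshold; `NULL` to derive from
#'   `target_degree`.
#' @param target_degree desired median neighbor count.
#' @return list of class `adjacency_graph`: `labels`, `neighbors` (list of
#'   integer vectors), `threshold`.
#' @export
build_adjacency <- function(positions, threshold = NULL, target_degree = 6L) {
  stopifnot(is.matrix(positions), nrow(positions) >= 2)
  d <- as.matrix(dist(positions))
  if (is.null(threshold)) {
    kth <- apply(d, 1, function(r) sort(r[r > 0])[min(target_degree, nrow(d) - 1L)])
    threshold <- median(kth)
  }
  nb <- lapply(seq_len(nrow(d)), function(i) {
    which(d[i, ] <= threshold & seq_len(ncol(d)) != i)
  })
  structure(list(labels = rownames(positions), neighbors = nb,
                 threshold = threshold),
            class = "adjacency_graph")
}

#' Paired t statistics per channel
#'
#' Dependent-sample t over subjects for every channel. A channel with zero
#' variance of the paired differences receives a large sentinel value with
#' the sign of the mean difference (0 when the mean is also 0), with a
#' warning.
#'
#' @param a,b subject x channel matrices of the two conditions (same order).
#' @return numeric vector of t values, one per channel.
#' @export
paired_t_map <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)), nrow(a) >= 2)
  d <- a - b
  n <- nrow(d)
  m <- colMeans(d)
  s <- sqrt(colSums(sweep(d, 2, m)^2) / (n - 1))
  t <- m / (s / sqrt(n))
  degenerate <- s == 0
  if (any(degenerate)) {
    warning(sprintf("%d channel(s) with zero-variance differences; sentinel t assigned",
                    sum(degenerate)))
    t[degenerate] <- sign(m[degenerate]) * 1e10
  }
  t
}

# max cluster mass (|summed t|) among supra-threshold channels, signs
# clustered separately
max_cluster_mass <- function(t, crit, neighbors) {
  m <- 0
  pos <- which(t > crit)
  if (length(pos)) {
    for (comp in connected_components(pos, neighbors))
      m <- max(m, sum(t[comp]))
  }
  neg <- which(t < -crit)
  if (length(neg)) {
    for (comp in connected_components(neg, neighbors))
      m <- max(m, -sum(t[comp]))
  }
  m
}

#' Cluster-based permutation test for paired topographies
#'
#' Channels whose paired t exceeds the two-tailed critical value at
#' `alpha_channel` are clustered into connected sets (positive and negative
#' channels separately) using the adjacency graph; each cluster's statistic
#' is the sum of its t values. The Monte-Carlo reference distribution of the
#' maximal cluster mass is obtained by randomly swapping the two conditions
#' within subject (sign flips of the paired differences); each observed
#' cluster's p is `(1 + #{permutation max >= cluster mass}) / (1 + n_perm)`.
#'
#' @param a,b subject x channel matrices (paired conditions).
#' @param adjacency an `adjacency_graph` covering all channels.
#' @param alpha cluster-level significance threshold.
#' @param alpha_channel channel-level threshold forming clusters.
#' @param n_perm number of random permutations.
#' @param seed integer seed.
#' @return list of class `cluster_result`: `clusters` (list of
#'   `channels`, `sum_t`, `p`), `t` (per channel), `crit`,
#'   `sig_mask` (channels in clusters with p < alpha), `n_perm`.
#' @export
cluster_permutation_test <- function(a, b, adjacency, alpha = 0.05,
                                     alpha_channel = 0.05,
                                     n_perm = 5000L, seed = NULL) {
  stopifnot(inherits(adjacency, "adjacency_graph"),
            ncol(a) == length(adjacency$neighbors))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(a)
  nch <- ncol(a)
  d <- a - b
  crit <- qt(1 - alpha_channel / 2, df = n - 1)
  t_obs <- paired_t_map(a, b)

  clusters <- list()
  for (sgn in c(1, -1)) {
    supra <- which(sgn * t_obs > crit)
    for (comp in connected_components(supra, adjacency$neighbors))
      clusters[[length(clusters) + 1L]] <-
        list(channels = comp, sum_t = sum(t_obs[comp]))
  }
  if (length(clusters) == 0) {
    return(structure(list(clusters = list(), t = t_obs, crit = crit,
                          sig_mask = rep(FALSE, nch), n_perm = n_perm),
                     class = "cluster_result"))
  }

  # vectorized permutation t maps: mean of sign-flipped differences; the
  # per-channel mean square is invariant under sign flips
  ss <- colMeans(d^2)
  S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), nrow = n_perm)
  M <- (S %*% d) / n
  null_max <- numeric(n_perm)
  fac <- n / (n - 1)
  sqn <- sqrt(n)
  for (p in seq_len(n_perm)) {
    mp <- M[p, ]
    sdp <- sqrt(pmax(ss - mp^2, 0) * fac)
    tp <- mp / (sdp / sqn)
    tp[sdp == 0] <- 0
    null_max[p] <- max_cluster_mass(tp, crit, adjacency$neighbors)
  }
  for (i in seq_along(clusters)) {
    mass <- abs(clusters[[i]]$sum_t)
    clusters[[i]]$p <- (1 + sum(null_max >= mass)) / (1 + n_perm)
  }
  ord <- order(vapply(clusters, function(cl) -abs(cl$sum_t), numeric(1)))
  clusters <- clusters[ord]
  mask <- rep(FALSE, nch)
  for (cl in clusters) if (cl$p < alpha) mask[cl$channels] <- TRUE
  structure(list(clusters = clusters, t = t_obs, crit = crit,
                 sig_mask = mask, n_perm = n_perm),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), channel threshold |t| > %.3f, %d permutations\n",
              length(x$clusters), x$crit, x$n_perm))
  for (cl in x$clusters)
    cat(sprintf("  %d channels, sum t = %.2f, p = %.4f\n",
                length(cl$channels), cl$sum_t, cl$p))
  invisible(x)
}
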