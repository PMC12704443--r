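# Nonparametric cluster-based permutation testing over channel x time
# (HEP) and channel x frequency (state power) grids.

#' Channel adjacency from montage positions
#'
#' Two channels are neighbors when their 2-D distance is below a
#' threshold (default 1.6 times the median nearest-neighbor distance).
#' The resulting matrix is symmetric and irreflexive.
#'
#' @param montage data.frame with `channel`, `x`, `y`.
#' @param threshold distance threshold; `NULL` for the default rule.
#' @return logical channels x channels adjacency matrix.
#' @export
adjacency_from_positions <- function(montage, threshold = NULL) {
  d <- as.matrix(stats::dist(montage[, c("x", "y")]))
  if (is.null(threshold)) {
    nn <- apply(d + diag(Inf, nrow(d)), 1, min)
    threshold <- 1.6 * median(nn)
  }
  adj <- d > 0 & d <= threshold
  diag(adj) <- FALSE
  adj <- adj | t(adj)
  dimnames(adj) <- list(montage$channel, montage$channel)
  adj
}

#' Pointwise paired t statistics over a channel x point grid
#'
#' @param cond_a,cond_b participant x channel x point arrays with the
#'   same participants in the same order (n >= 3).
#' @return channel x point matrix of paired t values; points with
#'   zero-variance differences get t = 0 and are flagged in the
#'   `zero_var` attribute.
#' @export
paired_t_map <- function(cond_a, cond_b) {
  stopifnot(identical(dim(cond_a), dim(cond_b)), dim(cond_a)[1] >= 3)
  d <- cond_a - cond_b
  n <- dim(d)[1]
  m <- apply(d, c(2, 3), mean)
  s <- apply(d, c(2, 3), sd)
  zero <- s < 1e-12
  s[zero] <- 1
  t_map <- m / (s / sqrt(n))
  t_map[zero] <- 0
  attr(t_map, "zero_var") <- zero
  attr(t_map, "df") <- n - 1
  t_map
}

#' Group suprathreshold points into signed clusters
#'
#' Points with `|t|` above the threshold are split by sign and joined
#' into connected components; two points are connected when they share a
#' channel and are adjacent along the axis, or share an axis position on
#' neighboring channels.  Each cluster's statistic is the sum of its
#' member t values.
#'
#' @param t_map channel x point matrix of t values.
#' @param threshold positive t threshold (e.g.
#'   `qt(0.975, n - 1)` for a pointwise two-tailed p < .05 rule).
#' @param adjacency logical channel adjacency matrix.
#' @return list of clusters, each a list with `members` (two-column
#'   matrix of channel/point indices), `stat` (summed t), `sign`.
#'   Empty list when nothing exceeds the threshold.
#' @export
clusterize <- function(t_map, threshold, adjacency) {
  stopifnot(nrow(t_map) == nrow(adjacency))
  n_ch <- nrow(t_map); n_k <- ncol(t_map)
  supra <- abs(t_map) > threshold
  sgn <- sign(t_map)
  labels <- matrix(0L, n_ch, n_k)
  clusters <- list()
  for (ch in seq_len(n_ch)) for (k in seq_len(n_k)) {
    if (!supra[ch, k] || labels[ch, k] != 0L) next
    id <- length(clusters) + 1L
    queue <- matrix(c(ch, k), ncol = 2)
    labels[ch, k] <- id
    members <- queue
    s <- sgn[ch, k]
    while (nrow(queue)) {
      c0 <- queue[1, 1]; k0 <- queue[1, 2]
      queue <- queue[-1, , drop = FALSE]
      nb <- rbind(
        if (k0 > 1) c(c0, k0 - 1L),
        if (k0 < n_k) c(c0, k0 + 1L))
      nbr_ch <- which(adjacency[c0, ])
      if (length(nbr_ch))
        nb <- rbind(nb, cbind(nbr_ch, rep(k0, length(nbr_ch))))
      if (is.null(nb)) next
      for (j in seq_len(nrow(nb))) {
        cc <- nb[j, 1]; kk <- nb[j, 2]
        if (supra[cc, kk] && labels[cc, kk] == 0L && sgn[cc, kk] == s) {
          labels[cc, kk] <- id
          queue <- rbind(queue, c(cc, kk))
          members <- rbind(members, c(cc, kk))
        }
      }
    }
    clusters[[id]] <- list(members = members,
                           stat = sum(t_map[members]),
                           sign = s)
  }
  clusters
}

#' Cluster-based permutation test for a paired design
#'
#' Pointwise dependent-samples t tests are thresholded at two-tailed
#' p < .05, suprathreshold points are joined into signed clusters under
#' the channel/axis adjacency, and each observed cluster's summed-t
#' statistic is compared against the permutation null of maximum
#' absolute cluster statistics obtained by randomly flipping the sign of
#' each participant's condition difference (the paired-data equivalent
#' of permuting condition labels).  The add-one Monte-Carlo rule gives
#' `p = (1 + #(null >= |observed|)) / (1 + n_perm)`, and a cluster is
#' significant at `p < .025` per tail (two-sided test).
#'
#' @param cond_a,cond_b participant x channel x point arrays.
#' @param adjacency logical channel adjacency matrix.
#' @param n_perm number of permutations.
#' @param seed optional seed.
#' @param alpha per-tail significance level.
#' @param point_alpha pointwise two-tailed threshold level.
#' @return object of class `cluster_result`: list with `clusters` (each
#'   with members, stat, sign, p, significant), `t_map`, `threshold`,
#'   `null_max`, `n_perm`.
#' @export
permutation_test <- function(cond_a, cond_b, adjacency, n_perm = 1000,
                             seed = NULL, alpha = 0.025,
                             point_alpha = 0.05) {
  d <- cond_a - cond_b
  n <- dim(d)[1]; n_ch <- dim(d)[2]; n_k <- dim(d)[3]
  if (2^n < n_perm)
    warning("only 2^", n, " distinct sign flips exist; sampling with ",
            "replacement among them")
  t_obs <- paired_t_map(cond_a, cond_b)
  thr <- qt(1 - point_alpha / 2, df = n - 1)
  obs <- clusterize(t_obs, thr, adjacency)
  D <- matrix(d, nrow = n)                   # n x (ch * k), channel-major
  ss <- colSums(D^2)
  null_max <- with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    M <- signs %*% D / n
    v <- sweep(-M^2, 2, ss / n, "+") * (n / (n - 1))
    v[v < 1e-24] <- Inf                      # zero-variance points -> t = 0
    Tm <- M / sqrt(v / n)
    max_cluster_stat(Tm, n_ch, n_k, adjacency, thr)
  })
  for (i in seq_along(obs)) {
    p <- (1 + sum(null_max >= abs(obs[[i]]$stat))) / (1 + n_perm)
    obs[[i]]$p <- p
    obs[[i]]$significant <- p < alpha
  }
  structure(list(clusters = obs, t_map = t_obs, threshold = thr,
                 null_max = null_max, n_perm = n_perm),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", length(x$clusters), " cluster(s), ",
      x$n_perm, " permutations, |t| threshold ",
      signif(x$threshold, 4), "\n", sep = "")
  for (cl in x$clusters)
    cat(sprintf("  sign %+d  stat %8.2f  p = %.4f%s  (%d points)\n",
                cl$sign, cl$stat, cl$p,
                if (cl$significant) " *" else "", nrow(cl$members)))
  invisible(x)
}

# Maximum |summed t| over sign-consistent connected clusters, per row of
# a permutation t matrix (rows are permutations, columns the flattened
# channel x point grid).  Thin wrapper over the compiled search.
max_cluster_stat <- function(t_rows, n_ch, n_k, adjacency, threshold) {
  nb <- lapply(seq_len(n_ch), function(i) which(adjacency[i, ]) - 1L)
  cpp_max_cluster_stat(t_rows, n_ch, n_k, nb, threshold)
}
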