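#' Snowball-sample a connected synthetic cluster
#'
#' Draws one synthetic cluster by picking a seed node uniformly at random
#' and growing breadth-first: the seed's neighbours, their neighbours, and
#' so on. When absorbing the whole next frontier would overshoot the target
#' size, the remainder is filled by uniform random choice from that
#' frontier. If the seed's connected component is smaller than the target,
#' the sample is the whole component (truncated, not resampled - resampling
#' would bias the null toward large components).
#'
#' @param network A `bocc_network`.
#' @param target_size Desired cluster size (>= 1).
#' @return A character vector of node ids.
#' @export
snowball_sample <- function(network, target_size) {
  adj <- build_adjacency(network)
  adj$ids[snowball_sample_idx(adj$nbrs, target_size)]
}

build_adjacency <- function(network) {
  ids <- network$nodes$id
  n <- length(ids)
  ui <- match(network$edges$u, ids)
  vi <- match(network$edges$v, ids)
  nbrs <- vector("list", n)
  if (length(ui) > 0) {
    ends <- c(ui, vi)
    other <- c(vi, ui)
    ord <- order(ends)
    nbrs_split <- split(other[ord], ends[ord])
    nbrs[as.integer(names(nbrs_split))] <- nbrs_split
  }
  list(ids = ids, nbrs = nbrs, n = n)
}

snowball_sample_idx <- function(nbrs, target_size) {
  n <- length(nbrs)
  if (target_size < 1) stop("target_size must be >= 1", call. = FALSE)
  seed <- sample.int(n, 1)
  selected <- logical(n)
  selected[seed] <- TRUE
  n_sel <- 1L
  frontier_src <- seed
  while (n_sel < target_size) {
    cand <- unique(unlist(nbrs[frontier_src], use.names = FALSE))
    cand <- cand[!selected[cand]]
    if (length(cand) == 0) break  # component exhausted: truncated sample
    if (n_sel + length(cand) <= target_size) {
      selected[cand] <- TRUE
      n_sel <- n_sel + length(cand)
      frontier_src <- cand
    } else {
      fill <- cand[sample.int(length(cand), target_size - n_sel)]
      selected[fill] <- TRUE
      n_sel <- target_size
    }
  }
  which(selected)
}

new_null <- function(counts, model) {
  structure(list(counts = as.integer(counts),
                 replicates = length(counts), model = model),
            class = "bocc_null")
}

#' @export
print.bocc_null <- function(x, ...) {
  cat(sprintf("<bocc_null '%s'> %d replicates, mean count %.3f, max %d\n",
              x$model, x$replicates, mean(x$counts), max(x$counts)))
  invisible(x)
}

count_inside <- function(ui, vi, member_flag) {
  if (length(ui) == 0) return(0L)
  sum(member_flag[ui] & member_flag[vi])
}

#' Empirical null distributions of the rediscovery count
#'
#' Three nulls for the per-cluster rediscovery count, all seeded and
#' returning a `bocc_null` (integer replicate counts):
#'
#' * `snowball_null()`: each replicate draws an independent connected
#'   synthetic cluster of the same size by [snowball_sample()] and counts
#'   the new edges falling inside it. This is the pipeline's reference
#'   null: connected random sets respect the network's local density, which
#'   makes the resulting p-values conservative.
#' * `random_cluster_null()`: synthetic clusters are uniform random node
#'   subsets with no connectivity requirement - the classical
#'   "random-cluster" comparison null, which tends to overstate
#'   significance on clustered networks.
#' * `edge_shuffle_null()`: holds the cluster fixed and randomises the
#'   discovery process instead, rewiring the new-edge set by
#'   degree-preserving double-edge swaps (rejecting self-loops, duplicate
#'   new edges and collisions with existing snapshot edges) and counting
#'   how many shuffled new edges land inside the cluster.
#'
#' @param network A `bocc_network`.
#' @param cluster_members Character vector of the real cluster's node ids.
#' @param new_edges Edge tibble (`u`, `v`) of future edges.
#' @param replicates Number of synthetic replicates (default 10000).
#' @param seed Integer seed.
#' @return A `bocc_null` object.
#' @name null_models
NULL

#' @rdname null_models
#' @export
snowball_null <- function(network, cluster_members, new_edges,
                          replicates = 10000, seed = 1) {
  stopifnot(length(cluster_members) >= 1)
  adj <- build_adjacency(network)
  ui <- match(new_edges$u, adj$ids)
  vi <- match(new_edges$v, adj$ids)
  k <- length(cluster_members)
  counts <- with_seed(seed, {
    vapply(seq_len(replicates), function(i) {
      flag <- logical(adj$n)
      flag[snowball_sample_idx(adj$nbrs, k)] <- TRUE
      count_inside(ui, vi, flag)
    }, integer(1))
  })
  new_null(counts, "snowball")
}

#' @rdname null_models
#' @export
random_cluster_null <- function(network, cluster_members, new_edges,
                                replicates = 10000, seed = 1) {
  adj <- build_adjacency(network)
  k <- length(cluster_members)
  if (k > adj$n) {
    stop("cluster size exceeds the number of network nodes", call. = FALSE)
  }
  ui <- match(new_edges$u, adj$ids)
  vi <- match(new_edges$v, adj$ids)
  counts <- with_seed(seed, {
    vapply(seq_len(replicates), function(i) {
      flag <- logical(adj$n)
      flag[sample.int(adj$n, k)] <- TRUE
      count_inside(ui, vi, flag)
    }, integer(1))
  })
  new_null(counts, "random_cluster")
}

#' @rdname null_models
#' @param swaps_per_edge Attempted double-edge swaps per new edge
#'   (default 10).
#' @export
edge_shuffle_null <- function(network, cluster_members, new_edges,
                              replicates = 10000, seed = 1,
                              swaps_per_edge = 10) {
  adj <- build_adjacency(network)
  member_flag <- logical(adj$n)
  member_flag[match(intersect(cluster_members, adj$ids), adj$ids)] <- TRUE
  ui <- match(new_edges$u, adj$ids)
  vi <- match(new_edges$v, adj$ids)
  n_e <- length(ui)
  existing <- paste(pmin(network$edges$u, network$edges$v),
                    pmax(network$edges$u, network$edges$v))
  counts <- with_seed(seed, {
    vapply(seq_len(replicates), function(r) {
      e <- shuffle_edge_set(ui, vi, adj$ids, existing,
                            attempts = swaps_per_edge * n_e)
      count_inside(e$ui, e$vi, member_flag)
    }, integer(1))
  })
  new_null(counts, "edge_shuffle")
}

# Degree-preserving double-edge swaps on an edge set, rejecting proposals
# that create self-loops, duplicates within the set, or edges already
# present in the snapshot.
shuffle_edge_set <- function(ui, vi, ids, existing, attempts) {
  n_e <- length(ui)
  if (n_e < 2) return(list(ui = ui, vi = vi))
  key <- function(a, b) paste(ids[pmin(a, b)], ids[pmax(a, b)])
  keys <- key(ui, vi)
  for (t in seq_len(attempts)) {
    pick <- sample.int(n_e, 2)
    a <- pick[1]; b <- pick[2]
    if (stats::runif(1) < 0.5) {
      nu1 <- ui[a]; nv1 <- vi[b]; nu2 <- ui[b]; nv2 <- vi[a]
    } else {
      nu1 <- ui[a]; nv1 <- ui[b]; nu2 <- vi[a]; nv2 <- vi[b]
    }
    if (nu1 == nv1 || nu2 == nv2) next
    k1 <- key(nu1, nv1); k2 <- key(nu2, nv2)
    if (k1 == k2) next
    other <- keys[-c(a, b)]
    if (k1 %in% other || k2 %in% other ||
        k1 %in% existing || k2 %in% existing) next
    ui[a] <- nu1; vi[a] <- nv1
    ui[b] <- nu2; vi[b] <- nv2
    keys[a] <- k1; keys[b] <- k2
  }
  list(ui = ui, vi = vi)
}

#' Empirical p-value of an observed rediscovery count
#'
#' The plain proportion of synthetic counts greater than or equal to the
#' observed count, so attainable values are exactly `0, 1/R, ..., 1` and a
#' cluster with no rediscoveries always gets p = 1. The `plus_one` variant
#' (`(x + 1)/(R + 1)`) that avoids exact zeros is available behind a flag.
#'
#' @param observed Observed rediscovery count (integer >= 0).
#' @param null A `bocc_null` or an integer vector of synthetic counts.
#' @param plus_one Use the add-one estimator? Default `FALSE`.
#' @return A single numeric p-value in (0, 1].
#' @export
empirical_pvalue <- function(observed, null, plus_one = FALSE) {
  counts <- if (inherits(null, "bocc_null")) null$counts else null
  if (length(counts) == 0) {
    stop("empty null distribution", call. = FALSE)
  }
  hits <- sum(counts >= observed)
  if (plus_one) (hits + 1) / (length(counts) + 1) else hits / length(counts)
}

#' Per-cluster empirical p-values for a whole clustering
#'
#' Convenience wrapper scoring every cluster of a cluster table against a
#' chosen null. For the snowball and random-cluster nulls the synthetic
#' count distribution depends on the cluster only through its size, so null
#' draws are shared across equal-sized clusters; for the edge-shuffle null
#' the shuffled new-edge sets are generated once and scored against every
#' cluster.
#'
#' @param network A `bocc_network`.
#' @param clusters A cluster tibble.
#' @param new_edges Edge tibble of future edges.
#' @param replicates Replicates per null distribution.
#' @param seed Integer seed.
#' @param model `"snowball"` (default), `"random_cluster"` or
#'   `"edge_shuffle"`.
#' @param plus_one Passed to [empirical_pvalue()].
#' @return A tibble: `cluster_id`, `observed`, `replicates`, `p`.
#' @export
cluster_pvalues <- function(network, clusters, new_edges, replicates = 1000,
                            seed = 1, model = c("snowball", "random_cluster",
                                                "edge_shuffle"),
                            plus_one = FALSE) {
  model <- match.arg(model)
  obs <- count_rediscoveries(clusters, new_edges)
  sizes <- lengths(clusters$members)
  adj <- build_adjacency(network)
  ui <- match(new_edges$u, adj$ids)
  vi <- match(new_edges$v, adj$ids)

  p <- numeric(nrow(clusters))
  if (model %in% c("snowball", "random_cluster")) {
    null_by_size <- list()
    for (k in sort(unique(sizes))) {
      counts <- with_seed(derive_seed(seed, k), {
        vapply(seq_len(replicates), function(i) {
          flag <- logical(adj$n)
          idx <- if (model == "snowball") {
            snowball_sample_idx(adj$nbrs, k)
          } else {
            sample.int(adj$n, min(k, adj$n))
          }
          flag[idx] <- TRUE
          count_inside(ui, vi, flag)
        }, integer(1))
      })
      null_by_size[[as.character(k)]] <- counts
    }
    for (i in seq_len(nrow(clusters))) {
      p[i] <- empirical_pvalue(obs$observed[i],
                               null_by_size[[as.character(sizes[i])]],
                               plus_one = plus_one)
    }
  } else {
    existing <- paste(pmin(network$edges$u, network$edges$v),
                      pmax(network$edges$u, network$edges$v))
    shuffles <- with_seed(seed, {
      lapply(seq_len(replicates), function(r) {
        shuffle_edge_set(ui, vi, adj$ids, existing,
                         attempts = 10 * length(ui))
      })
    })
    for (i in seq_len(nrow(clusters))) {
      flag <- logical(adj$n)
      flag[match(intersect(clusters$members[[i]], adj$ids), adj$ids)] <- TRUE
      counts <- vapply(shuffles, function(e) count_inside(e$ui, e$vi, flag),
                       integer(1))
      p[i] <- empirical_pvalue(obs$observed[i], counts, plus_one = plus_one)
    }
  }
  tibble::tibble(
    cluster_id = clusters$cluster_id,
    observed = obs$observed,
    replicates = replicates,
    p = p
  )
}
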