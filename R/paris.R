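# Paris agglomerative hierarchical clustering (Bonald et al. style).
#
# Nodes are merged bottom-up by the reducible distance
#   d(a, b) = w(a) w(b) / (W * w(a, b))
# where w(a) is the (summed degree) weight of cluster a, w(a, b) the total
# edge weight between a and b, and W the total node weight. Disconnected
# parts that never share an edge are attached at the end at infinite
# distance, so the dendrogram always has a single root.

paris_dendrogram <- function(g) {
  n <- igraph::vcount(g)
  names <- igraph::V(g)$name
  if (n == 1) {
    return(list(child1 = NA_integer_, child2 = NA_integer_,
                leaf_count = 1L, names = names, root = 1L))
  }
  total <- 2L * n - 1L
  A <- matrix(0, total, total)
  el <- igraph::ends(g, igraph::E(g), names = FALSE)
  if (nrow(el) > 0) {
    for (i in seq_len(nrow(el))) {
      A[el[i, 1], el[i, 2]] <- A[el[i, 1], el[i, 2]] + 1
      A[el[i, 2], el[i, 1]] <- A[el[i, 2], el[i, 1]] + 1
    }
  }
  w <- c(igraph::degree(g), rep(0, n - 1L))
  W <- sum(w)
  child1 <- child2 <- rep(NA_integer_, total)
  leaf_count <- c(rep(1L, n), rep(0L, n - 1L))
  active <- seq_len(n)

  for (step in seq_len(n - 1L)) {
    new_id <- n + step
    sub <- A[active, active, drop = FALSE]
    conn <- which(sub > 0 & upper.tri(sub), arr.ind = TRUE)
    if (nrow(conn) > 0 && W > 0) {
      d <- (w[active[conn[, 1]]] * w[active[conn[, 2]]]) /
        (W * sub[conn])
      best <- which(d == min(d))
      # deterministic tie-break: smallest pair of original indices
      if (length(best) > 1) {
        key <- active[conn[best, 1]] * (total + 1) + active[conn[best, 2]]
        best <- best[which.min(key)]
      }
      a <- active[conn[best, 1]]
      b <- active[conn[best, 2]]
    } else {
      a <- active[1]
      b <- active[2]
    }
    child1[new_id] <- a
    child2[new_id] <- b
    leaf_count[new_id] <- leaf_count[a] + leaf_count[b]
    w[new_id] <- w[a] + w[b]
    A[new_id, ] <- A[a, ] + A[b, ]
    A[, new_id] <- A[new_id, ]
    A[new_id, new_id] <- 0
    active <- c(setdiff(active, c(a, b)), new_id)
  }
  list(child1 = child1, child2 = child2, leaf_count = leaf_count,
       names = names, root = total)
}

# Leaves under a dendrogram node.
paris_leaves <- function(dendro, node) {
  out <- character(0)
  stack <- node
  n_leaves <- length(dendro$names)
  while (length(stack) > 0) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (cur <= n_leaves) {
      out <- c(out, dendro$names[cur])
    } else {
      stack <- c(stack, dendro$child1[cur], dendro$child2[cur])
    }
  }
  out
}

# Cut the dendrogram into the maximal subtrees with <= max_size leaves,
# descending from the root.
paris_cut <- function(dendro, max_size) {
  out <- list()
  stack <- dendro$root
  n_leaves <- length(dendro$names)
  while (length(stack) > 0) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    size <- if (cur <= n_leaves) 1L else dendro$leaf_count[cur]
    if (size <= max_size) {
      out[[length(out) + 1]] <- paris_leaves(dendro, cur)
    } else {
      stack <- c(stack, dendro$child1[cur], dendro$child2[cur])
    }
  }
  out
}
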