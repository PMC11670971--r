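# Shared fixtures and independent brute-force oracles used across the suite.

withr_local_dir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

withr_local_file <- function(name, env = parent.frame()) {
  file.path(withr::local_tempdir(.local_envir = env), name)
}

empty_edges <- function() tibble::tibble(u = character(), v = character())

make_net <- function(g2g = empty_edges(), p2p = empty_edges(),
                     g2p = empty_edges(), ts = "t1") {
  build_snapshot(g2g, p2p, g2p, timestamp = ts)
}

two_triangles <- function() {
  make_net(g2g = tibble::tibble(u = c("a", "b", "a", "d", "e", "d"),
                                v = c("b", "c", "c", "e", "f", "f")))
}

clusters_tbl <- function(members, ts = "t1", algorithm = "test") {
  tibble::tibble(
    cluster_id = sprintf("%s.%s:%d", algorithm, ts, seq_along(members)),
    algorithm = algorithm, timestamp = ts, members = members
  )
}

# Random hybrid network: Erdos-Renyi within each layer plus random g2p.
rand_hybrid_net <- function(n_genes, n_phens, p, seed, ts = "t1") {
  set.seed(seed)
  genes <- sprintf("G%03d", seq_len(n_genes))
  phens <- sprintf("HP:%07d", seq_len(n_phens))
  pick_pairs <- function(a, b = NULL) {
    if (is.null(b)) {
      idx <- utils::combn(length(a), 2)
      tbl <- tibble::tibble(u = a[idx[1, ]], v = a[idx[2, ]])
    } else {
      tbl <- tidyr::expand_grid(u = a, v = b)
    }
    tbl[stats::runif(nrow(tbl)) < p, ]
  }
  make_net(g2g = pick_pairs(genes), p2p = pick_pairs(phens),
           g2p = pick_pairs(genes, phens), ts = ts)
}

# Brute-force rediscovery count: explicit double loop.
brute_count <- function(members, new_edges) {
  n <- 0L
  for (i in seq_len(nrow(new_edges))) {
    hit_u <- FALSE
    hit_v <- FALSE
    for (m in members) {
      if (m == new_edges$u[i]) hit_u <- TRUE
      if (m == new_edges$v[i]) hit_v <- TRUE
    }
    if (hit_u && hit_v) n <- n + 1L
  }
  n
}

# Brute-force cluster features via edge-by-edge scans.
brute_features <- function(network, members) {
  edges <- network$edges
  n <- nrow(network$nodes)
  m <- nrow(edges)
  inside <- function(x) x %in% members
  ei <- 0L
  b <- 0L
  for (i in seq_len(m)) {
    iu <- inside(edges$u[i]); iv <- inside(edges$v[i])
    if (iu && iv) ei <- ei + 1L else if (iu || iv) b <- b + 1L
  }
  deg <- function(id) sum(edges$u == id) + sum(edges$v == id)
  int_deg <- function(id) {
    sum((edges$u == id & inside(edges$v)) | (edges$v == id & inside(edges$u)))
  }
  embed <- vapply(members, function(id) {
    d <- deg(id)
    if (d == 0) 0 else int_deg(id) / d
  }, numeric(1))
  vol <- sum(vapply(members, deg, numeric(1)))
  genes <- members[!grepl("^HP:\\d+$", members)]
  annot <- unique(unlist(edges[edges$kind == "g2p", c("u", "v")]))
  annot <- annot[!grepl("^HP:\\d+$", annot)]
  size <- length(members)
  list(
    boundary = b,
    size = size,
    gene_ratio = length(genes) / size,
    disease_specificity = if (length(genes)) mean(genes %in% annot) else 0,
    edges_inside = ei,
    aid = 2 * ei / size,
    ngm = if (m > 0) ei / m - (vol / (2 * m))^2 else 0,
    ae = mean(embed),
    conductance = if (2 * ei + b > 0) b / (2 * ei + b) else 0,
    cut = if (size < n) b / (size * (n - size)) else 0
  )
}

# All set partitions of 1..n as membership vectors (restricted growth).
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, max_used) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible(NULL))
    }
    for (v in seq_len(max_used + 1)) {
      recurse(c(prefix, v), max(max_used, v))
    }
  }
  recurse(integer(0), 0L)
  out
}

adjusted_rand <- function(m1, m2) {
  igraph::compare(as.integer(factor(m1)), as.integer(factor(m2)),
                  method = "adjusted.rand")
}

# Rank-statistic AUC, the independent oracle for evaluate_auc().
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}
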