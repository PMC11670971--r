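#' Community detection ensemble over a network snapshot
#'
#' The pipeline clusters each snapshot with four algorithms chosen for their
#' different algorithmic bases: greedy modularity maximisation, walktrap
#' (random walks), infomap (map equation / information theory) and CESNA
#' (overlapping communities from edge structure plus binary node
#' attributes). No single algorithm dominates - each rediscovers edges the
#' others miss - so all four are run and considered together.
#'
#' Each function returns a cluster table: a tibble with `cluster_id`
#' (`"<algorithm>.<timestamp>:<index>"`), `algorithm`, `timestamp` and a
#' `members` list-column of node ids, with an `overlapping` attribute. The
#' partitioning algorithms cover every non-isolated node exactly once;
#' CESNA communities may overlap and may leave nodes unassigned.
#'
#' @param network A `bocc_network` with at least one edge.
#' @param steps Walktrap random-walk length (default 4).
#' @param seed Integer seed for the stochastic algorithms.
#' @return A cluster tibble (see Details).
#' @name cluster_algorithms
NULL

new_clustering <- function(members, algorithm, timestamp, overlapping,
                           prefix = NULL) {
  members <- members[lengths(members) > 0]
  members <- lapply(members, function(m) sort(unique(m)))
  stem <- paste0(c(prefix, algorithm, timestamp), collapse = ".")
  out <- tibble::tibble(
    cluster_id = sprintf("%s:%d", stem, seq_along(members)),
    algorithm = algorithm,
    timestamp = timestamp,
    members = unname(members)
  )
  attr(out, "overlapping") <- overlapping
  out
}

clustering_graph <- function(network) {
  if (nrow(network$edges) == 0) {
    stop("cannot cluster a network with no edges", call. = FALSE)
  }
  g <- as_igraph(network)
  igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
}

membership_to_clusters <- function(comm, g) {
  memb <- igraph::membership(comm)
  split(igraph::V(g)$name, memb)
}

#' @rdname cluster_algorithms
#' @export
cluster_greedy <- function(network) {
  g <- clustering_graph(network)
  comm <- igraph::cluster_fast_greedy(g, weights = NULL)
  # cut the merge tree at the modularity maximum explicitly (first maximum
  # on ties, i.e. the finer partition), which also covers tiny graphs where
  # the default membership stops short of the final beneficial merge
  memb <- igraph::cut_at(comm, steps = which.max(comm$modularity) - 1L)
  new_clustering(split(igraph::V(g)$name, memb), "greedy",
                 network$timestamp, overlapping = FALSE)
}

#' @rdname cluster_algorithms
#' @export
cluster_walktrap <- function(network, steps = 4) {
  g <- clustering_graph(network)
  comm <- igraph::cluster_walktrap(g, steps = steps, weights = NULL)
  new_clustering(membership_to_clusters(comm, g), "walktrap",
                 network$timestamp, overlapping = FALSE)
}

#' @rdname cluster_algorithms
#' @export
cluster_infomap <- function(network, seed = 1) {
  g <- clustering_graph(network)
  comm <- with_seed(seed, igraph::cluster_infomap(g))
  new_clustering(membership_to_clusters(comm, g), "infomap",
                 network$timestamp, overlapping = FALSE)
}

#' @rdname cluster_algorithms
#' @param node_attributes Binary attribute table for CESNA: a data frame or
#'   matrix with one row per node (rownames or an `id` column) and 0/1
#'   columns. Default: a single `is_gene` attribute derived from node kind.
#' @param n_communities Number of CESNA communities; default
#'   `ceiling(n / 50)` so mean community size sits near half the 100-node
#'   curation cap.
#' @export
cluster_cesna <- function(network, node_attributes = NULL,
                          n_communities = NULL, seed = 1) {
  g <- clustering_graph(network)
  ids <- igraph::V(g)$name
  n <- length(ids)
  if (is.null(n_communities)) n_communities <- max(1L, ceiling(n / 50))
  if (n_communities < 1) {
    stop("n_communities must be >= 1", call. = FALSE)
  }
  if (is.null(node_attributes)) {
    x <- matrix(as.numeric(igraph::V(g)$kind == "gene"), ncol = 1,
                dimnames = list(ids, "is_gene"))
  } else {
    x <- as.matrix(tibble::column_to_rownames(
      as.data.frame(node_attributes), var = intersect(
        c("id"), colnames(node_attributes))[1] %||% "id"
    ))
    x <- x[ids, , drop = FALSE]
    storage.mode(x) <- "double"
  }
  comms <- cesna_fit(g, x, k = n_communities, seed = seed)
  new_clustering(comms, "cesna", network$timestamp, overlapping = TRUE)
}

#' Cap cluster sizes by Paris hierarchical sub-clustering
#'
#' Re-clusters every cluster of `clustering` with the Paris agglomerative
#' hierarchy on its induced subgraph and cuts the dendrogram into the
#' maximal subtrees whose leaf counts do not exceed `max_size`. Clusters
#' already under the cap are emitted whole (the dendrogram root). The union
#' of a parent's subclusters always equals the parent's member set, and
#' every emitted subcluster has at most `max_size` members. Cluster ids
#' gain the `"paris."` prefix and are renumbered sequentially.
#'
#' The 100-node default follows the curation limit used when clusters are
#' reviewed by hand: raw community detection on knowledge networks can emit
#' clusters of many thousands of nodes, far too large to interpret.
#'
#' @param network The `bocc_network` the clustering came from.
#' @param clustering A cluster tibble.
#' @param max_size Maximum members per emitted subcluster (>= 2).
#' @return A cluster tibble with the same `algorithm` and `timestamp`.
#' @export
paris_subcluster <- function(network, clustering, max_size = 100) {
  stopifnot(max_size >= 2)
  if (nrow(clustering) == 0) return(clustering)
  g <- as_igraph(network)
  pieces <- lapply(clustering$members, function(members) {
    if (length(members) <= max_size) return(list(members))
    sub <- igraph::induced_subgraph(g, members)
    dendro <- paris_dendrogram(sub)
    paris_cut(dendro, max_size)
  })
  new_clustering(
    unlist(pieces, recursive = FALSE),
    algorithm = clustering$algorithm[1],
    timestamp = clustering$timestamp[1],
    overlapping = isTRUE(attr(clustering, "overlapping")),
    prefix = "paris"
  )
}

#' Run the full clustering ensemble with Paris size capping
#'
#' Runs the four algorithms, applies [paris_subcluster()] to each result,
#' and returns one capped cluster table per algorithm. An algorithm that
#' fails is reported with a warning and omitted (recorded in the
#' `"failures"` attribute); if every algorithm fails, an error is raised.
#'
#' @param network A `bocc_network`.
#' @param algorithms Algorithms to run.
#' @param max_size Paris size cap (default 100).
#' @param seed Seed for the stochastic algorithms.
#' @param steps Walktrap step length.
#' @param n_communities CESNA community count (default `ceiling(n / 50)`).
#' @return A named list of cluster tibbles.
#' @export
run_ensemble <- function(network,
                         algorithms = c("greedy", "walktrap", "infomap", "cesna"),
                         max_size = 100, seed = 1, steps = 4,
                         n_communities = NULL) {
  runners <- list(
    greedy = function() cluster_greedy(network),
    walktrap = function() cluster_walktrap(network, steps = steps),
    infomap = function() cluster_infomap(network, seed = seed),
    cesna = function() cluster_cesna(network, n_communities = n_communities,
                                     seed = seed)
  )
  out <- list()
  failures <- character(0)
  for (alg in algorithms) {
    res <- tryCatch(runners[[alg]](), error = function(e) e)
    if (inherits(res, "error")) {
      warning("algorithm '", alg, "' failed: ", conditionMessage(res),
              call. = FALSE)
      failures <- c(failures, alg)
    } else {
      out[[alg]] <- paris_subcluster(network, res, max_size = max_size)
    }
  }
  if (length(out) == 0) {
    stop("all clustering algorithms failed", call. = FALSE)
  }
  attr(out, "failures") <- failures
  out
}
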