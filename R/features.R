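#' Biological and topological features of one cluster
#'
#' Computes the nine per-cluster features used by the significance
#' classifier. With `S` the member set, `ei` the number of edges internal
#' to `S`, `b` the number of boundary edges (exactly one endpoint in `S`),
#' `m` the total edge count and `vol` the summed total degree of members:
#'
#' * `size`: number of members.
#' * `gene_ratio`: genes / size.
#' * `disease_specificity`: fraction of the cluster's genes carrying at
#'   least one g2p annotation anywhere in the snapshot.
#' * `edges_inside`: `ei`.
#' * `aid`: average internal degree, `2 ei / size`.
#' * `ngm`: the cluster's Newman-Girvan modularity contribution,
#'   `ei / m - (vol / 2m)^2`.
#' * `ae`: average embeddedness - mean over members of internal degree over
#'   total degree (an isolated member contributes 0).
#' * `conductance`: `b / (2 ei + b)` (0 when the cluster has no incident
#'   edges at all).
#' * `cut`: cut ratio `b / (size (N - size))` (0 when the cluster is the
#'   whole graph).
#'
#' @param network A `bocc_network`.
#' @param members Character vector of node ids, all present in the network.
#' @param annotated_genes Optional character vector of genes that count as
#'   annotated for `disease_specificity`; defaults to the genes incident to
#'   any g2p edge of the snapshot.
#' @return A one-row tibble of the nine features.
#' @export
compute_features <- function(network, members, annotated_genes = NULL) {
  ids <- network$nodes$id
  missing <- setdiff(members, ids)
  if (length(missing) > 0) {
    stop("cluster member(s) absent from the network: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  ctx <- feature_context(network, annotated_genes)
  feature_row(ctx, members)
}

feature_context <- function(network, annotated_genes = NULL) {
  ids <- network$nodes$id
  ui <- match(network$edges$u, ids)
  vi <- match(network$edges$v, ids)
  deg <- tabulate(c(ui, vi), nbins = length(ids))
  if (is.null(annotated_genes)) {
    g2p <- network$edges[network$edges$kind == "g2p", ]
    annotated_genes <- unique(c(g2p$u, g2p$v))
    annotated_genes <- annotated_genes[!is_hpo_id(annotated_genes)]
  }
  list(ids = ids, ui = ui, vi = vi, deg = deg, m = length(ui),
       n = length(ids), annotated = ids %in% annotated_genes,
       is_gene = !is_hpo_id(ids))
}

feature_row <- function(ctx, members) {
  idx <- match(members, ctx$ids)
  flag <- logical(ctx$n)
  flag[idx] <- TRUE
  size <- length(idx)

  in_u <- flag[ctx$ui]
  in_v <- flag[ctx$vi]
  ei <- sum(in_u & in_v)
  b <- sum(xor(in_u, in_v))

  genes <- ctx$is_gene[idx]
  gene_ratio <- mean(genes)
  disease_specificity <- if (any(genes)) mean(ctx$annotated[idx][genes]) else 0

  deg_members <- ctx$deg[idx]
  int_deg <- tabulate(c(ctx$ui[in_u & in_v], ctx$vi[in_u & in_v]),
                      nbins = ctx$n)[idx]
  ae <- mean(ifelse(deg_members > 0, int_deg / deg_members, 0))

  vol <- sum(deg_members)
  ngm <- if (ctx$m > 0) ei / ctx$m - (vol / (2 * ctx$m))^2 else 0
  conductance <- if (2 * ei + b > 0) b / (2 * ei + b) else 0
  cut <- if (size < ctx$n) b / (size * (ctx$n - size)) else 0

  tibble::tibble(
    size = size, gene_ratio = gene_ratio,
    disease_specificity = disease_specificity,
    edges_inside = as.integer(ei), aid = 2 * ei / size, ngm = ngm,
    ae = ae, conductance = conductance, cut = cut
  )
}

#' Feature table for one or several clusterings
#'
#' One row per cluster (keyed by `cluster_id`), nine feature columns, no
#' missing values; degenerate clusters resolve as documented in
#' [compute_features()]. Recomputing the table is bit-identical.
#'
#' @param network A `bocc_network`.
#' @param clusterings A cluster tibble or a (possibly named) list of them.
#' @param annotated_genes Passed to [compute_features()].
#' @return A tibble: `cluster_id` plus the nine feature columns.
#' @export
feature_table <- function(network, clusterings, annotated_genes = NULL) {
  if (is.data.frame(clusterings)) clusterings <- list(clusterings)
  clusters <- dplyr::bind_rows(clusterings)
  ctx <- feature_context(network, annotated_genes)
  rows <- purrr::map(clusters$members, function(m) feature_row(ctx, m))
  dplyr::bind_cols(
    tibble::tibble(cluster_id = clusters$cluster_id),
    dplyr::bind_rows(rows)
  )
}

bocc_feature_names <- function() {
  c("size", "gene_ratio", "disease_specificity", "edges_inside", "aid",
    "ngm", "ae", "conductance", "cut")
}
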