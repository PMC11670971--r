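#' Count future-edge rediscoveries per cluster
#'
#' A rediscovery is a new edge (typically a g2p edge added by the following
#' year's snapshot) whose two endpoints already co-occur in a cluster
#' computed on the earlier snapshot. Every cluster is scored independently:
#' an edge rediscovered by several clusters counts in each of them.
#'
#' @param clusters A cluster tibble (see [cluster_algorithms]).
#' @param new_edges Edge tibble (`u`, `v`), e.g. from [new_edges_between()].
#' @return A `RediscoveryResult` tibble: `cluster_id`, `observed`,
#'   `eligible_new_edges`, and a `rediscovered` list-column of edge tibbles.
#' @export
count_rediscoveries <- function(clusters, new_edges) {
  n_new <- nrow(new_edges)
  res <- purrr::map(clusters$members, function(members) {
    if (n_new == 0) {
      return(tibble::tibble(u = character(), v = character()))
    }
    inside <- new_edges$u %in% members & new_edges$v %in% members
    new_edges[inside, c("u", "v")]
  })
  tibble::tibble(
    cluster_id = clusters$cluster_id,
    observed = vapply(res, nrow, integer(1)),
    eligible_new_edges = n_new,
    rediscovered = res
  )
}

#' Non-trivial clusters
#'
#' A cluster can only generate gene-phenotype hypotheses if it is
#' heterogeneous (holds at least one gene AND one phenotype) and has more
#' than 3 members; all rediscovery statistics are reported over these
#' non-trivial clusters.
#'
#' @param clusters A cluster tibble.
#' @return A logical vector, one entry per cluster.
#' @export
is_nontrivial <- function(clusters) {
  vapply(clusters$members, function(members) {
    phen <- is_hpo_id(members)
    length(members) > 3 && any(phen) && !all(phen)
  }, logical(1))
}

#' Overlap of rediscovered edges across algorithms
#'
#' Tallies, for every subset of algorithms, how many distinct edges were
#' rediscovered by exactly that subset (the accounting behind an upset
#' plot). Here an edge counts once per algorithm no matter how many of that
#' algorithm's clusters rediscovered it, and the counts over all subsets sum
#' to the size of the union.
#'
#' @param rediscovered_by Named list of edge tibbles (`u`, `v`), one per
#'   algorithm; or named list of `RediscoveryResult` tibbles (their
#'   `rediscovered` columns are pooled).
#' @return A tibble with `algorithms` (plus-joined subset label), `n_edges`,
#'   and logical indicator columns, sorted by descending count.
#' @export
rediscovery_overlap <- function(rediscovered_by) {
  stopifnot(length(rediscovered_by) >= 2, !is.null(names(rediscovered_by)))
  edge_keys <- lapply(rediscovered_by, function(x) {
    if ("rediscovered" %in% names(x)) x <- dplyr::bind_rows(x$rediscovered)
    if (nrow(x) == 0) return(character(0))
    unique(paste(pmin(x$u, x$v), pmax(x$u, x$v)))
  })
  all_edges <- unique(unlist(edge_keys, use.names = FALSE))
  if (length(all_edges) == 0) {
    return(tibble::tibble(algorithms = character(), n_edges = integer()))
  }
  ind <- vapply(edge_keys, function(k) all_edges %in% k,
                logical(length(all_edges)))
  ind <- matrix(ind, nrow = length(all_edges),
                dimnames = list(NULL, names(edge_keys)))
  sig <- apply(ind, 1, function(r) paste(names(edge_keys)[r], collapse = "+"))
  counts <- table(sig)
  out <- tibble::tibble(
    algorithms = names(counts),
    n_edges = as.integer(counts)
  )
  for (alg in names(edge_keys)) {
    out[[alg]] <- stringr::str_detect(
      out$algorithms, stringr::fixed(alg)
    ) & vapply(strsplit(out$algorithms, "\\+"), function(p) alg %in% p,
               logical(1))
  }
  dplyr::arrange(out, dplyr::desc(.data$n_edges), .data$algorithms)
}

#' Proportion of clusters with a rediscovery at growing time horizons
#'
#' For a base snapshot with clusters, computes per horizon h the new-edge
#' set between the base snapshot and the snapshot h steps later (directly
#' base-to-target, not chained), and the proportion of non-trivial clusters
#' with at least one rediscovery. When later snapshots accumulate edges,
#' the proportion is non-decreasing in the horizon: the longer one waits,
#' the more likely a cluster anticipates at least one future discovery.
#'
#' @param series List of `bocc_network` snapshots, ordered by timestamp.
#' @param clusters A cluster tibble computed on the base snapshot.
#' @param base_index Index of the base snapshot in `series`.
#' @param kinds Edge kinds counted as new (default `"g2p"`).
#' @return A tibble: `horizon`, `target_timestamp`, `n_new_edges`,
#'   `n_clusters`, `prop_with_rediscovery`.
#' @export
multi_horizon_rediscovery <- function(series, clusters, base_index = 1,
                                      kinds = "g2p") {
  if (base_index >= length(series)) {
    stop("base snapshot has no later snapshot to compare against",
         call. = FALSE)
  }
  keep <- clusters[is_nontrivial(clusters), ]
  purrr::map_dfr(seq_len(length(series) - base_index), function(h) {
    target <- series[[base_index + h]]
    new_edges <- new_edges_between(series[[base_index]], target, kinds = kinds)
    res <- count_rediscoveries(keep, new_edges)
    tibble::tibble(
      horizon = h,
      target_timestamp = target$timestamp,
      n_new_edges = nrow(new_edges),
      n_clusters = nrow(keep),
      prop_with_rediscovery = if (nrow(keep) == 0) 0 else
        mean(res$observed >= 1)
    )
  })
}
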