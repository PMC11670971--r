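#' Infer gene-to-phenotype edges through drug intermediaries
#'
#' Builds candidate g2p edges from drug-gene and drug-disease association
#' tables (the layout of the Comparative Toxicogenomics Database): a drug
#' linking gene g and a disease that maps to HPO term h implies a candidate
#' edge (g, h). Two filters apply first, in set semantics (order
#' independent): any (drug, disease) pair listed BOTH as therapeutic and as
#' causative is contradictory and removed entirely, and diseases without an
#' HPO mapping are dropped.
#'
#' @param drug_gene Tibble with columns `drug`, `gene`.
#' @param drug_disease Tibble with columns `drug`, `disease`, `label`
#'   (values `"therapeutic"` or `"causative"`; a causative/marker row
#'   contributes evidence too - only the contradiction is removed).
#' @param mesh_to_hpo Tibble with columns `disease`, `hpo_id` mapping
#'   disease (MESH) identifiers to HPO terms.
#' @return A tibble of inferred edges: `gene`, `hpo_term`, `intermediary`
#'   (the drug), deduplicated.
#' @export
ctd_infer_edges <- function(drug_gene, drug_disease, mesh_to_hpo) {
  need <- function(tbl, cols, what) {
    if (!all(cols %in% names(tbl))) {
      stop(what, " table lacks required column(s): ",
           paste(setdiff(cols, names(tbl)), collapse = ", "), call. = FALSE)
    }
  }
  need(drug_gene, c("drug", "gene"), "drug-gene")
  need(drug_disease, c("drug", "disease", "label"), "drug-disease")
  need(mesh_to_hpo, c("disease", "hpo_id"), "MESH-to-HPO")

  labels <- dplyr::distinct(drug_disease, .data$drug, .data$disease,
                            .data$label)
  contradictory <- dplyr::count(labels, .data$drug, .data$disease) |>
    dplyr::filter(.data$n > 1)
  dd <- dplyr::anti_join(drug_disease, contradictory,
                         by = c("drug", "disease"))
  dd <- dplyr::inner_join(dplyr::distinct(dd, .data$drug, .data$disease),
                          mesh_to_hpo, by = "disease",
                          relationship = "many-to-many")
  edges <- dplyr::inner_join(dd, drug_gene, by = "drug",
                             relationship = "many-to-many")
  dplyr::distinct(
    tibble::tibble(gene = edges$gene, hpo_term = edges$hpo_id,
                   intermediary = edges$drug)
  )
}

#' Count inferred edges inside predicted-significant vs other clusters
#'
#' For a set of externally inferred g2p edges, counts how many distinct
#' edges co-occur in at least one cluster predicted significant at the
#' threshold, and how many in at least one cluster predicted
#' non-significant; an edge can contribute to both groups. The
#' significant-to-non-significant ratio is the headline enrichment
#' statistic (reported as `Inf` when no edge falls in a non-significant
#' cluster, `NaN` when neither group has any).
#'
#' @param edges Tibble with `gene` and `hpo_term` columns.
#' @param clusters A cluster tibble.
#' @param predictions Output of [predict_clusters()].
#' @param threshold Threshold whose predictions define the two groups.
#' @return A one-row tibble: `threshold`, `n_significant`,
#'   `n_non_significant`, `ratio`.
#' @export
search_inferred_in_clusters <- function(edges, clusters, predictions,
                                        threshold = 0.05) {
  sig_ids <- eligible_clusters(predictions, threshold)
  pred_here <- predictions[predictions$threshold == threshold, ]
  nonsig_ids <- setdiff(unique(pred_here$cluster_id), sig_ids)

  count_group <- function(ids) {
    cl <- clusters[clusters$cluster_id %in% ids, ]
    if (nrow(cl) == 0 || nrow(edges) == 0) return(0L)
    found <- vapply(seq_len(nrow(edges)), function(i) {
      any(vapply(cl$members, function(m) {
        edges$gene[i] %in% m && edges$hpo_term[i] %in% m
      }, logical(1)))
    }, logical(1))
    keys <- paste(edges$gene, edges$hpo_term)[found]
    length(unique(keys))
  }
  n_sig <- count_group(sig_ids)
  n_nonsig <- count_group(nonsig_ids)
  tibble::tibble(
    threshold = threshold,
    n_significant = n_sig,
    n_non_significant = n_nonsig,
    ratio = n_sig / n_nonsig
  )
}
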