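#' Variant selection rule for patient candidate genes
#'
#' A variant is retained when
#' `(f < 0.01 | i) & (e | s) & (c | l)`:
#' it is rare (population allele frequency below 1%) or has insufficient
#' frequency data (`i`), lies on an exon (`e`) or a splice site (`s`), and
#' has a non-synonymous coding effect (`c`) or a ClinVar
#' pathogenic/likely-pathogenic label (`l`). A missing `f` must be
#' accompanied by `i = TRUE`.
#'
#' @param variants A tibble with columns `f` (numeric, may be `NA`), and
#'   logicals `i`, `e`, `s`, `c`, `l`.
#' @return A logical vector, one entry per variant.
#' @export
select_variant <- function(variants) {
  f_ok <- !is.na(variants$f) & variants$f < 0.01
  (f_ok | variants$i) & (variants$e | variants$s) & (variants$c | variants$l)
}

#' Default VCF INFO field mapping
#'
#' The annotation source feeding the variant filter is pluggable: this
#' mapping names the INFO keys carrying the allele frequency, consequence
#' term and ClinVar significance, and the consequence vocabularies counted
#' as exonic, splice-site and coding-non-synonymous. A record missing the
#' frequency key is treated as "insufficient population frequency"
#' (`i = TRUE`); other missing keys leave their flags `FALSE`.
#'
#' @param af,gene,consequence,clnsig INFO keys.
#' @param exonic_terms,splice_terms,coding_terms Consequence vocabularies.
#' @return A named list consumed by [filter_vcf()].
#' @export
vcf_field_map <- function(af = "AF", gene = "GENE",
                          consequence = "CSQ", clnsig = "CLNSIG",
                          exonic_terms = c(
                            "missense_variant", "synonymous_variant",
                            "stop_gained", "stop_lost", "start_lost",
                            "frameshift_variant", "inframe_insertion",
                            "inframe_deletion"
                          ),
                          splice_terms = c(
                            "splice_acceptor_variant", "splice_donor_variant",
                            "splice_region_variant"
                          ),
                          coding_terms = c(
                            "missense_variant", "stop_gained", "stop_lost",
                            "start_lost", "frameshift_variant",
                            "inframe_insertion", "inframe_deletion"
                          )) {
  list(af = af, gene = gene, consequence = consequence, clnsig = clnsig,
       exonic_terms = exonic_terms, splice_terms = splice_terms,
       coding_terms = coding_terms)
}

#' Candidate genes of a patient from an annotated VCF
#'
#' Reads a VCF, decodes the mapped INFO fields into the six variant-filter
#' inputs, applies [select_variant()] and returns the deduplicated genes of
#' the passing variants. Record and selection counts are reported in a
#' message.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param field_map A [vcf_field_map()].
#' @return Character vector of candidate gene symbols; the record counts
#'   are attached as attributes `n_records` and `n_selected`.
#' @export
filter_vcf <- function(path, field_map = vcf_field_map()) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  n <- nrow(vcf@fix)
  if (is.null(n) || n == 0) {
    out <- character(0)
    attr(out, "n_records") <- 0L
    attr(out, "n_selected") <- 0L
    return(out)
  }
  info_field <- function(key) {
    res <- tryCatch(vcfR::extract.info(vcf, element = key),
                    error = function(e) rep(NA_character_, n))
    if (is.null(res)) rep(NA_character_, n) else res
  }
  gene <- info_field(field_map$gene)
  af_raw <- info_field(field_map$af)
  af <- suppressWarnings(as.numeric(af_raw))
  csq <- info_field(field_map$consequence)
  clnsig <- info_field(field_map$clnsig)
  if (all(is.na(gene))) {
    warning("no '", field_map$gene, "' INFO field found; no genes selected",
            call. = FALSE)
  }

  has_term <- function(x, terms) {
    !is.na(x) & stringr::str_detect(
      x, paste0("(^|[,&|])(", paste(terms, collapse = "|"), ")($|[,&|])")
    )
  }
  variants <- tibble::tibble(
    gene = gene,
    f = af,
    i = is.na(af) | af == 0,
    e = has_term(csq, field_map$exonic_terms),
    s = has_term(csq, field_map$splice_terms),
    c = has_term(csq, setdiff(field_map$coding_terms, "synonymous_variant")),
    l = !is.na(clnsig) &
      stringr::str_detect(clnsig, "Pathogenic|Likely_pathogenic")
  )
  keep <- select_variant(variants) & !is.na(variants$gene)
  message(sum(keep), " of ", n, " variant record(s) selected")
  out <- unique(variants$gene[keep])
  attr(out, "n_records") <- n
  attr(out, "n_selected") <- sum(keep)
  out
}

#' Assemble a patient profile
#'
#' @param patient_id Identifier.
#' @param hpo_terms Character vector of HPO term ids (nonempty for
#'   querying).
#' @param candidate_genes Character vector of candidate gene symbols
#'   (deduplicated).
#' @return A one-row tibble matching [generate_patient_cohort()]'s layout.
#' @export
patient_profile <- function(patient_id, hpo_terms, candidate_genes) {
  tibble::tibble(
    patient_id = patient_id,
    hpo_terms = list(unique(hpo_terms)),
    candidate_genes = list(unique(candidate_genes))
  )
}

#' Predict significance of clusters at each threshold
#'
#' Applies each threshold model to a feature table, returning one row per
#' cluster and threshold with the predicted probability and binary call.
#'
#' @param models Named or unnamed list of `bocc_model`s (each carries its
#'   threshold).
#' @param features A feature table with `cluster_id`.
#' @return A tibble: `cluster_id`, `threshold`, `prob`, `call`.
#' @export
predict_clusters <- function(models, features) {
  purrr::map_dfr(models, function(m) {
    out <- predict(m, features)
    out$threshold <- m$threshold
    out[, c("cluster_id", "threshold", "prob", "call")]
  })
}

eligible_clusters <- function(predictions, threshold) {
  hit <- predictions[predictions$threshold == threshold &
                       predictions$call == 1, ]
  unique(hit$cluster_id)
}

best_threshold_of <- function(predictions) {
  pos <- predictions[predictions$call == 1, ]
  dplyr::group_by(pos, .data$cluster_id) |>
    dplyr::summarise(best_threshold = min(.data$threshold), .groups = "drop")
}

#' Search predicted-significant clusters for latent gene-phenotype pairs
#'
#' Finds, in the clusters predicted significant at the requested threshold,
#' every (candidate gene, patient HPO term) pair that co-occurs in a
#' cluster WITHOUT a direct g2p edge in the snapshot - the latent
#' connections the pipeline exists to surface. Results are ordered by the
#' number of the patient's terms matched in the cluster (descending), then
#' by the cluster's best (smallest) predicted threshold, with remaining
#' ties broken by alphabetic cluster id.
#'
#' @param profile A one-row patient tibble ([patient_profile()]).
#' @param clusters A cluster tibble.
#' @param predictions Output of [predict_clusters()].
#' @param network The snapshot the clusters came from (supplies the direct
#'   g2p edges to exclude).
#' @param threshold Significance threshold whose predictions gate the
#'   search (default 0.05).
#' @return A tibble: `patient_id`, `gene`, `hpo_term`, `cluster_id`,
#'   `best_threshold`, `n_matching_terms`.
#' @export
find_cooccurrences <- function(profile, clusters, predictions, network,
                               threshold = 0.05) {
  genes <- profile$candidate_genes[[1]]
  terms <- profile$hpo_terms[[1]]
  stopifnot(length(terms) > 0)
  keep_ids <- eligible_clusters(predictions, threshold)
  cl <- clusters[clusters$cluster_id %in% keep_ids, ]
  if (nrow(cl) == 0) return(empty_hits())

  direct <- direct_g2p_keys(network)

  best <- best_threshold_of(predictions)
  hits <- purrr::map_dfr(seq_len(nrow(cl)), function(i) {
    members <- cl$members[[i]]
    g <- intersect(genes, members)
    t <- intersect(terms, members)
    if (length(g) == 0 || length(t) == 0) return(NULL)
    pairs <- tidyr::expand_grid(gene = g, hpo_term = t)
    pairs <- pairs[!paste(pairs$gene, pairs$hpo_term) %in% direct, ]
    if (nrow(pairs) == 0) return(NULL)
    pairs$cluster_id <- cl$cluster_id[i]
    pairs$n_matching_terms <- length(t)
    pairs
  })
  if (is.null(hits) || nrow(hits) == 0) return(empty_hits())
  hits <- dplyr::left_join(hits, best, by = "cluster_id")
  hits$patient_id <- profile$patient_id[1]
  hits <- hits[, c("patient_id", "gene", "hpo_term", "cluster_id",
                   "best_threshold", "n_matching_terms")]
  dplyr::arrange(hits, dplyr::desc(.data$n_matching_terms),
                 .data$best_threshold, .data$cluster_id, .data$gene,
                 .data$hpo_term)
}

# "gene term" keys of direct g2p edges, in both endpoint orders (snapshot
# edges are stored under a canonical ordering).
direct_g2p_keys <- function(network) {
  g2p <- network$edges[network$edges$kind == "g2p", ]
  c(paste(g2p$u, g2p$v), paste(g2p$v, g2p$u))
}

empty_hits <- function() {
  tibble::tibble(
    patient_id = character(), gene = character(), hpo_term = character(),
    cluster_id = character(), best_threshold = double(),
    n_matching_terms = integer()
  )
}

count_patient_pairs <- function(genes, terms, clusters_eligible, direct) {
  if (length(genes) == 0 || length(terms) == 0) return(0L)
  pairs <- character(0)
  for (members in clusters_eligible$members) {
    g <- intersect(genes, members)
    t <- intersect(terms, members)
    if (length(g) == 0 || length(t) == 0) next
    p <- tidyr::expand_grid(gene = g, hpo_term = t)
    pairs <- c(pairs, paste(p$gene, p$hpo_term))
  }
  pairs <- unique(pairs)
  sum(!pairs %in% direct)
}

#' Patient-level permutation p-value
#'
#' How surprising is this patient's number of latent co-occurring pairs?
#' Each replicate swaps in the full HPO term set of another patient drawn
#' uniformly (with replacement across replicates) from the rest of the
#' cohort, recounts distinct co-occurring (gene, term) pairs with this
#' patient's candidate genes, and the p-value is the fraction of replicates
#' with at least as many pairs as observed.
#'
#' @param profile The patient's one-row tibble.
#' @param cohort The full cohort tibble (>= 2 patients).
#' @param clusters,predictions,network,threshold As in
#'   [find_cooccurrences()].
#' @param replicates Number of term-set swaps (default 100).
#' @param seed Integer seed.
#' @return A tibble: `patient_id`, `observed_pairs`, `replicates`, `p`.
#' @export
patient_null_pvalue <- function(profile, cohort, clusters, predictions,
                                network, threshold = 0.05,
                                replicates = 100, seed = 1) {
  others <- cohort[cohort$patient_id != profile$patient_id[1], ]
  if (nrow(others) == 0) {
    stop("patient permutation null needs at least one other patient",
         call. = FALSE)
  }
  keep_ids <- eligible_clusters(predictions, threshold)
  cl <- clusters[clusters$cluster_id %in% keep_ids, ]
  direct <- direct_g2p_keys(network)
  genes <- profile$candidate_genes[[1]]

  observed <- count_patient_pairs(genes, profile$hpo_terms[[1]], cl, direct)
  null_counts <- with_seed(seed, {
    vapply(seq_len(replicates), function(r) {
      donor <- sample.int(nrow(others), 1)
      count_patient_pairs(genes, others$hpo_terms[[donor]], cl, direct)
    }, integer(1))
  })
  tibble::tibble(
    patient_id = profile$patient_id[1],
    observed_pairs = observed,
    replicates = replicates,
    p = mean(null_counts >= observed)
  )
}

#' Permutation p-values for every patient in a cohort
#'
#' @param cohort A cohort tibble.
#' @inheritParams patient_null_pvalue
#' @return A tibble with one row per patient.
#' @export
cohort_pvalues <- function(cohort, clusters, predictions, network,
                           threshold = 0.05, replicates = 100, seed = 1) {
  purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    patient_null_pvalue(cohort[i, ], cohort, clusters, predictions, network,
                        threshold = threshold, replicates = replicates,
                        seed = derive_seed(seed, i))
  })
}
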