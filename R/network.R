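#' Hybrid gene-phenotype network snapshots
#'
#' A `bocc_network` is one time-stamped snapshot of the hybrid knowledge
#' network: genes from a protein-interaction graph, phenotype terms from the
#' Human Phenotype Ontology (HPO), and the gene-to-phenotype (g2p)
#' annotations that connect the two layers. It is a light container of two
#' tibbles: `nodes` (`id`, `kind`) and `edges` (`u`, `v`, `kind`, `weight`),
#' with edges stored undirected under a canonical `u < v` ordering.
#'
#' Node kind is determined by the identifier: ids matching the HPO pattern
#' `HP:NNNNNNN` are phenotypes, everything else is a gene symbol. Edge kind
#' follows from the endpoint kinds: `g2g` (gene-gene), `p2p`
#' (phenotype-phenotype) or `g2p` (mixed).
#'
#' @param g2g,p2p,g2p Edge tibbles with columns `u`, `v` and optionally
#'   `weight` (missing weights become 0), as returned by
#'   [read_string_links()], [read_hpo_obo()] and [read_g2p_annotations()].
#'   Any of them may have zero rows.
#' @param timestamp Opaque snapshot label (e.g. `"2019"`). Snapshots in a
#'   series are ordered lexicographically by this label.
#' @return A `bocc_network` object.
#' @examples
#' g2g <- tibble::tibble(u = "GRIN2B", v = "NBEA", weight = 900)
#' p2p <- tibble::tibble(u = "HP:0001250", v = "HP:0000118")
#' g2p <- tibble::tibble(u = "GRIN2B", v = "HP:0001250")
#' net <- build_snapshot(g2g, p2p, g2p, timestamp = "2019")
#' net
#' @export
build_snapshot <- function(g2g, p2p, g2p, timestamp = "t0") {
  g2g <- normalize_edge_tbl(g2g, "g2g")
  p2p <- normalize_edge_tbl(p2p, "p2p")
  g2p <- normalize_edge_tbl(g2p, "g2p")

  bad_g2g <- is_hpo_id(g2g$u) | is_hpo_id(g2g$v)
  bad_p2p <- !is_hpo_id(p2p$u) | !is_hpo_id(p2p$v)
  bad_g2p <- is_hpo_id(g2p$u) == is_hpo_id(g2p$v)
  if (any(bad_g2g) || any(bad_p2p) || any(bad_g2p)) {
    offender <- c(g2g$u[bad_g2g], p2p$u[bad_p2p], g2p$u[bad_g2p])[1]
    stop("identifier used with inconsistent node kinds near '", offender,
         "': g2g endpoints must be gene symbols, p2p endpoints HP: terms, ",
         "g2p edges exactly one of each", call. = FALSE)
  }

  edges <- dplyr::bind_rows(g2g, p2p, g2p)
  edges <- canonicalize_edges(edges)
  edges <- dplyr::distinct(edges, .data$u, .data$v, .keep_all = TRUE)

  ids <- sort(unique(c(edges$u, edges$v)))
  nodes <- tibble::tibble(
    id = ids,
    kind = dplyr::if_else(is_hpo_id(ids), "phenotype", "gene")
  )
  new_bocc_network(nodes, edges, timestamp)
}

new_bocc_network <- function(nodes, edges, timestamp) {
  structure(
    list(nodes = nodes, edges = edges, timestamp = as.character(timestamp)),
    class = "bocc_network"
  )
}

#' @export
print.bocc_network <- function(x, ...) {
  kinds <- table(factor(x$edges$kind, levels = c("g2g", "p2p", "g2p")))
  cat(sprintf(
    "<bocc_network '%s'> %d nodes (%d genes, %d phenotypes), %d edges (g2g %d, p2p %d, g2p %d)\n",
    x$timestamp, nrow(x$nodes),
    sum(x$nodes$kind == "gene"), sum(x$nodes$kind == "phenotype"),
    nrow(x$edges), kinds[["g2g"]], kinds[["p2p"]], kinds[["g2p"]]
  ))
  invisible(x)
}

is_hpo_id <- function(x) stringr::str_detect(x, "^HP:\\d+$")

normalize_edge_tbl <- function(tbl, kind) {
  if (is.null(tbl) || nrow(tbl) == 0) {
    return(tibble::tibble(u = character(), v = character(),
                          kind = character(), weight = double()))
  }
  stopifnot(all(c("u", "v") %in% names(tbl)))
  out <- tibble::tibble(
    u = as.character(tbl$u), v = as.character(tbl$v),
    kind = kind,
    weight = if ("weight" %in% names(tbl)) as.double(tbl$weight) else 0
  )
  out[out$u != out$v, ]
}

canonicalize_edges <- function(edges) {
  swap <- edges$u > edges$v
  tmp <- edges$u[swap]
  edges$u[swap] <- edges$v[swap]
  edges$v[swap] <- tmp
  dplyr::arrange(edges, .data$u, .data$v)
}

#' Convert a network snapshot to an igraph graph
#'
#' Vertices are added in sorted id order (so downstream community detection
#' has a reproducible vertex ordering) and carry a `kind` attribute; edge
#' `kind` and `weight` are kept as edge attributes. The graph is undirected
#' and simple.
#'
#' @param network A `bocc_network`.
#' @param weighted Keep the `weight` edge attribute under the name igraph
#'   treats as weights? Default `FALSE`: community detection in the pipeline
#'   runs on the unweighted topology, and confidence scores of 0 on
#'   ontology-derived edges would otherwise poison weighted algorithms.
#' @return An igraph object.
#' @export
as_igraph <- function(network, weighted = FALSE) {
  stopifnot(inherits(network, "bocc_network"))
  g <- igraph::graph_from_data_frame(
    d = network$edges[, c("u", "v", "kind")],
    directed = FALSE,
    vertices = network$nodes[, c("id", "kind")]
  )
  if (weighted) {
    igraph::E(g)$weight <- network$edges$weight
  }
  g
}

#' Read a STRING-style protein links table as gene-gene edges
#'
#' Parses a whitespace- or tab-delimited table of protein pairs with a
#' numeric confidence column (the layout of STRING's `protein.links` files:
#' `protein1 protein2 combined_score`), optionally translating protein
#' identifiers to gene symbols through an alias table. Self-loops are
#' dropped, reciprocal duplicates collapse to one undirected edge, and rows
#' below `min_confidence` are discarded.
#'
#' The confidence threshold defaults to 0 (keep everything): the pipeline's
#' reference network is closest to an unthresholded human STRING graph, and
#' the cutoff is a study-level choice, not a parser default.
#'
#' @param path Path to the links file. A header row is detected (and
#'   skipped) when its third field is not numeric.
#' @param min_confidence Minimum confidence score to keep (default 0).
#' @param aliases Optional identifier mapping: a two-column data frame
#'   (protein id, gene symbol) or a named character vector. Identifiers
#'   without a mapping are dropped and counted in a message; they are never
#'   guessed.
#' @return A tibble of deduplicated undirected `g2g` edges
#'   (`u`, `v`, `weight`).
#' @export
read_string_links <- function(path, min_confidence = 0, aliases = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(u = character(), v = character(), weight = double()))
  }
  fields <- stringr::str_split(trimws(lines), "\\s+")
  first_line <- 1L
  if (is.na(suppressWarnings(as.numeric(fields[[1]][3])))) first_line <- 2L

  n_fields <- lengths(fields)
  bad <- which(n_fields < 3)
  bad <- bad[bad >= first_line]
  if (length(bad) > 0) {
    stop("malformed STRING links row at line ", bad[1],
         ": expected at least 3 whitespace-delimited fields", call. = FALSE)
  }
  if (first_line > length(fields)) {
    return(tibble::tibble(u = character(), v = character(), weight = double()))
  }
  keep <- first_line:length(fields)
  u <- vapply(fields[keep], `[`, "", 1L)
  v <- vapply(fields[keep], `[`, "", 2L)
  score <- suppressWarnings(as.numeric(vapply(fields[keep], `[`, "", 3L)))
  if (anyNA(score)) {
    stop("malformed STRING links row at line ",
         keep[which(is.na(score))[1]],
         ": non-numeric confidence score", call. = FALSE)
  }

  if (!is.null(aliases)) {
    map <- if (is.data.frame(aliases)) {
      stats::setNames(as.character(aliases[[2]]), as.character(aliases[[1]]))
    } else {
      aliases
    }
    u_new <- unname(map[u])
    v_new <- unname(map[v])
    unmapped <- is.na(u_new) | is.na(v_new)
    if (any(unmapped)) {
      message(sum(unmapped), " link row(s) dropped: unmapped protein identifier")
    }
    u <- u_new[!unmapped]; v <- v_new[!unmapped]; score <- score[!unmapped]
  }

  edges <- tibble::tibble(u = u, v = v, weight = score)
  edges <- edges[edges$u != edges$v & edges$weight >= min_confidence, ]
  edges <- canonicalize_edges(edges)
  dplyr::distinct(edges, .data$u, .data$v, .keep_all = TRUE)
}

#' Read the Human Phenotype Ontology from an OBO file
#'
#' Minimal OBO parser covering what the pipeline consumes: `[Term]` stanzas
#' with `id:`, `name:`, `is_a:` and `is_obsolete:` tags. Obsolete terms are
#' excluded from nodes, edges and the parent map. Each `is_a` relation
#' yields one undirected `p2p` edge; the child-to-parent direction is
#' retained separately in `parents` because sub-ontology pruning needs it.
#'
#' @param path Path to an OBO file.
#' @return A list with `terms` (tibble: `id`, `name`), `edges` (tibble `u`,
#'   `v` of undirected is-a edges) and `parents` (tibble `id`, `parent`).
#' @export
read_hpo_obo <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "[Term]")
  if (length(starts) == 0) {
    stop("no [Term] stanzas found in OBO file '", path, "'", call. = FALSE)
  }
  block_starts <- which(stringr::str_detect(lines, "^\\["))
  ends <- vapply(starts, function(s) {
    nxt <- block_starts[block_starts > s]
    if (length(nxt) == 0) length(lines) else nxt[1] - 1L
  }, integer(1))

  parse_stanza <- function(s, e) {
    body <- lines[(s + 1):e]
    id <- stringr::str_match(body, "^id:\\s*(\\S+)")[, 2]
    id <- id[!is.na(id)]
    if (length(id) == 0) {
      stop("OBO [Term] stanza starting at line ", s, " has no id: tag",
           call. = FALSE)
    }
    name <- stringr::str_match(body, "^name:\\s*(.+)$")[, 2]
    name <- name[!is.na(name)]
    parents <- stringr::str_match(body, "^is_a:\\s*(\\S+)")[, 2]
    parents <- parents[!is.na(parents)]
    obsolete <- any(stringr::str_detect(body, "^is_obsolete:\\s*true"))
    list(id = id[1], name = if (length(name)) name[1] else NA_character_,
         parents = parents, obsolete = obsolete)
  }
  stanzas <- Map(parse_stanza, starts, ends)
  stanzas <- stanzas[!vapply(stanzas, `[[`, TRUE, "obsolete")]

  ids <- vapply(stanzas, `[[`, "", "id")
  terms <- tibble::tibble(
    id = ids,
    name = vapply(stanzas, `[[`, "", "name")
  )
  parents <- dplyr::bind_rows(lapply(stanzas, function(s) {
    if (length(s$parents) == 0) return(NULL)
    tibble::tibble(id = s$id, parent = s$parents)
  }))
  if (is.null(parents) || nrow(parents) == 0) {
    parents <- tibble::tibble(id = character(), parent = character())
  }
  # drop relations pointing at obsolete (hence absent) terms
  parents <- parents[parents$parent %in% ids, ]
  edges <- canonicalize_edges(
    tibble::tibble(u = parents$id, v = parents$parent)
  )
  edges <- dplyr::distinct(edges, .data$u, .data$v)
  list(terms = terms, edges = edges, parents = parents)
}

#' Prune the ontology to one sub-ontology root and its descendants
#'
#' Keeps exactly the root term and everything reachable from it downwards in
#' the is-a hierarchy, dropping all other terms and every edge incident to a
#' dropped term. With the default root HP:0000118 ("Phenotypic abnormality")
#' this removes the non-phenotype hub terms (modes of inheritance, clinical
#' modifiers, frequencies, ...) that would otherwise create uninformative
#' shortcuts through the network. A term reachable both from the root and
#' from a removed branch is kept: the test is descent from the root, not
#' exclusive descent.
#'
#' @param terms,edges,parents As returned by [read_hpo_obo()].
#' @param root Sub-ontology root term id (default `"HP:0000118"`).
#' @return A list with pruned `terms` and `edges`.
#' @export
prune_to_phenotypic_abnormality <- function(terms, edges, parents,
                                            root = "HP:0000118") {
  if (!root %in% terms$id && !root %in% parents$parent) {
    stop("pruning root '", root, "' not present in the ontology", call. = FALSE)
  }
  children <- split(parents$id, parents$parent)
  keep <- character(0)
  frontier <- root
  seen <- new.env(parent = emptyenv())
  assign(root, TRUE, envir = seen)
  while (length(frontier) > 0) {
    keep <- c(keep, frontier)
    nxt <- unique(unlist(children[frontier], use.names = FALSE))
    nxt <- nxt[!vapply(nxt, exists, TRUE, envir = seen)]
    for (id in nxt) assign(id, TRUE, envir = seen)
    frontier <- nxt
  }
  keep <- unique(keep)
  list(
    terms = terms[terms$id %in% keep, ],
    edges = edges[edges$u %in% keep & edges$v %in% keep, ]
  )
}

#' Read gene-to-phenotype annotations
#'
#' Reads a tab-separated annotation table (as distributed with HPO by the
#' Monarch Initiative from OMIM/Orphanet) and keeps rows whose gene and
#' phenotype both survive in the supplied vocabularies, e.g. the genes of
#' the protein network and the pruned phenotype terms. Dropped rows are
#' counted in a message.
#'
#' @param path Path to a TSV file.
#' @param known_genes,known_phenotypes Character vectors of admissible gene
#'   symbols and HPO term ids, or `NULL` to keep all.
#' @param gene_col,hpo_col Column names holding the gene symbol and HPO term
#'   id.
#' @return A tibble of deduplicated `g2p` edges (`u` = gene, `v` = term).
#' @export
read_g2p_annotations <- function(path, known_genes = NULL,
                                 known_phenotypes = NULL,
                                 gene_col = "gene_symbol",
                                 hpo_col = "hpo_id") {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (!all(c(gene_col, hpo_col) %in% names(tbl))) {
    stop("annotation file '", path, "' lacks required column(s): ",
         paste(setdiff(c(gene_col, hpo_col), names(tbl)), collapse = ", "),
         call. = FALSE)
  }
  edges <- tibble::tibble(
    u = as.character(tbl[[gene_col]]),
    v = as.character(tbl[[hpo_col]])
  )
  n0 <- nrow(edges)
  if (!is.null(known_genes)) edges <- edges[edges$u %in% known_genes, ]
  if (!is.null(known_phenotypes)) edges <- edges[edges$v %in% known_phenotypes, ]
  if (nrow(edges) < n0) {
    message(n0 - nrow(edges),
            " annotation row(s) dropped: endpoint not in the pruned node sets")
  }
  dplyr::distinct(edges)
}

#' Edges new in a later snapshot between already-known nodes
#'
#' Returns the edges present in `later` but absent in `earlier` whose BOTH
#' endpoints already existed as nodes in `earlier` - i.e. the discoveries
#' that the earlier network could in principle have anticipated. Edges
#' touching a node that did not yet exist are excluded.
#'
#' The default keeps only gene-to-phenotype edges, the pipeline's unit of
#' rediscovery; pass `kinds = "all"` to count every edge kind.
#'
#' @param earlier,later `bocc_network` snapshots over the same identifier
#'   namespace.
#' @param kinds `"g2p"` (default), `"all"`, or a character vector of edge
#'   kinds.
#' @return A tibble of edges (`u`, `v`, `kind`, `weight`).
#' @export
new_edges_between <- function(earlier, later, kinds = "g2p") {
  stopifnot(inherits(earlier, "bocc_network"), inherits(later, "bocc_network"))
  if (identical(kinds, "all")) kinds <- c("g2g", "p2p", "g2p")
  cand <- later$edges[later$edges$kind %in% kinds, ]
  known <- cand$u %in% earlier$nodes$id & cand$v %in% earlier$nodes$id
  cand <- cand[known, ]
  old_keys <- paste(earlier$edges$u, earlier$edges$v)
  cand[!paste(cand$u, cand$v) %in% old_keys, ]
}

#' Serialize / restore a network snapshot
#'
#' Writes a snapshot as a gzipped edge-list TSV (`u`, `v`, `kind`, `weight`)
#' plus a plain node table (`id`, `kind`); `read_snapshot()` restores it
#' exactly (round-trip identical node and edge tables).
#'
#' @param network A `bocc_network`.
#' @param prefix File prefix; writes `<prefix>.edges.tsv.gz` and
#'   `<prefix>.nodes.tsv`.
#' @return `write_snapshot()` returns the prefix invisibly;
#'   `read_snapshot()` returns a `bocc_network`.
#' @export
write_snapshot <- function(network, prefix) {
  stopifnot(inherits(network, "bocc_network"))
  readr::write_tsv(network$edges, paste0(prefix, ".edges.tsv.gz"))
  nodes <- network$nodes
  nodes$timestamp <- network$timestamp
  readr::write_tsv(nodes, paste0(prefix, ".nodes.tsv"))
  invisible(prefix)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(prefix) {
  edges <- readr::read_tsv(paste0(prefix, ".edges.tsv.gz"),
                           col_types = "cccd", progress = FALSE)
  nodes <- readr::read_tsv(paste0(prefix, ".nodes.tsv"),
                           col_types = "ccc", progress = FALSE)
  timestamp <- unique(nodes$timestamp)[1]
  new_bocc_network(nodes[, c("id", "kind")], edges, timestamp)
}
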