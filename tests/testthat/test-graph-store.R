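test_that("STRING links parsing deduplicates, thresholds and maps aliases", {
  path <- withr_local_file("links.txt")
  writeLines(c("protein1 protein2 combined_score",
               "A B 900", "B A 900", "C C 700"), path)
  edges <- read_string_links(path)
  expect_equal(nrow(edges), 1)
  expect_equal(edges$u, "A")
  expect_equal(edges$v, "B")

  writeLines(c("A B 150", "A C 700"), path)
  edges <- read_string_links(path, min_confidence = 400)
  expect_equal(paste(edges$u, edges$v), "A C")

  # alias mapping drops unmapped identifiers, never guesses
  writeLines(c("9606.p1 9606.p2 500", "9606.p1 9606.p3 500"), path)
  aliases <- c("9606.p1" = "GENE1", "9606.p2" = "GENE2")
  expect_message(
    edges <- read_string_links(path, aliases = aliases),
    "1 link row"
  )
  expect_equal(paste(edges$u, edges$v), "GENE1 GENE2")
})

test_that("malformed STRING rows raise a parse error naming the line", {
  path <- withr_local_file("links.txt")
  writeLines(c("A B 900", "A B"), path)
  expect_error(read_string_links(path), "line 2")
  writeLines(c("A B 900", "A C high"), path)
  expect_error(read_string_links(path), "line 2.*non-numeric")
})

test_that("OBO parsing yields terms, is-a edges and a parent map", {
  path <- withr_local_file("hp.obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: HP:0000001", "name: All", "",
    "[Term]", "id: HP:0000002", "name: Child", "is_a: HP:0000001 ! All", "",
    "[Term]", "id: HP:0000003", "name: Gone", "is_obsolete: true", "",
    "[Typedef]", "id: part_of"
  ), path)
  obo <- read_hpo_obo(path)
  expect_setequal(obo$terms$id, c("HP:0000001", "HP:0000002"))
  expect_equal(nrow(obo$edges), 1)
  expect_equal(obo$parents$parent, "HP:0000001")
})

test_that("pruning keeps exactly the root's descendants", {
  path <- withr_local_file("hp.obo")
  writeLines(c(
    "[Term]", "id: HP:0000001", "name: All", "",
    "[Term]", "id: HP:0000118", "name: Phenotypic abnormality",
    "is_a: HP:0000001", "",
    "[Term]", "id: HP:0000007", "name: Mode of inheritance",
    "is_a: HP:0000001", "",
    "[Term]", "id: HP:0000010", "name: A", "is_a: HP:0000118", "",
    "[Term]", "id: HP:0000011", "name: B", "is_a: HP:0000010", "",
    # reachable from the root AND from a pruned branch: kept
    "[Term]", "id: HP:0000012", "name: Dual",
    "is_a: HP:0000010", "is_a: HP:0000007"
  ), path)
  obo <- read_hpo_obo(path)
  pruned <- prune_to_phenotypic_abnormality(obo$terms, obo$edges, obo$parents)
  expect_setequal(pruned$terms$id,
                  c("HP:0000118", "HP:0000010", "HP:0000011", "HP:0000012"))
  expect_false(any(pruned$edges$u == "HP:0000001" |
                     pruned$edges$v == "HP:0000001"))
  expect_error(
    prune_to_phenotypic_abnormality(obo$terms, obo$edges, obo$parents,
                                    root = "HP:9999999"),
    "root"
  )
})

test_that("pruning a random DAG matches brute-force reachability", {
  set.seed(31)
  n <- 50
  ids <- sprintf("HP:%07d", 1:n)
  # random DAG: each non-root term gets 1-2 parents among earlier terms
  parents <- dplyr::bind_rows(lapply(2:n, function(i) {
    k <- sample(1:2, 1)
    tibble::tibble(id = ids[i], parent = ids[sample(i - 1, min(k, i - 1))])
  }))
  terms <- tibble::tibble(id = ids, name = ids)
  edges <- tibble::tibble(u = pmin(parents$id, parents$parent),
                          v = pmax(parents$id, parents$parent))
  root <- ids[3]
  pruned <- prune_to_phenotypic_abnormality(terms, edges, parents, root = root)

  # oracle: transitive closure by iterating the child relation to fixpoint
  reach <- root
  repeat {
    more <- parents$id[parents$parent %in% reach]
    new <- setdiff(more, reach)
    if (length(new) == 0) break
    reach <- c(reach, new)
  }
  expect_setequal(pruned$terms$id, reach)
  # every surviving edge has both endpoints reachable
  expect_true(all(pruned$edges$u %in% reach & pruned$edges$v %in% reach))
})

test_that("g2p annotation loading restricts to known endpoints", {
  path <- withr_local_file("g2p.tsv")
  readr::write_tsv(tibble::tibble(
    gene_symbol = c("GRIN2B", "NBEA"),
    hpo_id = c("HP:0001250", "HP:0009999")
  ), path)
  expect_message(
    edges <- read_g2p_annotations(path, known_genes = c("GRIN2B", "NBEA"),
                                  known_phenotypes = "HP:0001250"),
    "1 annotation row"
  )
  expect_equal(nrow(edges), 1)
  expect_equal(edges$u, "GRIN2B")
  expect_error(
    read_g2p_annotations(path, gene_col = "nope"),
    "required column"
  )
})

test_that("build_snapshot forms a consistent typed union graph", {
  net <- make_net(
    g2g = tibble::tibble(u = "g1", v = "g2"),
    p2p = tibble::tibble(u = "HP:0000001", v = "HP:0000002"),
    g2p = tibble::tibble(u = "g1", v = "HP:0000001")
  )
  expect_equal(nrow(net$nodes), 4)
  expect_equal(sort(net$edges$kind), c("g2g", "g2p", "p2p"))

  # empty g2p layer is a valid degenerate input
  net2 <- make_net(g2g = tibble::tibble(u = "g1", v = "g2"))
  expect_equal(nrow(net2$edges), 1)

  # duplicate edge supplied in two sets is stored once
  net3 <- make_net(
    g2g = tibble::tibble(u = c("g1", "g2"), v = c("g2", "g1"))
  )
  expect_equal(nrow(net3$edges), 1)

  # edge-kind partition is exhaustive and disjoint
  fix <- generate_series(fixture_config(seed = 3))
  e <- fix$series[[1]]$edges
  expect_equal(nrow(e), sum(e$kind == "g2g") + sum(e$kind == "p2p") +
                 sum(e$kind == "g2p"))

  # an identifier cannot be both gene and phenotype
  expect_error(
    make_net(g2g = tibble::tibble(u = "HP:0000001", v = "g1")),
    "inconsistent node kinds"
  )
})

test_that("new_edges_between applies the node-presence rule", {
  earlier <- make_net(
    g2g = tibble::tibble(u = "g1", v = "g2"),
    g2p = tibble::tibble(u = "g1", v = "HP:0000001")
  )
  later <- make_net(
    g2g = tibble::tibble(u = "g1", v = "g2"),
    g2p = tibble::tibble(u = c("g1", "g2", "g1"),
                         v = c("HP:0000001", "HP:0000001", "HP:0000002")),
    ts = "t2"
  )
  # g1-HP:2 touches a node unknown to the earlier snapshot: excluded
  new_g2p <- new_edges_between(earlier, later, kinds = "g2p")
  expect_equal(nrow(new_g2p), 1)
  expect_setequal(c(new_g2p$u, new_g2p$v), c("g2", "HP:0000001"))
  # identity comparison yields nothing
  expect_equal(nrow(new_edges_between(earlier, earlier, kinds = "all")), 0)
})

test_that("snapshot serialization round-trips exactly", {
  fix <- generate_series(fixture_config(seed = 5))
  net <- fix$series[[1]]
  prefix <- file.path(withr_local_dir(), "snap")
  write_snapshot(net, prefix)
  back <- read_snapshot(prefix)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges, net$edges)
  expect_equal(back$timestamp, net$timestamp)
  # idempotence: serializing the restored snapshot changes nothing
  prefix2 <- file.path(withr_local_dir(), "snap2")
  write_snapshot(back, prefix2)
  again <- read_snapshot(prefix2)
  expect_equal(again$edges, net$edges)
})
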