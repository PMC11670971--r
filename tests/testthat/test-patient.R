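test_that("the variant selection formula is transcribed exactly", {
  v <- tibble::tibble(f = 0.005, i = FALSE, e = TRUE, s = FALSE,
                      c = TRUE, l = FALSE)
  expect_true(select_variant(v))
  v$f <- 0.02
  v$l <- TRUE
  expect_false(select_variant(v))  # frequency clause fails
  v2 <- tibble::tibble(f = NA_real_, i = TRUE, e = FALSE, s = TRUE,
                       c = FALSE, l = TRUE)
  expect_true(select_variant(v2))
})

test_that("the full 64-row truth table matches the literal formula", {
  grid <- tidyr::expand_grid(
    fcase = c(0.005, 0.02),
    i = c(TRUE, FALSE), e = c(TRUE, FALSE), s = c(TRUE, FALSE),
    c = c(TRUE, FALSE), l = c(TRUE, FALSE)
  )
  grid$f <- grid$fcase
  expect_equal(nrow(grid), 64)
  got <- select_variant(grid)
  oracle <- logical(64)
  for (r in 1:64) {
    oracle[r] <- (grid$f[r] < 0.01 || grid$i[r]) &&
      (grid$e[r] || grid$s[r]) && (grid$c[r] || grid$l[r])
  }
  expect_equal(got, oracle)

  # monotone in l and in i where the clause structure implies it
  for (r in which(!grid$l & got)) {
    flipped <- grid[r, ]
    flipped$l <- TRUE
    expect_true(select_variant(flipped))
  }
  for (r in which(!grid$i & got)) {
    flipped <- grid[r, ]
    flipped$i <- TRUE
    expect_true(select_variant(flipped))
  }
})

write_toy_vcf <- function(path, rows) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
    "##INFO=<ID=CLNSIG,Number=1,Type=String,Description=\"ClinVar\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  writeLines(c(header, rows), path)
}

test_that("VCF filtering extracts genes of passing variants", {
  path <- withr_local_file("toy.vcf")
  write_toy_vcf(path, c(
    # rare missense: passes
    "1\t100\t.\tA\tT\t50\tPASS\tGENE=GRIN2B;AF=0.001;CSQ=missense_variant",
    # common missense: frequency clause fails
    "1\t200\t.\tG\tC\t50\tPASS\tGENE=NBEA;AF=0.2;CSQ=missense_variant",
    # intergenic rare variant: location clause fails
    "1\t300\t.\tT\tA\t50\tPASS\tGENE=SCN2A;AF=0.001;CSQ=intergenic_variant"
  ))
  genes <- suppressMessages(filter_vcf(path))
  expect_equal(as.character(genes), "GRIN2B")
  expect_equal(attr(genes, "n_records"), 3L)
  expect_equal(attr(genes, "n_selected"), 1L)

  # missing AF counts as insufficient frequency; P/LP satisfies the
  # effect clause even for a synonymous change
  write_toy_vcf(path, c(
    "1\t100\t.\tA\tT\t50\tPASS\tGENE=TNNT3;CSQ=synonymous_variant;CLNSIG=Likely_pathogenic"
  ))
  genes <- suppressMessages(filter_vcf(path))
  expect_equal(as.character(genes), "TNNT3")

  empty <- withr_local_file("empty.vcf")
  write_toy_vcf(empty, character(0))
  expect_length(suppressWarnings(suppressMessages(filter_vcf(empty))), 0)
})

# A deterministic query world: clusters with known contents + predictions.
query_world <- function() {
  net <- make_net(
    g2g = tibble::tibble(u = c("g1", "g2"), v = c("g2", "g3")),
    p2p = tibble::tibble(u = "HP:0000001", v = "HP:0000002"),
    g2p = tibble::tibble(u = "g3", v = "HP:0000002")
  )
  clusters <- clusters_tbl(list(
    c("g1", "HP:0000001", "g2"),                # latent pair g1/g2 - HP:1
    c("g3", "HP:0000002"),                      # direct edge: excluded
    c("g1", "HP:0000001", "HP:0000002", "g3")   # two matching terms
  ))
  predictions <- tibble::tibble(
    cluster_id = rep(clusters$cluster_id, each = 2),
    threshold = rep(c(0.05, 0.35), 3),
    prob = 0.9,
    call = c(1, 1, 1, 1, 0, 1)  # cluster 3 significant only at 0.35
  )
  list(net = net, clusters = clusters, predictions = predictions)
}

test_that("co-occurrence search excludes direct edges and orders hits", {
  w <- query_world()
  profile <- patient_profile("P1", c("HP:0000001", "HP:0000002"),
                             c("g1", "g3"))
  hits <- find_cooccurrences(profile, w$clusters, w$predictions, w$net,
                             threshold = 0.35)
  # direct pair g3-HP:0000002 never appears
  expect_false(any(hits$gene == "g3" & hits$hpo_term == "HP:0000002"))
  # cluster 3 matches two terms: its hits come first
  expect_equal(hits$cluster_id[1], w$clusters$cluster_id[3])
  expect_equal(hits$n_matching_terms[1], 2L)

  # comparator oracle: explicit order() on the documented sort key
  ord <- order(-hits$n_matching_terms, hits$best_threshold, hits$cluster_id,
               hits$gene, hits$hpo_term)
  expect_equal(ord, seq_len(nrow(hits)))

  # restricting to the 0.05 predictions drops cluster 3
  hits05 <- find_cooccurrences(profile, w$clusters, w$predictions, w$net,
                               threshold = 0.05)
  expect_false(w$clusters$cluster_id[3] %in% hits05$cluster_id)

  # best_threshold is the smallest threshold predicting significance
  expect_equal(
    unique(hits$best_threshold[hits$cluster_id == w$clusters$cluster_id[3]]),
    0.35
  )
})

test_that("patient permutation p-values behave at the extremes", {
  w <- query_world()
  cohort <- dplyr::bind_rows(
    patient_profile("P1", c("HP:0000001", "HP:0000002"), c("g1", "g2")),
    patient_profile("P2", "HP:0000002", "g3"),
    patient_profile("P3", "HP:0000001", "g9")
  )
  # a patient with no co-occurring pairs has p = 1
  none <- patient_null_pvalue(cohort[3, ], cohort, w$clusters,
                              w$predictions, w$net, threshold = 0.35,
                              replicates = 50, seed = 1)
  expect_equal(none$observed_pairs, 0L)
  expect_equal(none$p, 1.0)
  expect_error(
    patient_null_pvalue(cohort[1, ], cohort[1, ], w$clusters, w$predictions,
                        w$net),
    "other patient"
  )
})

test_that("an engineered strong-signal patient is significant", {
  fix <- generate_series(fixture_config(seed = 111, enrichment = 25))
  net <- fix$series[[1]]
  clusters <- planted_clusters(fix)
  predictions <- tibble::tibble(
    cluster_id = clusters$cluster_id, threshold = 0.05, prob = 1, call = 1
  )
  # engineer the signal: genes and terms all from the first planted block,
  # embedded in an otherwise exchangeable cohort
  blocks <- fix$truth$blocks
  b <- min(blocks$block[blocks$signal])
  sig <- patient_profile(
    "SIG",
    utils::head(blocks$id[blocks$kind == "phenotype" & blocks$block == b], 5),
    utils::head(blocks$id[blocks$kind == "gene" & blocks$block == b], 5)
  )
  cohort <- dplyr::bind_rows(
    sig, generate_patient_cohort(fix, n_patients = 29, seed = 7)
  )
  res <- patient_null_pvalue(sig, cohort, clusters, predictions, net,
                             replicates = 100, seed = 3)
  expect_lte(res$p, 0.05)
  expect_gt(res$observed_pairs, 0)
})
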