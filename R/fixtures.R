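#' Configuration for the synthetic network generator
#'
#' The generator emulates the structural assumptions the pipeline relies on:
#' a two-layer (gene / phenotype) graph with planted community blocks, a
#' sparse gene-to-phenotype annotation layer, and a later snapshot that adds
#' new g2p edges preferentially inside designated "signal" blocks - the
#' synthetic analogue of curated disease modules that keep accruing
#' annotations. Signal blocks also carry a denser baseline annotation rate
#' (`signal_g2p_boost`), which is what gives cluster features predictive
#' power over future enrichment.
#'
#' @param n_genes,n_phenotypes Number of gene and phenotype nodes.
#' @param n_blocks Number of planted blocks; nodes of both kinds are spread
#'   over blocks evenly.
#' @param p_in,p_out Within- / between-block edge probability for same-kind
#'   (g2g, p2p) pairs.
#' @param g2p_rate Baseline within-block gene-phenotype annotation
#'   probability; between-block pairs use `g2p_rate * p_out / p_in`.
#' @param n_future_edges Number of new g2p edges added by the next snapshot.
#' @param enrichment Odds multiplier (>= 1) that a future g2p edge lands
#'   inside a signal block rather than on any other eligible pair;
#'   `enrichment = 1` places future edges uniformly over all eligible
#'   (non-adjacent gene-phenotype) pairs.
#' @param signal_blocks How many blocks are planted signal blocks.
#' @param signal_g2p_boost Multiplier on `g2p_rate` inside signal blocks.
#' @param hub_fraction,hub_factor A fraction of nodes receive an elevated
#'   expected degree (edge probabilities scaled by `hub_factor` per hub
#'   endpoint, capped at 1) so that hub handling is exercised.
#' @param n_snapshots Number of snapshots in the series (>= 2); each
#'   snapshot after the first adds `n_future_edges` further g2p edges
#'   cumulatively.
#' @param seed Integer seed; the series is fully reproducible from it.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_genes = 60, n_phenotypes = 60, n_blocks = 6,
                           p_in = 0.25, p_out = 0.015, g2p_rate = 0.08,
                           n_future_edges = 60, enrichment = 10,
                           signal_blocks = 2, signal_g2p_boost = 4,
                           hub_fraction = 0.05, hub_factor = 3,
                           n_snapshots = 2, seed = 1) {
  stopifnot(
    n_blocks >= 1, p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1,
    g2p_rate >= 0, g2p_rate <= 1, enrichment >= 1,
    signal_blocks >= 0, signal_blocks <= n_blocks, n_snapshots >= 2
  )
  structure(as.list(environment()), class = "fixture_config")
}

#' Generate a seeded series of synthetic network snapshots
#'
#' Builds the block-model hybrid network, then one or more later snapshots
#' each adding `n_future_edges` new g2p edges between already-present nodes,
#' placed with odds `enrichment` inside signal blocks. Ground truth (block
#' assignments, signal-block flags, planted future edges per horizon) is
#' returned for oracle tests.
#'
#' @param config A [fixture_config()].
#' @return A list with `series` (list of `bocc_network`, timestamps `"t1"`,
#'   `"t2"`, ...), `truth` (list: `blocks` tibble with `id`, `kind`,
#'   `block`, `signal`; `future_edges` tibble with `u`, `v`, `horizon`,
#'   `in_signal_block`) and `config`.
#' @export
generate_series <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  with_seed(config$seed, {
    genes <- sprintf("G%03d", seq_len(config$n_genes))
    phens <- sprintf("HP:%07d", seq_len(config$n_phenotypes))
    blocks <- tibble::tibble(
      id = c(genes, phens),
      kind = rep(c("gene", "phenotype"), c(config$n_genes, config$n_phenotypes)),
      block = c(
        rep_len(seq_len(config$n_blocks), config$n_genes),
        rep_len(seq_len(config$n_blocks), config$n_phenotypes)
      )
    )
    signal_ids <- seq_len(config$signal_blocks)
    blocks$signal <- blocks$block %in% signal_ids
    hub <- stats::runif(nrow(blocks)) < config$hub_fraction
    deg_factor <- ifelse(hub, config$hub_factor, 1)
    names(deg_factor) <- blocks$id
    block_of <- stats::setNames(blocks$block, blocks$id)

    pair_tbl <- function(a, b, same_kind) {
      if (same_kind) {
        idx <- utils::combn(length(a), 2)
        tibble::tibble(u = a[idx[1, ]], v = a[idx[2, ]])
      } else {
        tidyr::expand_grid(u = a, v = b)
      }
    }
    sample_edges <- function(pairs, p_same, p_diff, boost_signal = 1) {
      same <- block_of[pairs$u] == block_of[pairs$v]
      in_signal <- same & block_of[pairs$u] %in% signal_ids
      p <- ifelse(same, p_same, p_diff)
      p <- p * ifelse(in_signal, boost_signal, 1)
      p <- pmin(1, p * sqrt(deg_factor[pairs$u] * deg_factor[pairs$v]))
      pairs[stats::runif(nrow(pairs)) < p, c("u", "v")]
    }

    g2g <- sample_edges(pair_tbl(genes, NULL, TRUE), config$p_in, config$p_out)
    p2p <- sample_edges(pair_tbl(phens, NULL, TRUE), config$p_in, config$p_out)
    g2p_cross_rate <- config$g2p_rate *
      (if (config$p_in > 0) config$p_out / config$p_in else 0)
    g2p <- sample_edges(pair_tbl(genes, phens, FALSE),
                        config$g2p_rate, g2p_cross_rate,
                        boost_signal = config$signal_g2p_boost)

    base <- build_snapshot(g2g, p2p, g2p, timestamp = "t1")

    all_gp <- tidyr::expand_grid(u = genes, v = phens)
    existing <- paste(g2p$u, g2p$v)
    future <- list()
    series <- list(base)
    cum_g2p <- g2p
    for (h in seq_len(config$n_snapshots - 1)) {
      eligible <- all_gp[!paste(all_gp$u, all_gp$v) %in% existing, ]
      if (nrow(eligible) < config$n_future_edges) {
        stop("infeasible fixture: only ", nrow(eligible),
             " eligible gene-phenotype non-edges remain but ",
             config$n_future_edges, " future edges requested", call. = FALSE)
      }
      in_sig <- block_of[eligible$u] == block_of[eligible$v] &
        block_of[eligible$u] %in% signal_ids
      w <- ifelse(in_sig, config$enrichment, 1)
      pick <- sample.int(nrow(eligible), config$n_future_edges, prob = w)
      new <- eligible[pick, ]
      future[[h]] <- tibble::tibble(
        u = new$u, v = new$v, horizon = h, in_signal_block = in_sig[pick]
      )
      existing <- c(existing, paste(new$u, new$v))
      cum_g2p <- dplyr::bind_rows(cum_g2p, new[, c("u", "v")])
      series[[h + 1]] <- build_snapshot(g2g, p2p, cum_g2p,
                                        timestamp = paste0("t", h + 1))
    }

    list(
      series = series,
      truth = list(
        blocks = blocks,
        future_edges = dplyr::bind_rows(future)
      ),
      config = config
    )
  })
}

#' Planted block memberships as a cluster table
#'
#' Convenience accessor turning the generator's ground-truth block
#' assignment into the same tibble layout the clustering functions return,
#' so planted blocks can be fed to the rediscovery and null-model machinery
#' directly.
#'
#' @param fixture A value returned by [generate_series()].
#' @param signal_only Keep only planted signal blocks?
#' @return A cluster tibble (`cluster_id`, `algorithm`, `timestamp`,
#'   `members` list-column).
#' @export
planted_clusters <- function(fixture, signal_only = FALSE) {
  blocks <- fixture$truth$blocks
  if (signal_only) blocks <- blocks[blocks$signal, ]
  dplyr::group_by(blocks, .data$block) |>
    dplyr::summarise(members = list(.data$id), .groups = "drop") |>
    dplyr::transmute(
      cluster_id = sprintf("planted.%s:%d", fixture$series[[1]]$timestamp,
                           .data$block),
      algorithm = "planted",
      timestamp = fixture$series[[1]]$timestamp,
      members = .data$members
    )
}

#' Generate a synthetic patient cohort
#'
#' Patients carry a set of candidate genes and a set of HPO terms. Term
#' counts follow a truncated-geometric distribution with support 1-17 and
#' median 3 (the shape of real rare-disease phenotype profiles), assigned by
#' quantile matching so the cohort median is exact by construction. Signal
#' patients draw both genes and terms from one planted signal block, so
#' their gene-term pairs genuinely co-cluster; all other patients draw genes
#' and terms independently and are exchangeable (for calibration tests).
#'
#' @param fixture A value returned by [generate_series()].
#' @param n_patients Cohort size (>= 2).
#' @param signal_patients Number of patients with planted signal.
#' @param genes_per_patient Range of candidate-gene counts, drawn uniformly.
#' @param seed Integer seed.
#' @return A tibble with `patient_id`, `hpo_terms` and `candidate_genes`
#'   list-columns, `signal` flag and ground-truth `block`.
#' @export
generate_patient_cohort <- function(fixture, n_patients = 50,
                                    signal_patients = 0,
                                    genes_per_patient = c(2, 8),
                                    seed = 1) {
  stopifnot(n_patients >= 2, signal_patients <= n_patients)
  blocks <- fixture$truth$blocks
  genes <- blocks$id[blocks$kind == "gene"]
  phens <- blocks$id[blocks$kind == "phenotype"]
  with_seed(seed, {
    n_terms <- sample(term_count_quantiles(n_patients))
    signal <- c(rep(TRUE, signal_patients),
                rep(FALSE, n_patients - signal_patients))
    sig_blocks <- unique(blocks$block[blocks$signal])
    purrr::map_dfr(seq_len(n_patients), function(i) {
      ng <- sample(seq(genes_per_patient[1], genes_per_patient[2]), 1)
      if (signal[i] && length(sig_blocks) > 0) {
        b <- sample(sig_blocks, 1)
        gpool <- blocks$id[blocks$kind == "gene" & blocks$block == b]
        ppool <- blocks$id[blocks$kind == "phenotype" & blocks$block == b]
      } else {
        b <- NA_integer_
        gpool <- genes
        ppool <- phens
      }
      tibble::tibble(
        patient_id = sprintf("P%03d", i),
        hpo_terms = list(sample(ppool, min(n_terms[i], length(ppool)))),
        candidate_genes = list(sample(gpool, min(ng, length(gpool)))),
        signal = signal[i],
        block = b
      )
    })
  })
}

# Quantile-matched draw of HPO-term counts: truncated geometric on 1..17
# with decay 0.75, whose median is 3; evaluating its quantile function on a
# regular grid makes the sample median 3 exactly for even n >= 4.
term_count_quantiles <- function(n) {
  k <- 1:17
  w <- 0.75^(k - 1)
  cdf <- cumsum(w) / sum(w)
  probs <- (seq_len(n) - 0.5) / n
  vapply(probs, function(p) k[which(cdf >= p)[1]], integer(1))
}
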