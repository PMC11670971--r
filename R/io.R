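#' Read and write cluster tables
#'
#' Clusters are exchanged as TSV with columns `cluster_id`, `algorithm`,
#' `timestamp` and `member_ids` (comma-joined node ids); the round trip is
#' exact.
#'
#' @param clusters A cluster tibble (or list of them, bound together).
#' @param path Output / input file path.
#' @return `write_clusters()` the path invisibly; `read_clusters()` a
#'   cluster tibble.
#' @export
write_clusters <- function(clusters, path) {
  if (!is.data.frame(clusters)) clusters <- dplyr::bind_rows(clusters)
  out <- tibble::tibble(
    cluster_id = clusters$cluster_id,
    algorithm = clusters$algorithm,
    timestamp = clusters$timestamp,
    member_ids = vapply(clusters$members, paste, "", collapse = ",")
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  tbl <- readr::read_tsv(path, col_types = "cccc", progress = FALSE)
  tibble::tibble(
    cluster_id = tbl$cluster_id,
    algorithm = tbl$algorithm,
    timestamp = tbl$timestamp,
    members = stringr::str_split(tbl$member_ids, ",")
  )
}

#' Persist / restore a threshold model
#'
#' A model is stored as a directory: the serialized booster plus a JSON
#' sidecar with the threshold, feature list, hyperparameters and seeds.
#'
#' @param model A `bocc_model`.
#' @param dir Directory path (created if needed).
#' @return `save_model()` the directory invisibly; `load_model()` a
#'   `bocc_model`.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  xgboost::xgb.save(model$booster, file.path(dir, "booster.ubj"))
  meta <- model[setdiff(names(model), "booster")]
  meta$class_sizes <- as.list(meta$class_sizes)
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  booster <- xgboost::xgb.load(file.path(dir, "booster.ubj"))
  structure(list(
    booster = booster,
    threshold = meta$threshold,
    features = meta$features,
    hyperparams = as.list(meta$hyperparams),
    seed = meta$seed,
    class_sizes = unlist(meta$class_sizes),
    train_timestamps = meta$train_timestamps
  ), class = "bocc_model")
}
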