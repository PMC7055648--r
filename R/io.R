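# Plain-text serialization. Numeric values are written with 17 significant
# digits, which round-trips IEEE doubles exactly.

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

# jsonlite may simplify a list of length-3 numeric-string rows to a matrix;
# normalize either shape back to an n x 3 numeric matrix.
json_coord_matrix <- function(x) {
  if (is.list(x)) x <- do.call(rbind, x)
  matrix(as.numeric(x), ncol = 3)
}

#' Write / read a functional-connectivity network
#'
#' `write_fc_network()` writes `<prefix>.csv` (upper-triangle edge list
#' `i,j,weight`, 0-based node indices) and `<prefix>.json` (node count,
#' coordinates, condition, subject). The round trip through
#' `read_fc_network()` is exact.
#'
#' @param net An [fc_network()].
#' @param prefix Path prefix (without extension).
#' @return `write_fc_network()`: the prefix, invisibly. `read_fc_network()`:
#'   an [fc_network()].
#' @export
write_fc_network <- function(net, prefix) {
  stopifnot(inherits(net, "fc_network"))
  W <- net$weights
  up <- which(upper.tri(W), arr.ind = TRUE)
  df <- data.frame(i = up[, 1] - 1L, j = up[, 2] - 1L,
                   weight = fmt_num(W[up]))
  utils::write.csv(df, paste0(prefix, ".csv"), row.names = FALSE,
                   quote = FALSE)
  meta <- list(n_nodes = nrow(W), condition = net$condition,
               subject_id = net$subject_id)
  if (!is.null(net$coords))
    meta$coords <- apply(net$coords, 1, fmt_num, simplify = FALSE)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_fc_network
#' @export
read_fc_network <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(paste0(prefix, ".csv"),
                        colClasses = c("integer", "integer", "numeric"))
  n <- meta$n_nodes
  W <- matrix(0, n, n)
  W[cbind(df$i + 1L, df$j + 1L)] <- df$weight
  W <- W + t(W)
  coords <- if (!is.null(meta$coords)) json_coord_matrix(meta$coords)
  else NULL
  fc_network(W, coords = coords,
             condition = meta$condition %||% NA_character_,
             subject_id = meta$subject_id %||% NA_character_)
}

#' Write / read a module partition
#'
#' CSV with columns `node_id` (0-based) and `module_id` (1-based).
#'
#' @param partition A `partition` or label vector.
#' @param path CSV path.
#' @return `read_partition()` returns a `partition`.
#' @export
write_partition <- function(partition, path) {
  labels <- if (inherits(partition, "partition")) partition$labels
  else canonicalize_labels(partition)
  utils::write.csv(
    data.frame(node_id = seq_along(labels) - 1L, module_id = labels),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  df <- utils::read.csv(path, colClasses = c("integer", "integer"))
  new_partition(df$module_id[order(df$node_id)])
}

#' Write / read a parcellation
#'
#' `write_parcellation()` writes `<prefix>.csv` (`cell_id,subject_id,
#' parcel_id`, 0-based cells) and a JSON sidecar with parcel centroids,
#' hemisphere labels, homotopic map, and parameters. The round trip is
#' lossless for the fields needed by downstream analyses.
#'
#' @param parcellation A `parcellation` (see [run_parcellation()]).
#' @param prefix Path prefix.
#' @param subject_id Subject label written in the CSV.
#' @return `read_parcellation()` returns a `parcellation`.
#' @export
write_parcellation <- function(parcellation, prefix,
                               subject_id = "shared") {
  p <- parcellation
  utils::write.csv(
    data.frame(cell_id = seq_along(p$parcel_of_cell) - 1L,
               subject_id = subject_id, parcel_id = p$parcel_of_cell),
    paste0(prefix, ".csv"), row.names = FALSE, quote = FALSE)
  meta <- list(
    n_parcels = p$n_parcels,
    centroids = apply(p$parcel_centroids, 1, fmt_num, simplify = FALSE),
    hemisphere = p$parcel_hemisphere,
    homotopic_partner = p$homotopic_partner,
    parcel_functional = p$parcel_functional,
    params = p$params[c("k_spatial", "k_functional", "n_replicates",
                        "max_diameter", "min_gap", "seed")])
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  df <- utils::read.csv(paste0(prefix, ".csv"))
  base::structure(
    list(n_parcels = meta$n_parcels,
         parcel_of_cell = df$parcel_id[order(df$cell_id)],
         parcel_centroids = json_coord_matrix(meta$centroids),
         parcel_hemisphere = meta$hemisphere,
         homotopic_partner = meta$homotopic_partner,
         parcel_functional = meta$parcel_functional,
         cell_counts = tabulate(df$parcel_id, nbins = meta$n_parcels),
         params = do.call(parcellation_params, meta$params)),
    class = "parcellation")
}

#' Write / read a fluorescence recording
#'
#' `save_recording()` writes `<prefix>_traces.csv` (cells x frames, no
#' header) and `<prefix>.json` with `frame_rate`, `condition`, `subject_id`,
#' `n_cells`, `n_frames`. `load_recording()` validates the schema and names
#' any missing field in its error.
#'
#' @param recording A `fluorescence_recording`.
#' @param prefix Path prefix.
#' @return `load_recording()` returns a `fluorescence_recording`.
#' @export
save_recording <- function(recording, prefix) {
  stopifnot(inherits(recording, "fluorescence_recording"))
  utils::write.table(
    matrix(fmt_num(recording$traces), nrow(recording$traces)),
    paste0(prefix, "_traces.csv"), sep = ",", row.names = FALSE,
    col.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(frame_rate = recording$frame_rate, condition = recording$condition,
         subject_id = recording$subject_id,
         n_cells = nrow(recording$traces),
         n_frames = ncol(recording$traces)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname save_recording
#' @export
load_recording <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  required <- c("frame_rate", "condition", "subject_id", "n_cells",
                "n_frames")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop_mesoconn("recording schema is missing field(s): ",
                  paste(missing, collapse = ", "), class = "schema_error")
  traces <- as.matrix(utils::read.table(paste0(prefix, "_traces.csv"),
                                        sep = ",", header = FALSE))
  dimnames(traces) <- NULL
  if (nrow(traces) != meta$n_cells || ncol(traces) != meta$n_frames)
    stop_mesoconn("trace matrix shape does not match schema",
                  class = "schema_error")
  base::structure(
    list(traces = traces, frame_rate = meta$frame_rate,
         condition = meta$condition, subject_id = meta$subject_id),
    class = "fluorescence_recording")
}

#' Write / read a hierarchy as JSON
#'
#' @param hierarchy A `hierarchy` (see [consensus_hierarchy()]).
#' @param path JSON path.
#' @return `read_hierarchy()` returns a `hierarchy`.
#' @export
write_hierarchy <- function(hierarchy, path) {
  jsonlite::write_json(
    list(levels = lapply(hierarchy$levels, `[[`, "labels"),
         gamma_per_level = hierarchy$gamma_per_level,
         q_per_level = hierarchy$q_per_level,
         alpha = hierarchy$alpha,
         n_partitions = hierarchy$n_partitions),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hierarchy
#' @export
read_hierarchy <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lv <- x$levels
  if (is.matrix(lv)) lv <- lapply(seq_len(nrow(lv)), function(i) lv[i, ])
  base::structure(
    list(levels = lapply(lv, new_partition),
         gamma_per_level = x$gamma_per_level,
         q_per_level = x$q_per_level,
         alpha = x$alpha, n_partitions = x$n_partitions),
    class = "hierarchy")
}
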