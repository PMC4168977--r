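#' Export a cluster as Newick or JSON text
#'
#' Newick export writes the lineage tree with unit branch lengths (one
#' generation per mother-daughter edge) and tags dead cells in their node
#' labels (`c<id>` for living, `c<id>_dead` for dead cells). JSON export is
#' lossless: it round-trips through [cluster_from_json()] to an identical
#' cluster.
#'
#' @param cluster A `snowflake_cluster`.
#' @param format `"newick"` or `"json"`.
#' @return A single character string.
#' @examples
#' export_cluster(new_founder(0), "newick") # "c1:1;"
#' @export
export_cluster <- function(cluster, format = c("newick", "json")) {
  format <- match.arg(format)
  if (format == "json") return(cluster_to_json(cluster))
  cells <- cluster$cells
  lab <- paste0("c", cells$id, ifelse(cells$alive, "", "_dead"))
  kids_of <- split(seq_len(nrow(cells)), factor(cells$parent, levels = cells$id))
  # build node strings leaves-first so each node is assembled exactly once
  node_str <- character(nrow(cells))
  for (d in sort(unique(cells$shell), decreasing = TRUE)) {
    for (i in which(cells$shell == d)) {
      kid_rows <- kids_of[[as.character(cells$id[i])]]
      node_str[i] <- if (length(kid_rows)) {
        paste0("(", paste(node_str[kid_rows], collapse = ","), ")", lab[i], ":1")
      } else {
        paste0(lab[i], ":1")
      }
    }
  }
  paste0(node_str[.row_of(cluster, cluster$root_id)], ";")
}

#' Serialize a cluster to JSON
#'
#' @param cluster A `snowflake_cluster`.
#' @return A JSON string recording every cell field plus the root id and
#'   founding generation.
#' @export
cluster_to_json <- function(cluster) {
  jsonlite::toJSON(list(root_id = cluster$root_id,
                        founding_gen = cluster$founding_gen,
                        cells = cluster$cells),
                   auto_unbox = TRUE, digits = NA)
}

#' Rebuild a cluster from its JSON serialization
#'
#' @param txt JSON produced by [cluster_to_json()].
#' @return The reconstructed `snowflake_cluster`.
#' @export
cluster_from_json <- function(txt) {
  x <- jsonlite::fromJSON(txt)
  cells <- as.data.frame(x$cells)
  if (is.null(cells$parent)) cells$parent <- NA_integer_ # single-root clusters
  cells <- cells[, c("id", "parent", "birth_gen", "last_repro_gen",
                     "alive", "shell", "links_used")]
  for (col in c("id", "parent", "birth_gen", "last_repro_gen",
                "shell", "links_used")) {
    cells[[col]] <- as.integer(cells[[col]])
  }
  cells$alive <- as.logical(cells$alive)
  rownames(cells) <- NULL
  structure(list(cells = cells, root_id = as.integer(x$root_id),
                 founding_gen = as.integer(x$founding_gen)),
            class = "snowflake_cluster")
}

#' Write a simulation configuration to YAML
#'
#' @param config A [sim_config()] or [evo_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
config_to_yaml <- function(config, path) {
  lst <- unclass(config)
  lst$.class <- class(config)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' Round-trips bit-exactly with [config_to_yaml()].
#'
#' @param path YAML file written by [config_to_yaml()].
#' @return The restored `sim_config` or `evo_config`.
#' @export
config_from_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  cls <- lst$.class
  lst$.class <- NULL
  args <- lst
  if (identical(cls, "sim_config")) do.call(sim_config, args)
  else if (identical(cls, "evo_config")) do.call(evo_config, args)
  else stop("unrecognized config class in ", path)
}

#' Write a run manifest next to a results file
#'
#' Records the command, full configuration, master seed, package version and
#' timestamp needed to regenerate a results file (bit-for-bit for
#' deterministic operations, distributionally for stochastic ones).
#'
#' @param command Character label of the operation (e.g. a CLI subcommand).
#' @param config List or config object used for the run.
#' @param seed Master seed (may be `NULL`).
#' @param output Path of the results file the manifest describes.
#' @return The manifest path (`<output>.manifest.json`), invisibly.
#' @export
write_manifest <- function(command, config, seed, output) {
  manifest <- list(command = command,
                   config = unclass(config),
                   seed = seed,
                   package = "snowflaker",
                   version = as.character(utils::packageVersion("snowflaker")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   output = output)
  path <- paste0(output, ".manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}
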