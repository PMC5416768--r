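#' Read a regulator -> target edge list
#'
#' Tab-separated, two or more columns (regulator, target), `#` comment lines
#' and blank lines ignored. Edges are deduplicated. Node roles are inferred
#' (any node with an outgoing edge is a TF) unless a roles table overrides
#' them.
#'
#' @param path edge-list TSV.
#' @param roles_path optional TSV with columns `node`, `is_tf`
#'   (TRUE/FALSE or 1/0).
#' @return A [regnetwork].
#' @export
read_edge_list <- function(path, roles_path = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    stop_rs(sprintf("empty network: no edges in '%s'", path),
            "rs_empty_network")
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 2L)
  if (length(bad) > 0L) {
    stop_rs(sprintf("malformed edge line %d in '%s': %s",
                    lineno[bad[1L]], path, lines[bad[1L]]),
            "rs_parse_error")
  }
  edges <- data.frame(from = vapply(parts, `[[`, character(1), 1L),
                      to = vapply(parts, `[[`, character(1), 2L),
                      stringsAsFactors = FALSE)
  tf_nodes <- NULL
  nodes <- NULL
  if (!is.null(roles_path)) {
    roles <- utils::read.delim(roles_path, header = TRUE,
                               stringsAsFactors = FALSE)
    if (!all(c("node", "is_tf") %in% names(roles))) {
      stop_rs("roles file needs columns `node` and `is_tf`", "rs_parse_error")
    }
    tf_nodes <- roles$node[as.logical(roles$is_tf)]
    nodes <- roles$node
  }
  regnetwork(edges, nodes = nodes, tf_nodes = tf_nodes)
}

#' Write a network's edge list as TSV
#'
#' @param net a [regnetwork].
#' @param path output file.
#' @param roles_path optional path for a companion node-roles TSV.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path, roles_path = NULL) {
  writeLines(paste(net$edges$from, net$edges$to, sep = "\t"), path)
  if (!is.null(roles_path)) {
    utils::write.table(
      data.frame(node = net$nodes, is_tf = unname(net$is_tf[net$nodes])),
      roles_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read plate-screen measurements from CSV
#'
#' Expects the exact header `plate,well,clone,signal,growth,round`.
#' Validates types, non-negativity of signal and growth, and uniqueness of
#' (plate, well, round); violations raise an error naming the offending row.
#'
#' @param path CSV file.
#' @return Data frame of typed measurements.
#' @export
read_plate_csv <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  want <- c("plate", "well", "clone", "signal", "growth", "round")
  if (!identical(header, want)) {
    stop_rs(sprintf("plate CSV header must be '%s' (got '%s')",
                    paste(want, collapse = ","),
                    paste(header, collapse = ",")),
            "rs_parse_error")
  }
  dat <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "character",
                                        "numeric", "numeric", "integer"))
  bad <- which(is.na(dat$signal) | dat$signal < 0)
  if (length(bad) > 0L) {
    stop_rs(sprintf("row %d: signal must be non-negative", bad[1L]),
            "rs_validation")
  }
  bad <- which(is.na(dat$growth) | dat$growth < 0)
  if (length(bad) > 0L) {
    stop_rs(sprintf("row %d: growth must be non-negative", bad[1L]),
            "rs_validation")
  }
  bad <- which(is.na(dat$round) | dat$round < 1L)
  if (length(bad) > 0L) {
    stop_rs(sprintf("row %d: round must be a positive integer", bad[1L]),
            "rs_validation")
  }
  key <- paste(dat$plate, dat$well, dat$round, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop_rs(sprintf("row %d: duplicate (plate, well, round) = (%s, %s, %d)",
                    dup[1L], dat$plate[dup[1L]], dat$well[dup[1L]],
                    dat$round[dup[1L]]),
            "rs_validation")
  }
  dat
}

#' Write plate-screen measurements as CSV
#' @param measurements data frame with the standard plate columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(measurements, path) {
  utils::write.table(
    measurements[, c("plate", "well", "clone", "signal", "growth", "round")],
    path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a clone -> construct map (TSV)
#'
#' The in-silico stand-in for Sanger sequencing: columns `clone`, `promoter`,
#' `cds` (an optional `construct` column is rebuilt if absent).
#'
#' @param path TSV file.
#' @return Data frame with columns `clone`, `promoter`, `cds`, `construct`.
#' @export
read_clone_map <- function(path) {
  cm <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("clone", "promoter", "cds") %in% names(cm))) {
    stop_rs("clone map needs columns clone, promoter, cds", "rs_parse_error")
  }
  if (is.null(cm$construct)) cm$construct <- paste0(cm$promoter, "::", cm$cds)
  cm
}

#' @rdname read_clone_map
#' @param clone_map data frame to write.
#' @export
write_clone_map <- function(clone_map, path) {
  utils::write.table(clone_map[, c("clone", "promoter", "cds")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ortholog mapping table (TSV: source, target)
#' @param path TSV with two columns; a header line `source<TAB>target` is
#'   accepted and skipped.
#' @return Data frame with columns `source`, `target`.
#' @export
read_ortholog_table <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(tab) < 2L) {
    stop_rs("ortholog table needs two tab-separated columns", "rs_parse_error")
  }
  names(tab)[1:2] <- c("source", "target")
  if (nrow(tab) > 0L && identical(tolower(tab$source[1L]), "source")) {
    tab <- tab[-1L, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab[, c("source", "target")]
}

#' Read externally determined hierarchy levels (TSV: node, level)
#' @param path TSV with header `node<TAB>level`.
#' @return Data frame with columns `node`, `level`.
#' @export
read_levels_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("node", "level") %in% names(tab))) {
    stop_rs("levels file needs columns `node` and `level`", "rs_parse_error")
  }
  tab
}

#' Default configuration for the demo pipeline
#'
#' A small, fully simulated end-to-end run: a 200-gene / 40-TF synthetic
#' regulatory network, a 12 x 15 rewiring library whose CDSs are TF genes of
#' that network, five planted enhancer constructs (10-fold) whose CDSs are
#' the top TFs by betweenness, a 2x-coverage two-round screen, hit calling at
#' 2 SD then 1 SD, and topology enrichment of the hit CDSs.
#'
#' @param seed integer seed driving every stage.
#' @param out output directory for the artifacts.
#' @return A named list understood by [run_pipeline()].
#' @export
demo_config <- function(seed = 1, out = tempfile("rewire_demo_")) {
  list(
    seed = seed,
    out = out,
    network = list(n_nodes = 200, n_tfs = 40, mean_out_degree = 37.5),
    library = list(n_promoters = 12, n_cds = 15),
    planted = list(k = 5, metric = "betweenness", bias = 1, fold = 10),
    screen = list(coverage = 2, wells_per_plate = 96, baseline = 1000,
                  well_cv = 0.2, plate_sd = 0.1, growth_mean = 0.5,
                  growth_cv = 0.2),
    thresholds = c(2, 1),
    mode = "fluorescence",
    metrics = c("out_degree", "betweenness", "clustering", "eccentricity",
                "hierarchy")
  )
}

#' Run the full simulate -> screen -> netstats -> enrich pipeline
#'
#' Executes the demo pipeline described by a configuration list (see
#' [demo_config()]) or a JSON config file: simulates a regulatory network and
#' a rewiring screen with planted enhancer constructs, calls hits with the
#' multi-round outlier pipeline, computes per-node topology metrics, tests
#' the hit CDSs for topological enrichment, and writes all artifacts plus a
#' provenance manifest to the output directory. Everything is determined by
#' `config$seed`.
#'
#' Artifacts written: `plates.csv`, `clone_map.tsv`, `edges.tsv`,
#' `truth.json`, `hits.tsv`, `tally.tsv`, `node_metrics.tsv`,
#' `enrichment.tsv`, `manifest.json`.
#'
#' @param config named list or path to a JSON file.
#' @return Invisibly, a list with the in-memory results (`network`, `sim`,
#'   `hit_set`, `metrics`, `enrichment`, `out`).
#' @export
run_pipeline <- function(config = demo_config()) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  for (field in c("seed", "out", "network", "library", "planted", "screen",
                  "thresholds")) {
    if (is.null(config[[field]])) {
      stop_rs(sprintf("config is missing field `%s`", field), "rs_validation")
    }
  }
  seed <- assert_seed(config$seed)
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  # stage 1: synthetic network + library with planted enhancers
  nw <- config$network
  net <- simulate_regnet(nw$n_nodes, nw$n_tfs, nw$mean_out_degree,
                         seed = seed)
  pl <- config$planted
  hit_truth <- plant_hit_tfs(net, pl$metric, pl$k, pl$bias, seed = seed + 1L)
  tfs <- net$nodes[net$is_tf[net$nodes]]
  n_cds <- config$library$n_cds
  if (pl$k > n_cds || pl$k > config$library$n_promoters) {
    stop_rs("planted k must not exceed the library promoter or CDS count",
            "rs_validation")
  }
  set.seed(seed + 2L)
  cds_ids <- sort(c(hit_truth, sample(setdiff(tfs, hit_truth),
                                      n_cds - pl$k)))
  design <- make_library_design(config$library$n_promoters, n_cds,
                                cds_ids = cds_ids)
  # plant one enhancer construct per hit TF (distinct promoters), keeping
  # enhancers a small minority of the library as in a real screen
  enhanced <- paste0(design$promoters[seq_along(hit_truth)], "::", hit_truth)
  sc <- config$screen
  truth <- screen_ground_truth(
    design,
    fold_effects = stats::setNames(rep(pl$fold, length(enhanced)), enhanced),
    baseline = sc$baseline, well_cv = sc$well_cv, plate_sd = sc$plate_sd,
    growth_mean = sc$growth_mean, growth_cv = sc$growth_cv)
  sim <- simulate_screen(design, truth, coverage = sc$coverage,
                         wells_per_plate = sc$wells_per_plate,
                         n_rounds = length(config$thresholds),
                         seed = seed + 3L)
  write_plate_csv(sim$measurements, file.path(out, "plates.csv"))
  write_clone_map(sim$clone_map, file.path(out, "clone_map.tsv"))
  write_edge_list(net, file.path(out, "edges.tsv"),
                  roles_path = file.path(out, "node_roles.tsv"))
  jsonlite::write_json(list(seed = seed, planted_tfs = hit_truth,
                            planted_fold = pl$fold,
                            enhanced_constructs = enhanced),
                       file.path(out, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  # stage 2: hit calling
  hs <- run_screen_rounds(sim$measurements, sim$clone_map,
                          thresholds = config$thresholds)
  utils::write.table(hs$z[hs$z$clone %in% hs$hits, , drop = FALSE],
                     file.path(out, "hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(hs$tally, file.path(out, "tally.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # stage 3: per-node topology metrics
  metrics <- config$metrics %||% c("out_degree", "betweenness", "clustering",
                                   "eccentricity", "hierarchy")
  mt <- node_metrics(net, metrics = metrics)
  utils::write.table(format(mt, digits = 12, trim = TRUE, scientific = FALSE),
                     file.path(out, "node_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # stage 4: enrichment of hit CDSs vs the TF background
  hit_cds <- unique(hs$tally$cds)
  enr <- NULL
  if (length(hit_cds) >= 2L) {
    enr <- topology_enrichment(net, hit_cds, metrics = metrics,
                               metrics_table = mt)
    utils::write.table(format(as.data.frame(enr), digits = 12, trim = TRUE),
                       file.path(out, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    warning("fewer than 2 hit CDSs; enrichment stage skipped", call. = FALSE)
  }

  manifest <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("rewirescreen")),
    stages = list(
      simulate = list(nodes = length(net$nodes), edges = nrow(net$edges),
                      clones = nrow(sim$clone_map),
                      measurements = nrow(sim$measurements)),
      screen = list(hits = length(hs$hits),
                    constructs = if (is.null(hs$tally)) 0L else nrow(hs$tally)),
      netstats = list(rows = nrow(mt)),
      enrich = list(rows = if (is.null(enr)) 0L else nrow(enr))
    )
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(network = net, sim = sim, hit_set = hs, metrics = mt,
                 enrichment = enr, out = out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
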