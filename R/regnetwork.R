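#' Directed transcriptional regulatory network
#'
#' Constructs a directed regulator -> target network from an edge table.
#' Nodes carry a transcription-factor (TF) flag; every edge must originate at
#' a TF. Duplicate edges are collapsed; self-loops (autoregulation) are kept
#' in storage but flagged and excluded from all topology metrics.
#'
#' @param edges a two-column data frame (or matrix) of character identifiers,
#'   first column the regulator, second the target.
#' @param nodes optional character vector of node identifiers; defaults to the
#'   union of edge endpoints. Extra entries become isolated nodes.
#' @param tf_nodes optional character vector naming the TF nodes. If `NULL`,
#'   roles are inferred: any node with at least one outgoing edge is a TF.
#'
#' @return An object of class `regnetwork`: a list with elements `nodes`
#'   (character), `is_tf` (named logical), `edges` (data frame with columns
#'   `from`, `to`), and `n_self_loops`.
#' @examples
#' net <- regnetwork(data.frame(from = c("tfA", "tfA"), to = c("g1", "g2")))
#' out_degree(net)
#' @export
regnetwork <- function(edges, nodes = NULL, tf_nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) {
    stop_rs("`edges` needs at least two columns (regulator, target)",
            "rs_invalid_parameter")
  }
  edges <- data.frame(from = as.character(edges[[1L]]),
                      to   = as.character(edges[[2L]]),
                      stringsAsFactors = FALSE)
  edges <- unique(edges)
  rownames(edges) <- NULL

  all_nodes <- unique(c(edges$from, edges$to, as.character(nodes)))
  if (length(all_nodes) == 0L) {
    stop_rs("network has no nodes", "rs_empty_network")
  }

  if (is.null(tf_nodes)) {
    tf_nodes <- unique(edges$from)
  } else {
    tf_nodes <- as.character(tf_nodes)
    missing_tf <- setdiff(tf_nodes, all_nodes)
    all_nodes <- c(all_nodes, missing_tf)
    bad <- setdiff(unique(edges$from), tf_nodes)
    if (length(bad) > 0L) {
      stop_rs(sprintf("edge sources are not all TFs: %s",
                      paste(utils::head(bad, 5L), collapse = ", ")),
              "rs_invalid_parameter")
    }
  }
  is_tf <- stats::setNames(all_nodes %in% tf_nodes, all_nodes)

  structure(
    list(nodes = all_nodes,
         is_tf = is_tf,
         edges = edges,
         n_self_loops = sum(edges$from == edges$to)),
    class = "regnetwork"
  )
}

#' @export
print.regnetwork <- function(x, ...) {
  cat(sprintf("Directed regulatory network: %d nodes (%d TFs), %d edges",
              length(x$nodes), sum(x$is_tf), nrow(x$edges)))
  if (x$n_self_loops > 0L) {
    cat(sprintf(" (%d self-loop%s, excluded from metrics)", x$n_self_loops,
                if (x$n_self_loops > 1L) "s" else ""))
  }
  cat("\n")
  invisible(x)
}

# Integer adjacency lists used by the metric implementations. Self-loops are
# dropped here, once, so every metric sees the same loop-free graph.
# mode "out": successors; "in": predecessors; "all": undirected projection
# (deduplicated union of in- and out-neighbours).
adjacency <- function(net, mode = c("out", "in", "all")) {
  mode <- match.arg(mode)
  n <- length(net$nodes)
  idx <- stats::setNames(seq_len(n), net$nodes)
  e <- net$edges[net$edges$from != net$edges$to, , drop = FALSE]
  from <- idx[e$from]
  to <- idx[e$to]
  adj <- rep(list(integer(0)), n)
  pairs <- switch(mode,
    out = list(from, to),
    `in` = list(to, from),
    all = list(c(from, to), c(to, from))
  )
  if (length(pairs[[1L]]) > 0L) {
    sp <- split(pairs[[2L]], pairs[[1L]])
    adj[as.integer(names(sp))] <- lapply(sp, function(v) sort(unique(v)))
  }
  list(adj = adj, n = n, ids = net$nodes, index = idx)
}
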