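#' Out-degree of every node
#'
#' Number of distinct outgoing regulatory edges per node. Self-loops are
#' excluded, so the sum of all out-degrees equals the number of non-loop
#' edges.
#'
#' @param net a [regnetwork].
#' @return A named integer vector over all nodes.
#' @export
out_degree <- function(net) {
  a <- adjacency(net, "out")
  stats::setNames(vapply(a$adj, length, integer(1)), a$ids)
}

#' Betweenness centrality (directed, unnormalized)
#'
#' For every node v, the sum over ordered pairs (s, t) with s != v != t of
#' sigma_st(v) / sigma_st, where sigma_st counts unweighted shortest directed
#' paths from s to t and sigma_st(v) those passing through v. Pairs with no
#' connecting path contribute zero. Computed with Brandes' single-source
#' BFS + dependency accumulation algorithm; values are raw pair counts, not
#' rescaled to \[0, 1\].
#'
#' @param net a [regnetwork].
#' @param directed follow edge direction (default); `FALSE` uses the
#'   undirected projection for a sensitivity analysis.
#' @return A named numeric vector over all nodes.
#' @references Brandes, U. (2001) A faster algorithm for betweenness
#'   centrality. Journal of Mathematical Sociology 25, 163-177.
#' @export
betweenness_centrality <- function(net, directed = TRUE) {
  a <- adjacency(net, if (directed) "out" else "all")
  n <- a$n
  adj <- a$adj
  bc <- numeric(n)
  for (s in seq_len(n)) {
    # BFS from s, recording path counts and predecessor lists
    dist <- rep(-1L, n)
    sigma <- numeric(n)
    preds <- rep(list(integer(0)), n)
    dist[s] <- 0L
    sigma[s] <- 1
    order_visited <- integer(n)
    head <- 1L; tail <- 1L
    order_visited[1L] <- s
    while (head <= tail) {
      v <- order_visited[head]; head <- head + 1L
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          tail <- tail + 1L
          order_visited[tail] <- w
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    # dependency back-propagation in reverse visit order
    delta <- numeric(n)
    if (tail > 1L) {
      for (i in seq.int(tail, 2L)) {
        w <- order_visited[i]
        coef <- (1 + delta[w]) / sigma[w]
        for (v in preds[[w]]) delta[v] <- delta[v] + sigma[v] * coef
      }
      visited <- order_visited[seq_len(tail)]
      bc[visited] <- bc[visited] + delta[visited]
      bc[s] <- bc[s] - delta[s]
    }
  }
  if (!directed) bc <- bc / 2
  stats::setNames(bc, a$ids)
}

#' Local clustering coefficient
#'
#' On the undirected projection of the network (the default, matching the
#' usual "how connected are a node's neighbours to each other" reading):
#' c(v) = 2 L(v) / (k (k - 1)) where k is the number of distinct neighbours
#' and L(v) the number of connected neighbour pairs. Nodes with fewer than two
#' neighbours take the value 0 by convention. With `directed = TRUE` the
#' numerator counts directed edges among neighbours out of k (k - 1) possible.
#'
#' @param net a [regnetwork].
#' @param directed count directed edges among neighbours instead of the
#'   undirected projection.
#' @return A named numeric vector in \[0, 1\] over all nodes.
#' @export
clustering_coefficient <- function(net, directed = FALSE) {
  und <- adjacency(net, "all")
  n <- und$n
  cc <- numeric(n)
  if (directed) {
    out_adj <- adjacency(net, "out")$adj
    # neighbour set is still the undirected one; links counted directed
    for (v in seq_len(n)) {
      nb <- und$adj[[v]]
      k <- length(nb)
      if (k < 2L) next
      links <- sum(vapply(nb, function(u) sum(out_adj[[u]] %in% nb), numeric(1)))
      cc[v] <- links / (k * (k - 1))
    }
  } else {
    for (v in seq_len(n)) {
      nb <- und$adj[[v]]
      k <- length(nb)
      if (k < 2L) next
      links <- sum(vapply(nb, function(u) sum(und$adj[[u]] %in% nb), numeric(1))) / 2
      cc[v] <- 2 * links / (k * (k - 1))
    }
  }
  stats::setNames(cc, und$ids)
}

#' Eccentricity (finite-reachable-set convention)
#'
#' ecc(v) = the maximum shortest-path distance from v to any node reachable
#' from v by directed BFS. Unreachable nodes are ignored rather than counted
#' as infinite; a node that reaches nothing (a sink) has eccentricity 0.
#'
#' @param net a [regnetwork].
#' @param directed follow edge direction (default) or use the undirected
#'   projection.
#' @return A named integer vector over all nodes.
#' @export
eccentricity <- function(net, directed = TRUE) {
  a <- adjacency(net, if (directed) "out" else "all")
  n <- a$n
  ecc <- integer(n)
  queue <- integer(n)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n)
    dist[s] <- 0L
    queue[1L] <- s
    head <- 1L; tail <- 1L
    maxd <- 0L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      for (w in a$adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          if (dist[w] > maxd) maxd <- dist[w]
          tail <- tail + 1L
          queue[tail] <- w
        }
      }
    }
    ecc[s] <- maxd
  }
  stats::setNames(ecc, a$ids)
}

# Iterative Kosaraju strongly-connected components on integer adjacency
# lists; returns an integer component label per node.
scc_components <- function(adj_out, adj_in, n) {
  # pass 1: DFS finishing order on the forward graph
  visited <- logical(n)
  finish <- integer(n)
  fcount <- 0L
  for (root in seq_len(n)) {
    if (visited[root]) next
    stack <- list(c(root, 0L))
    visited[root] <- TRUE
    while (length(stack) > 0L) {
      top <- stack[[length(stack)]]
      v <- top[1L]; i <- top[2L]
      nb <- adj_out[[v]]
      advanced <- FALSE
      while (i < length(nb)) {
        i <- i + 1L
        w <- nb[i]
        if (!visited[w]) {
          stack[[length(stack)]] <- c(v, i)
          stack[[length(stack) + 1L]] <- c(w, 0L)
          visited[w] <- TRUE
          advanced <- TRUE
          break
        }
      }
      if (!advanced) {
        fcount <- fcount + 1L
        finish[fcount] <- v
        stack[[length(stack)]] <- NULL
      }
    }
  }
  # pass 2: DFS on the reverse graph in decreasing finishing order
  comp <- integer(n)
  ncomp <- 0L
  for (v in rev(finish)) {
    if (comp[v] != 0L) next
    ncomp <- ncomp + 1L
    stack <- v
    comp[v] <- ncomp
    while (length(stack) > 0L) {
      u <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      for (w in adj_in[[u]]) {
        if (comp[w] == 0L) {
          comp[w] <- ncomp
          stack <- c(stack, w)
        }
      }
    }
  }
  comp
}

#' Regulatory hierarchy levels of transcription factors
#'
#' Assigns each TF a height in the TF-TF regulation hierarchy. The TF-TF
#' subnetwork (edges whose source and target are both TFs) is condensed into
#' its strongly connected components, guaranteeing a DAG, and then
#' level(v) = 1 + max level over v's TF targets outside its own component;
#' TFs that regulate no other TF sit at level 1 (the bottom). Higher level
#' means nearer the top of the regulatory cascade. Members of one strongly
#' connected component share a level.
#'
#' Alternatively, externally determined levels can be supplied and are
#' validated against the TF set and returned unchanged, preserving fidelity
#' when curated hierarchy assignments exist.
#'
#' @param net a [regnetwork].
#' @param external_levels optional data frame with columns `node` and `level`
#'   covering every TF in `net`.
#' @return A named integer vector over the TF nodes (1 = bottom).
#' @export
hierarchy_levels <- function(net, external_levels = NULL) {
  tfs <- net$nodes[net$is_tf[net$nodes]]
  if (!is.null(external_levels)) {
    external_levels <- as.data.frame(external_levels)
    if (!all(c("node", "level") %in% names(external_levels))) {
      stop_rs("external levels need columns `node` and `level`",
              "rs_invalid_parameter")
    }
    lv <- stats::setNames(as.integer(external_levels$level),
                          as.character(external_levels$node))
    missing <- setdiff(tfs, names(lv))
    if (length(missing) > 0L) {
      stop_rs(sprintf("external levels missing %d TF(s): %s",
                      length(missing),
                      paste(utils::head(missing, 10L), collapse = ", ")),
              "rs_validation")
    }
    return(lv[tfs])
  }
  if (length(tfs) == 0L) return(stats::setNames(integer(0), character(0)))

  # TF-TF subnetwork, self-loops dropped
  e <- net$edges
  e <- e[e$from %in% tfs & e$to %in% tfs & e$from != e$to, , drop = FALSE]
  idx <- stats::setNames(seq_along(tfs), tfs)
  n <- length(tfs)
  from <- idx[e$from]; to <- idx[e$to]
  adj_out <- rep(list(integer(0)), n)
  adj_in <- rep(list(integer(0)), n)
  if (nrow(e) > 0L) {
    sp <- split(to, from)
    adj_out[as.integer(names(sp))] <- lapply(sp, function(v) sort(unique(v)))
    sp <- split(from, to)
    adj_in[as.integer(names(sp))] <- lapply(sp, function(v) sort(unique(v)))
  }

  comp <- scc_components(adj_out, adj_in, n)
  ncomp <- max(comp)
  # condensation edges: component of source -> component of target
  if (nrow(e) > 0L) {
    ce <- unique(data.frame(from = comp[from], to = comp[to]))
    ce <- ce[ce$from != ce$to, , drop = FALSE]
  } else {
    ce <- data.frame(from = integer(0), to = integer(0))
  }
  comp_out <- rep(list(integer(0)), ncomp)
  if (nrow(ce) > 0L) {
    sp <- split(ce$to, ce$from)
    comp_out[as.integer(names(sp))] <- lapply(sp, identity)
  }
  # longest-path levels on the condensation DAG, memoised depth-first
  level <- rep(NA_integer_, ncomp)
  level_of <- function(c0) {
    stack <- c0
    while (length(stack) > 0L) {
      v <- stack[[length(stack)]]
      succ <- comp_out[[v]]
      unresolved <- succ[is.na(level[succ])]
      if (length(unresolved) > 0L) {
        stack <- c(stack, unresolved)
      } else {
        level[v] <<- if (length(succ) == 0L) 1L else 1L + max(level[succ])
        stack <- stack[-length(stack)]
      }
    }
    level[c0]
  }
  for (c0 in seq_len(ncomp)) if (is.na(level[c0])) level_of(c0)
  stats::setNames(level[comp], tfs)
}

#' Translate gene identifiers through an ortholog table
#'
#' Maps gene identifiers from the screened species onto the identifier space
#' of the reference network via a one-to-one correspondence table (e.g. an
#' Inparanoid-style best-ortholog mapping). Unmapped queries are reported,
#' never silently dropped.
#'
#' @param gene_ids character vector of query identifiers.
#' @param table data frame with columns `source` and `target` (one target per
#'   source).
#' @return A list with `mapped` (deduplicated character vector of translated
#'   identifiers, in first-appearance order) and `unmapped` (queries without a
#'   table entry, in input order).
#' @export
map_orthologs <- function(gene_ids, table) {
  table <- as.data.frame(table)
  if (ncol(table) < 2L) {
    stop_rs("ortholog table needs two columns (source, target)",
            "rs_invalid_parameter")
  }
  names(table)[1:2] <- c("source", "target")
  if (anyDuplicated(table$source)) {
    dup <- unique(table$source[duplicated(table$source)])
    stop_rs(sprintf("ortholog table maps source(s) to multiple targets: %s",
                    paste(utils::head(dup, 5L), collapse = ", ")),
            "rs_invalid_parameter")
  }
  gene_ids <- as.character(gene_ids)
  lut <- stats::setNames(as.character(table$target), as.character(table$source))
  hit <- gene_ids %in% names(lut)
  list(mapped = unique(unname(lut[gene_ids[hit]])),
       unmapped = gene_ids[!hit])
}

#' Per-node topology metric table
#'
#' Computes the requested topology metrics for every node of a network and
#' returns them as one data frame, ready for enrichment testing or export.
#' `hierarchy` is defined only for TF nodes; non-TF nodes get `NA` there.
#'
#' @param net a [regnetwork].
#' @param metrics character vector among `"out_degree"`, `"betweenness"`,
#'   `"clustering"`, `"eccentricity"`, `"hierarchy"`.
#' @param directed passed to the directional metrics.
#' @return A data frame with columns `node`, `is_tf` and one column per
#'   requested metric.
#' @export
node_metrics <- function(net,
                         metrics = c("out_degree", "betweenness", "clustering",
                                     "eccentricity", "hierarchy"),
                         directed = TRUE) {
  known <- c("out_degree", "betweenness", "clustering", "eccentricity",
             "hierarchy")
  bad <- setdiff(metrics, known)
  if (length(bad) > 0L) {
    stop_rs(sprintf("unknown metric(s): %s", paste(bad, collapse = ", ")),
            "rs_invalid_parameter")
  }
  out <- data.frame(node = net$nodes,
                    is_tf = unname(net$is_tf[net$nodes]),
                    stringsAsFactors = FALSE)
  for (m in metrics) {
    out[[m]] <- switch(m,
      out_degree = unname(out_degree(net)[out$node]),
      betweenness = unname(betweenness_centrality(net, directed)[out$node]),
      clustering = unname(clustering_coefficient(net)[out$node]),
      eccentricity = unname(eccentricity(net, directed)[out$node]),
      hierarchy = {
        lv <- hierarchy_levels(net)
        v <- rep(NA_integer_, nrow(out))
        v[match(names(lv), out$node)] <- unname(lv)
        v
      })
  }
  out
}
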