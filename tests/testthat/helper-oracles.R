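# Brute-force graph oracles, deliberately built on a different algorithm
# family than the package (dense matrix powers instead of BFS/Brandes):
# (A^L)[s, t] counts walks of length L, the minimal such L is the shortest
# path length, and the count at that L is the number of shortest paths
# (minimal-length walks cannot revisit a vertex).

# adjacency matrix (0/1, no self-loops) of a regnetwork
oracle_adj <- function(net, directed = TRUE) {
  ids <- net$nodes
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  e <- net$edges[net$edges$from != net$edges$to, , drop = FALSE]
  A[cbind(match(e$from, ids), match(e$to, ids))] <- 1
  if (!directed) A <- 1 * ((A + t(A)) > 0)
  A
}

# list(dist, sigma): shortest-path lengths (Inf if unreachable, 0 on the
# diagonal) and shortest-path counts
oracle_paths <- function(A) {
  n <- nrow(A)
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  diag(dist) <- 0
  diag(sigma) <- 1
  P <- diag(n)
  for (L in seq_len(n)) {
    P <- P %*% A
    new <- is.infinite(dist) & P > 0
    diag(new) <- FALSE
    dist[new] <- L
    sigma[new] <- P[new]
    if (!any(new)) break
  }
  list(dist = dist, sigma = sigma)
}

oracle_betweenness <- function(net, directed = TRUE) {
  A <- oracle_adj(net, directed)
  sp <- oracle_paths(A)
  n <- nrow(A)
  bc <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      if (s == v) next
      for (t in seq_len(n)) {
        if (t == v || t == s || is.infinite(sp$dist[s, t])) next
        if (sp$dist[s, v] + sp$dist[v, t] == sp$dist[s, t]) {
          bc[v] <- bc[v] + sp$sigma[s, v] * sp$sigma[v, t] / sp$sigma[s, t]
        }
      }
    }
  }
  if (!directed) bc <- bc / 2
  stats::setNames(bc, net$nodes)
}

oracle_eccentricity <- function(net, directed = TRUE) {
  d <- oracle_paths(oracle_adj(net, directed))$dist
  ecc <- apply(d, 1, function(row) {
    fin <- row[is.finite(row)]
    if (length(fin) == 0) 0 else max(fin)
  })
  stats::setNames(as.integer(ecc), net$nodes)
}

oracle_clustering <- function(net) {
  U <- oracle_adj(net, directed = FALSE)
  k <- rowSums(U)
  tri <- diag(U %*% U %*% U) # twice the triangle count at each node
  cc <- ifelse(k < 2, 0, tri / (k * (k - 1)))
  stats::setNames(cc, net$nodes)
}

# random directed graph (Erdos-Renyi on ordered pairs, no self-loops);
# roles inferred from out-edges, isolated nodes kept
random_dignet <- function(n, p, seed) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
  if (nrow(keep) == 0) keep <- pairs[1, , drop = FALSE]
  regnetwork(keep, nodes = ids)
}

# fraction of nodes in the largest weakly connected component
largest_weak_component_fraction <- function(net) {
  U <- oracle_adj(net, directed = FALSE)
  n <- nrow(U)
  R <- diag(n) + U
  for (i in seq_len(ceiling(log2(max(n, 2))))) R <- 1 * ((R %*% R) > 0)
  max(table(apply(R, 1, function(r) paste(which(r > 0), collapse = ","))) ) / n
}
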