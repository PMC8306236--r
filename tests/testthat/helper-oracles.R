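# Independent distance oracle: repeated breadth-first search on an
# adjacency list, no igraph involved.
bfs_distances <- function(g) {
  vn <- igraph::V(g)$name
  n <- length(vn)
  el <- igraph::as_edgelist(g)
  adj <- stats::setNames(vector("list", n), vn)
  for (i in seq_len(nrow(el))) {
    adj[[el[i, 1]]] <- c(adj[[el[i, 1]]], el[i, 2])
    adj[[el[i, 2]]] <- c(adj[[el[i, 2]]], el[i, 1])
  }
  d <- matrix(Inf, n, n, dimnames = list(vn, vn))
  for (s in vn) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier) > 0) {
      depth <- depth + 1
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[d[s, nxt] == Inf]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

oracle_centralities <- function(g) {
  d <- bfs_distances(g)
  diag(d) <- Inf
  n <- nrow(d)
  clo <- rowSums(ifelse(is.finite(d), 1 / d, 0))
  ec <- apply(d, 1, function(r) {
    f <- r[is.finite(r)]
    if (length(f) == 0) 0 else 1 / max(f)
  })
  rad <- numeric(n)
  comp <- igraph::components(g)$membership
  for (cid in unique(comp)) {
    mem <- which(comp == cid)
    if (length(mem) < 2) next
    dc <- d[mem, mem, drop = FALSE]
    delta <- max(dc[is.finite(dc)])
    for (k in seq_along(mem)) {
      rad[mem[k]] <- sum(delta + 1 - dc[k, -k]) / (length(mem) - 1)
    }
  }
  list(Clo = clo, EC = ec, Rad = stats::setNames(rad, rownames(d)))
}

# Exhaustive edge-percolation expectation (and second moment) for EPC.
epc_exhaustive <- function(g, p = 0.5) {
  m <- igraph::ecount(g)
  n <- igraph::vcount(g)
  ex <- numeric(n); ex2 <- numeric(n)
  for (mask in 0:(2^m - 1)) {
    keep <- as.logical(bitwAnd(mask, 2^(0:(m - 1))))
    prob <- p^sum(keep) * (1 - p)^(m - sum(keep))
    comp <- igraph::components(igraph::delete_edges(g, which(!keep)))
    size <- comp$csize[comp$membership]
    ex <- ex + prob * size
    ex2 <- ex2 + prob * size^2
  }
  list(mean = ex, var = ex2 - ex^2)
}


# Direct combinatorial oracle for the hypergeometric upper tail.
hyper_tail_oracle <- function(k, K, n, N) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

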