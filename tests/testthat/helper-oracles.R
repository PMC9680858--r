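# Independent brute-force oracles. These deliberately avoid the package's
# code paths: correlation by the textbook formula, ranks by sort-per-row,
# BFS by frontier expansion, Fisher p by binomial-coefficient enumeration,
# BH by the written-out step-up formula.

oracle_pearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

oracle_pcc_pvalue <- function(r, n) {
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

# per-row ranks by explicit sorting with fractional ties, then HRR/MR
oracle_scores <- function(pcc) {
  ng <- nrow(pcc)
  rk <- matrix(0, ng, ng, dimnames = dimnames(pcc))
  for (i in seq_len(ng)) {
    others <- setdiff(seq_len(ng), i)
    v <- pcc[i, others]
    v[is.na(v)] <- -Inf
    ord <- order(v, decreasing = TRUE)
    r <- numeric(length(v))
    pos <- 1L
    while (pos <= length(v)) {
      tied <- which(v == v[ord[pos]])
      r[tied] <- mean(seq(pos, pos + length(tied) - 1L))
      pos <- pos + length(tied)
    }
    rk[i, others] <- r
  }
  hrr <- matrix(0, ng, ng, dimnames = dimnames(pcc))
  mr <- hrr
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    if (i != j) {
      hrr[i, j] <- max(rk[i, j], rk[j, i])
      mr[i, j] <- sqrt(rk[i, j] * rk[j, i])
    }
  }
  list(rank = rk, hrr = hrr, mr = mr)
}

# unit-weight shortest paths by frontier expansion from a query set
oracle_bfs <- function(edges, nodes, queries) {
  adj <- lapply(setNames(nodes, nodes), function(n) {
    c(edges$to[edges$from == n], edges$from[edges$to == n])
  })
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  dist[queries] <- 0
  frontier <- queries
  d <- 0
  while (length(frontier) > 0L) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)),
                   names(dist)[is.finite(dist)])
    dist[nxt] <- d + 1
    frontier <- nxt
    d <- d + 1
  }
  dist
}

# two-sided Fisher p from binomial coefficients (no dhyper)
oracle_fisher <- function(k, K, n, N) {
  support <- max(0, n - (N - K)):min(n, K)
  lp <- lchoose(K, support) + lchoose(N - K, n - support) - lchoose(N, n)
  p_obs <- exp(lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n))
  min(1, sum(exp(lp)[exp(lp) <= p_obs * (1 + 1e-7)]))
}

# step-up BH written out directly
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# transitive closure of a parent list by repeated expansion
oracle_ancestors <- function(parents, term) {
  anc <- character()
  frontier <- parents[[term]]
  while (length(frontier) > 0L) {
    anc <- union(anc, frontier)
    frontier <- setdiff(unlist(parents[frontier], use.names = FALSE), anc)
  }
  anc
}

# membership-loop region assignment for set relations
oracle_regions <- function(sets) {
  universe <- unique(unlist(sets))
  assign <- vapply(universe, function(g) {
    paste(names(sets)[vapply(sets, function(s) g %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  table(assign)
}
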