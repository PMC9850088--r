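# independent brute-force oracles, deliberately naive implementations

# all-pairs unweighted shortest paths + path counts by Floyd-Warshall-style
# dynamic programming on the adjacency matrix; distinct from the package's
# igraph-backed code path.
oracle_centralities <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$a[i]; b <- net$edges$b[i]
    d[a, b] <- d[b, a] <- 1
  }
  adj <- d == 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  # shortest-path counts by layer counting over the exact distances
  cnt <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(n)) {
    cnt[i, i] <- 1
    for (j in order(d[i, ])) {
      if (j == i || !is.finite(d[i, j])) next
      pred <- which(adj[, j] & d[i, ] == d[i, j] - 1)
      cnt[i, j] <- sum(cnt[i, pred])
    }
  }
  degree <- vapply(nodes, function(v)
    sum(net$edges$a == v | net$edges$b == v), 0)
  closeness <- vapply(seq_len(n), function(i) {
    dd <- d[i, -i]
    if (n <= 1) return(0)
    sum(1 / dd[is.finite(dd) & dd > 0]) / (n - 1)
  }, 0)
  betweenness <- vapply(seq_len(n), function(v) {
    tot <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s >= t || s == v || t == v) next
      if (!is.finite(d[s, t]) || cnt[s, t] == 0) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t]) {
        tot <- tot + cnt[s, v] * cnt[v, t] / cnt[s, t]
      }
    }
    if (n > 2) tot / ((n - 1) * (n - 2) / 2) else 0
  }, 0)
  data.frame(node = nodes, degree = degree, closeness = closeness,
             betweenness = betweenness, stringsAsFactors = FALSE)[
               order(nodes), ]
}

random_network <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  cmb <- combn(nodes, 2)
  pick <- runif(ncol(cmb)) < p
  gene_network(data.frame(a = cmb[1, pick], b = cmb[2, pick],
                          confidence = 0.9), nodes = nodes)
}

# quadratic interval scans
oracle_neighbors <- function(lnc_ids, loci, window_bp) {
  res <- lapply(lnc_ids, function(id) {
    i <- match(id, loci$gene_id)
    hits <- character()
    for (j in seq_len(nrow(loci))) {
      if (j == i) next
      if (loci$biotype[j] != "pcg" || !loci$expressed[j]) next
      if (loci$chrom[j] != loci$chrom[i]) next
      if (loci$start[j] <= loci$end[i] + window_bp &&
          loci$end[j] >= loci$start[i] - window_bp) {
        hits <- c(hits, loci$gene_id[j])
      }
    }
    sort(hits)
  })
  names(res) <- lnc_ids
  res
}

oracle_risk_flagged <- function(gene_ids, loci, risk, window_bp) {
  flagged <- character()
  for (g in gene_ids) {
    i <- match(g, loci$gene_id)
    for (r in seq_len(nrow(risk))) {
      if (risk$chrom[r] != loci$chrom[i]) next
      dd <- max(max(loci$start[i], risk$start[r]) -
                  min(loci$end[i], risk$end[r]), 0)
      if (dd <= window_bp) {
        flagged <- c(flagged, g)
        break
      }
    }
  }
  sort(unique(flagged))
}

# exact hypergeometric upper tail via enumeration of binomial coefficients
oracle_hyper_tail <- function(N, K, n, k) {
  sum(vapply(k:min(n, K), function(j) {
    choose(K, j) * choose(N - K, n - j)
  }, 0)) / choose(N, n)
}
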