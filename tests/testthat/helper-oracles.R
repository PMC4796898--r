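# Independent brute-force oracles used to validate the package's
# implementations on small instances.

# Exact two-sided rank-sum p-value by enumerating every label assignment.
oracleWilcoxon <- function(x, y) {
  pooled <- c(x, y)
  N <- length(pooled)
  m <- length(x)
  r <- rank(pooled)
  sObs <- sum(r[seq_len(m)])
  idx <- combn(N, m)
  sums <- apply(idx, 2L, function(i) sum(r[i]))
  eps <- 1e-9
  pl <- mean(sums <= sObs + eps)
  pu <- mean(sums >= sObs - eps)
  min(1, 2 * min(pl, pu))
}

# Upper-tail over-representation p-value by enumerating every possible query
# draw of the same size from the universe.
oracleOra <- function(query, set, universe) {
  n <- length(query)
  k <- length(intersect(query, set))
  draws <- combn(length(universe), n)
  hits <- apply(draws, 2L, function(i) length(intersect(universe[i], set)))
  mean(hits >= k)
}

# All-pairs shortest-path betweenness and closeness by Floyd-Warshall path
# counting (no igraph).
oracleCentrality <- function(edgeFrom, edgeTo, nodes) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  cnt <- matrix(0, n, n, dimnames = list(nodes, nodes))
  diag(cnt) <- 1
  for (i in seq_along(edgeFrom)) {
    a <- edgeFrom[i]; b <- edgeTo[i]
    if (a == b) next
    d[a, b] <- d[b, a] <- 1
    cnt[a, b] <- cnt[b, a] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || i == k || j == k) next
    alt <- d[i, k] + d[k, j]
    if (alt < d[i, j]) {
      d[i, j] <- alt
      cnt[i, j] <- cnt[i, k] * cnt[k, j]
    } else if (is.finite(alt) && alt == d[i, j]) {
      cnt[i, j] <- cnt[i, j] + cnt[i, k] * cnt[k, j]
    }
  }
  # count shortest paths through v for every ordered pair, halve for undirected
  btw <- setNames(numeric(n), nodes)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s == t || s == v || t == v) next
      if (is.finite(d[s, t]) && d[s, v] + d[v, t] == d[s, t]) {
        tot <- tot + cnt[s, v] * cnt[v, t] / cnt[s, t]
      }
    }
    btw[v] <- tot / 2
  }
  btwNorm <- if (n > 2) btw / ((n - 1) * (n - 2) / 2) else btw * 0
  clo <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    r <- length(di) + 1L
    if (r <= 1L) return(0)
    ((r - 1) / sum(di)) * ((r - 1) / (n - 1))
  }, numeric(1L))
  data.frame(node = nodes, betweenness = unname(btwNorm),
             closeness = clo, stringsAsFactors = FALSE)
}

# Best joint up/down assignment of the free nodes by exhaustive search,
# maximizing the number of sign-consistent edges among determined nodes.
# Returns per-node decisions where the optimum is unique, NA otherwise.
oracleJointStates <- function(edges, fixedStates, freeNodes) {
  k <- length(freeNodes)
  best <- -Inf
  argmax <- list()
  for (mask in 0:(2^k - 1)) {
    st <- fixedStates
    bits <- as.integer(intToBits(mask))[seq_len(max(k, 1L))]
    st[freeNodes] <- ifelse(bits[seq_len(k)] == 1L, 1L, -1L)
    s <- st[edges$source]; t <- st[edges$target]
    score <- sum(t == edges$sign * s)
    if (score > best) {
      best <- score
      argmax <- list(st)
    } else if (score == best) {
      argmax <- c(argmax, list(st))
    }
  }
  per <- sapply(freeNodes, function(g) {
    v <- unique(vapply(argmax, `[[`, integer(1L), g))
    if (length(v) == 1L) v else NA_integer_
  })
  list(best = best, states = per)
}

# small random undirected edge list on n nodes
randomUndirectedEdges <- function(n, p) {
  nodes <- paste0("n", seq_len(n))
  pairs <- combn(n, 2L)
  keep <- runif(ncol(pairs)) < p
  data.frame(from = nodes[pairs[1L, keep]], to = nodes[pairs[2L, keep]],
             stringsAsFactors = FALSE)
}
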