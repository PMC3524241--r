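# Independent brute-force oracles used to validate the production
# implementations. These deliberately avoid igraph and the package's own
# graph code.

# random simple graph on n nodes: edge matrix (i < j per row)
rand_edges <- function(n, p = 0.3) {
  pairs <- t(utils::combn(n, 2))
  pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
}

adj_list <- function(n, edges) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# BFS from src: distances and shortest-path counts
bfs_sigma <- function(adj, n, src) {
  dist <- rep(Inf, n); sigma <- numeric(n)
  dist[src] <- 0; sigma[src] <- 1
  frontier <- src
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        nxt <- c(nxt, w)
      }
      if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

# exhaustive geodesic-enumeration betweenness: raw sums over unordered pairs
oracle_betweenness <- function(n, edges) {
  adj <- adj_list(n, edges)
  bf <- lapply(seq_len(n), function(s) bfs_sigma(adj, n, s))
  D <- t(vapply(bf, `[[`, numeric(n), "dist"))
  S <- t(vapply(bf, `[[`, numeric(n), "sigma"))
  nb <- numeric(n)
  eb <- numeric(nrow(edges))
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (is.infinite(D[s, t])) next
    tot <- S[s, t]
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (D[s, v] + D[v, t] == D[s, t])
        nb[v] <- nb[v] + S[s, v] * S[v, t] / tot
    }
    for (r in seq_len(nrow(edges))) {
      u <- edges[r, 1]; w <- edges[r, 2]
      thr <- 0
      if (D[s, u] + 1 + D[w, t] == D[s, t]) thr <- thr + S[s, u] * S[w, t]
      if (D[s, w] + 1 + D[u, t] == D[s, t]) thr <- thr + S[s, w] * S[u, t]
      eb[r] <- eb[r] + thr / tot
    }
  }
  list(nb = nb, eb = eb)
}

# O(n^3) triple scan for triangles
oracle_triangles <- function(n, edges) {
  A <- matrix(FALSE, n, n)
  A[edges] <- TRUE
  A[edges[, 2:1, drop = FALSE]] <- TRUE
  out <- NULL
  if (n >= 3) for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n)
    if (A[i, j] && A[i, k] && A[j, k]) out <- rbind(out, c(i, j, k))
  if (is.null(out)) matrix(integer(0), ncol = 3) else out
}

# union-find connected components over an edge list
oracle_components <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[as.character(x)]] != x) x <- parent[[as.character(x)]]
    x
  }
  for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1]); b <- find(edges[r, 2])
    if (a != b) parent[[as.character(a)]] <- b
  }
  split(nodes, vapply(nodes, find, numeric(1)))
}

# planted random "structure": a model with random far-apart residues plus
# engineered contacts, returned with its toy contact spec
rand_toy_model <- function(nres = 8, ncontacts = 3) {
  seqs <- paste(sample(setdiff(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "G"),
                       nres, replace = TRUE), collapse = "")
  pairs <- t(utils::combn(nres, 2))
  pairs <- pairs[pairs[, 2] - pairs[, 1] >= 2, , drop = FALSE]
  pick <- pairs[sample(nrow(pairs), min(ncontacts, nrow(pairs))), ,
                drop = FALSE]
  contacts <- data.frame(i = pick[, 1], j = pick[, 2],
                         n_pairs = sample(1:4, nrow(pick), replace = TRUE))
  path <- tempfile(fileext = ".pdb")
  make_toy_structure(seqs, contacts, path)
  list(model = read_structure(path), contacts = contacts, path = path)
}

# random gapped row for a model: place its residues into L columns
rand_gapped_row <- function(model, L) {
  n <- nchar(model$sequence)
  stopifnot(L >= n)
  cols <- sort(sample(L, n))
  row <- rep("-", L)
  row[cols] <- strsplit(model$sequence, "")[[1]]
  list(row = paste(row, collapse = ""), cols = cols)
}
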