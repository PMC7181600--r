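# shared fixtures and independent oracles, built in code

adj <- function(n, labels = NULL) {
  if (is.null(labels)) labels <- sprintf("b%02d_M", seq_len(n))
  matrix(0, n, n, dimnames = list(labels, labels))
}

path_graph <- function(labels = c("a_M", "b_M", "c_M")) {
  m <- adj(length(labels), labels)
  for (i in seq_len(length(labels) - 1))
    m[i, i + 1] <- m[i + 1, i] <- 1
  m
}

complete_graph <- function(n, labels = NULL) {
  m <- adj(n, labels)
  m[] <- 1
  diag(m) <- 0
  m
}

two_cliques <- function(k, bridge = TRUE) {
  # two k-cliques, optionally joined by one bridge edge
  m <- adj(2 * k)
  m[1:k, 1:k] <- 1
  m[(k + 1):(2 * k), (k + 1):(2 * k)] <- 1
  diag(m) <- 0
  if (bridge) m[k, k + 1] <- m[k + 1, k] <- 1
  m
}

random_connected_adj <- function(n, p = 0.35) {
  # rejection-sample a connected Erdos-Renyi graph
  repeat {
    m <- adj(n)
    up <- upper.tri(m)
    m[up] <- as.numeric(stats::runif(sum(up)) < p)
    m <- m + t(m)
    g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected")
    if (igraph::is_connected(g)) return(m)
  }
}

# ---- brute-force oracles ------------------------------------------------

oracle_clustering <- function(m) {
  # neighbour-triangle counting; degree<2 nodes contribute 0
  n <- nrow(m)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(m[i, ] == 1)
    if (length(nb) < 2) next
    pairs <- utils::combn(nb, 2)
    vals[i] <- mean(m[cbind(pairs[1, ], pairs[2, ])])
  }
  mean(vals)
}

oracle_mean_path <- function(m) {
  # all-pairs BFS
  n <- nrow(m)
  tot <- 0
  cnt <- 0
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in which(m[v, ] == 1)) if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
    tot <- tot + sum(dist[-s])
    cnt <- cnt + (n - 1)
  }
  tot / cnt
}

oracle_gtom1 <- function(m) {
  n <- nrow(m)
  t <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    shared <- sum(m[i, ] == 1 & m[j, ] == 1)
    t[i, j] <- (shared + m[i, j]) /
      (min(sum(m[i, ]), sum(m[j, ])) + 1 - m[i, j])
  }
  t
}

oracle_newman_q <- function(m, membership) {
  K <- sum(m) / 2
  deg <- rowSums(m)
  q <- 0
  for (s in unique(membership)) {
    ins <- membership == s
    q <- q + sum(m[ins, ins]) / 2 / K - (sum(deg[ins]) / (2 * K))^2
  }
  q
}

oracle_mwu_u <- function(x, y) {
  # exhaustive pairwise comparison count (ties count 1/2)
  sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

oracle_gower <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  rng <- apply(x, 2, function(col) diff(range(col)))
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- 0
    for (v in seq_len(p))
      if (rng[v] > 0) acc <- acc + abs(x[i, v] - x[j, v]) / rng[v]
    d[i, j] <- acc / p
  }
  d
}

procrustes_rms <- function(X, Y) {
  # least-squares superimposition of Y onto X (rotation/reflection +
  # translation), returning the RMS residual
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(t(Yc) %*% Xc)
  R <- s$u %*% t(s$v)
  sqrt(mean((Yc %*% R - Xc)^2))
}
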