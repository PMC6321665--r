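# Brute-force oracles and fixture builders shared across tests.

# --- exhaustive graph descriptor oracle (small graphs only) -----------------

# all simple paths between s and t in an adjacency matrix, by recursion
.all_paths <- function(adj, s, t) {
  n <- nrow(adj)
  paths <- list()
  recurse <- function(path) {
    last <- path[length(path)]
    if (last == t) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (v in which(adj[last, ] == 1)) {
      if (!(v %in% path)) recurse(c(path, v))
    }
  }
  recurse(s)
  paths
}

# betweenness / closeness / clustering coefficient by explicit shortest-path
# enumeration; mirrors the package's definitions but shares no code with it
bf_descriptors <- function(adj) {
  n <- nrow(adj)
  bn <- numeric(n); cl <- numeric(n); cc <- numeric(n)
  sp_len <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s >= t) next
      paths <- .all_paths(adj, s, t)
      if (!length(paths)) next
      lens <- vapply(paths, length, 1L) - 1L
      dmin <- min(lens)
      sp_len[s, t] <- sp_len[t, s] <- dmin
      shortest <- paths[lens == dmin]
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        through <- sum(vapply(shortest, function(p)
          v %in% p[-c(1, length(p))], TRUE))
        bn[v] <- bn[v] + through / length(shortest)
      }
    }
  }
  if (n >= 3) bn <- bn / (0.5 * n * (n - 1)) else bn <- rep(0, n)
  for (v in seq_len(n)) {
    d <- sp_len[v, -v]
    d <- d[is.finite(d)]
    cl[v] <- if (length(d)) length(d) / sum(d) else 0
    nb <- which(adj[v, ] == 1)
    k <- length(nb)
    cc[v] <- if (k < 2) 0 else
      sum(adj[nb, nb]) / 2 / (0.5 * k * (k - 1))
  }
  list(BN = bn, CL = cl, CC = cc)
}

# random connected-ish undirected graph on n nodes as adjacency matrix
random_adjacency <- function(n, p = 0.5) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
  adj
}

# wrap an adjacency matrix as a residue_graph (single chain, unit spacing)
graph_from_adjacency <- function(adj, kind = "hbond") {
  n <- nrow(adj)
  nodes <- data.frame(chain = "A", resno = seq_len(n), insert = "",
                      resid = "ALA",
                      res_key = paste0("A|", seq_len(n), "|"),
                      stringsAsFactors = FALSE)
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  edges <- if (nrow(idx)) data.frame(a = idx[, 1], b = idx[, 2],
                                     kind = kind, backbone = FALSE,
                                     sep = abs(idx[, 2] - idx[, 1]),
                                     stringsAsFactors = FALSE)
    else data.frame(a = integer(0), b = integer(0), kind = character(0),
                    backbone = logical(0), sep = integer(0))
  lvqfold:::.residue_graph(nodes, edges, "Plip")
}

# minimal structure from per-atom records
make_structure <- function(resno, resid, elety, xyz, chain = "A",
                           elesy = NULL) {
  if (is.null(elesy)) elesy <- substr(elety, 1, 1)
  lvqfold:::.protein_structure(data.frame(
    chain = rep_len(chain, length(resno)), resno = resno, insert = "",
    resid = resid, elety = elety, elesy = elesy,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE))
}

# pairwise-comparison auROC estimator: (concordant + 0.5 ties) / (n+ * n-)
concordance_auc <- function(scores, labels, positive = "EARLY") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  cmp <- outer(pos, neg, `-`)
  (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (length(pos) * length(neg))
}

# mean silhouette of a 2-class 2-d embedding (hand-rolled, euclidean)
mean_silhouette <- function(xy, labels) {
  d <- as.matrix(dist(xy))
  sil <- vapply(seq_len(nrow(xy)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(xy)) != i])
    b <- mean(d[i, !own])
    (b - a) / max(a, b)
  }, 0)
  mean(sil)
}

# standardized two-Gaussian training set in D dims, one informative dim
make_gaussian_xy <- function(n = 400, d = 2, mean_shift = 2, sd = 0.5,
                             seed = 1) {
  set.seed(seed)
  half <- n %/% 2
  x <- rbind(
    matrix(rnorm(half * d, 0, sd), ncol = d),
    matrix(rnorm((n - half) * d, 0, sd), ncol = d))
  x[seq_len(half), 1] <- x[seq_len(half), 1] - mean_shift
  x[(half + 1):n, 1] <- x[(half + 1):n, 1] + mean_shift
  list(x = x, labels = rep(c("EARLY", "LATE"), c(half, n - half)))
}
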