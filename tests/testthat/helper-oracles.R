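# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately naive (loops, enumeration, brute force)
# and must stay independent of the package implementation it checks.

# build a layer from an explicit matrix with default labels
mk_layer <- function(inc, name = "layer") {
  inc <- as.matrix(inc)
  if (is.null(rownames(inc))) rownames(inc) <- paste0("x", seq_len(nrow(inc)))
  if (is.null(colnames(inc))) colnames(inc) <- paste0("y", seq_len(ncol(inc)))
  bipartite_layer(inc, name = name)
}

mk_pair <- function(inc1, inc2, names = c("L1", "L2")) {
  multilayer_pair(mk_layer(inc1, names[1]), mk_layer(inc2, names[2]))
}

# random binary incidence with at least the possibility of zero rows/cols
random_layer <- function(m, p, density = 0.3, seed) {
  set.seed(seed)
  mk_layer(matrix(rbinom(m * p, 1, density), m, p))
}

# Eq.-by-term normalized mutual information oracle: explicit double loop
nmi_oracle <- function(N_ij) {
  N_ij <- as.matrix(N_ij)
  N <- sum(N_ij)
  Ni <- rowSums(N_ij); Nj <- colSums(N_ij)
  num <- 0
  for (i in seq_len(nrow(N_ij))) for (j in seq_len(ncol(N_ij))) {
    if (N_ij[i, j] > 0)
      num <- num - 2 * N_ij[i, j] * log(N_ij[i, j] * N / (Ni[i] * Nj[j]))
  }
  den <- 0
  for (i in seq_len(nrow(N_ij))) if (Ni[i] > 0) den <- den + Ni[i] * log(Ni[i] / N)
  for (j in seq_len(ncol(N_ij))) if (Nj[j] > 0) den <- den + Nj[j] * log(Nj[j] / N)
  if (den == 0) return(1)
  num / den
}

# modularity of a membership vector on a symmetric adjacency, by definition
q_oracle <- function(A, memb) {
  k <- rowSums(A); M <- sum(k) / 2
  if (M == 0) return(0)
  q <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(A))) {
    if (memb[i] == memb[j]) q <- q + A[i, j] - k[i] * k[j] / (2 * M)
  }
  unname(q / (2 * M))
}

# all set partitions of 1..n as membership vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, maxid) {
    if (length(prefix) == n) { out[[length(out) + 1L]] <<- prefix; return() }
    for (id in seq_len(maxid + 1L)) grow(c(prefix, id), max(maxid, id))
  }
  grow(integer(0), 0L)
  out
}

# brute-force best modularity over every partition of the nodes of A
best_q_bruteforce <- function(A) {
  parts <- all_partitions(nrow(A))
  best <- -Inf; best_part <- NULL
  for (p in parts) {
    q <- q_oracle(A, p)
    if (q > best) { best <- q; best_part <- p }
  }
  list(q = best, membership = best_part)
}

# enumerate all m x p binary matrices with given margins, as a list
enumerate_fixed_margin <- function(rd, cd) {
  m <- length(rd); p <- length(cd)
  cells <- expand.grid(rep(list(0:1), m * p))
  keep <- list()
  for (r in seq_len(nrow(cells))) {
    M <- matrix(as.numeric(cells[r, ]), m, p)
    if (all(rowSums(M) == rd) && all(colSums(M) == cd))
      keep[[length(keep) + 1L]] <- M
  }
  keep
}

# stable key for a binary matrix, to match draws against an enumeration
mat_key <- function(M) paste(as.integer(M), collapse = "")
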