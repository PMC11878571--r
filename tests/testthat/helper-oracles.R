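# Independent brute-force oracles: deliberately naive loop-based
# implementations, kept separate from the package's computational paths.

random_weighted_graph <- function(n, density = 0.6, wmax = 10) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < density) w[i, j] <- w[j, i] <- runif(1, 0.1, wmax)
  }
  w
}

oracle_strength <- function(w) {
  n <- nrow(w)
  s <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) s[i] <- s[i] + w[i, j]
  s
}

oracle_transitivity <- function(w) {
  n <- nrow(w)
  if (n < 3 || max(w) == 0) return(0)
  wn <- w / max(w)
  num <- 0
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    if (i != j && j != k && k != i)
      num <- num + (wn[i, j] * wn[j, k] * wn[k, i])^(1 / 3)
  denom <- 0
  for (i in 1:n) {
    k_i <- sum(w[i, ] > 0)
    denom <- denom + k_i * (k_i - 1)
  }
  if (denom == 0) return(0)
  num / denom
}

# All-pairs shortest paths by exhaustive relaxation (Floyd-Warshall) on
# lengths 1/w.
oracle_distances <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in 1:n) for (j in 1:n) if (i != j && w[i, j] > 0) d[i, j] <- 1 / w[i, j]
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_global_efficiency <- function(w) {
  n <- nrow(w)
  if (n < 2) return(0)
  d <- oracle_distances(w)
  tot <- 0
  for (i in 1:n) for (j in 1:n)
    if (i != j && is.finite(d[i, j])) tot <- tot + 1 / d[i, j]
  tot / (n * (n - 1))
}

oracle_local_efficiency <- function(w) {
  n <- nrow(w)
  sapply(1:n, function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(w[nb, nb, drop = FALSE])
  })
}

oracle_participation <- function(w, memb) {
  n <- nrow(w)
  pc <- numeric(n)
  for (i in 1:n) {
    k <- sum(w[i, ])
    if (k == 0) { pc[i] <- 0; next }
    acc <- 0
    for (s in unique(memb)) acc <- acc + (sum(w[i, memb == s]) / k)^2
    pc[i] <- 1 - acc
  }
  pc
}

oracle_eigencentrality <- function(w) {
  e <- eigen(w, symmetric = TRUE)
  v <- abs(e$vectors[, which.max(e$values)])
  v / sqrt(sum(v^2))
}

oracle_modularity_q <- function(w, memb, gamma = 1) {
  m2 <- sum(w)
  k <- rowSums(w)
  q <- 0
  n <- nrow(w)
  for (i in 1:n) for (j in 1:n)
    if (memb[i] == memb[j]) q <- q + w[i, j] - gamma * k[i] * k[j] / m2
  q / m2
}

# All set partitions of 1..n as membership vectors (restricted growth).
all_partitions <- function(n) {
  out <- list()
  rec <- function(memb, next_label) {
    i <- length(memb) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- memb; return() }
    for (lab in seq_len(next_label)) rec(c(memb, lab),
                                         max(next_label, lab + 1L))
  }
  rec(integer(), 1L)
  out
}

# Truncated-series average controllability: trace of
# sum_{t=0}^{T} A^t e_i e_i' (A')^t = sum_t ||A^t e_i||^2.
oracle_avg_ctrl_series <- function(a, terms = 500) {
  n <- nrow(a)
  sapply(1:n, function(i) {
    v <- numeric(n); v[i] <- 1
    tot <- 0
    for (t in 0:terms) { tot <- tot + sum(v^2); v <- a %*% v }
    tot
  })
}

oracle_modal_ctrl <- function(a) {
  e <- eigen(a, symmetric = TRUE)
  n <- nrow(a)
  phi <- numeric(n)
  for (i in 1:n) for (j in 1:n)
    phi[i] <- phi[i] + (1 - e$values[j]^2) * e$vectors[i, j]^2
  phi
}

# Exact two-sided signed-rank p by full enumeration over 2^n sign
# assignments of the ranked absolute differences.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- sapply(0:(2^n - 1), function(m) {
    signs <- as.integer(intToBits(m))[1:n]
    sum(r[signs == 1])
  })
  mu <- n * (n + 1) / 4
  # two-sided: as extreme or more extreme in either direction
  mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-12)
}
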