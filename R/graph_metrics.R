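# Weighted graph metrics on streamline-count connectomes. All functions
# accept either a connectome object or a bare symmetric matrix. Path-based
# measures map weight w to length 1/w (stronger connections are shorter),
# the standard convention for streamline counts.

as_adjacency <- function(x) {
  if (inherits(x, "connectome")) return(x$matrix)
  w <- as.matrix(x)
  if (nrow(w) != ncol(w)) stop("adjacency must be square", call. = FALSE)
  w
}

weighted_graph <- function(w) {
  igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Node strength (weighted degree)
#'
#' Total streamline weight attached to each node: the row sums of the
#' adjacency matrix.
#'
#' @param x A `connectome` or square symmetric matrix.
#' @return Numeric vector, one entry per parcel.
#' @export
node_strength <- function(x) {
  w <- as_adjacency(x)
  rowSums(w)
}

#' Mean degree of a weighted network
#'
#' Average weight of connections throughout the network: the mean of the
#' node strengths.
#'
#' @inheritParams node_strength
#' @return Scalar.
#' @export
mean_degree <- function(x) mean(node_strength(x))

#' Weighted transitivity
#'
#' Ratio of triangles to triplets, in the weighted (Onnela) formulation:
#' triangle intensities are geometric means of the three edge weights after
#' scaling by the maximum weight, and the denominator counts connected
#' triplets from the binary degree. Returns 0 when the network has no
#' triplets (fewer than 3 nodes, or no node with two neighbours).
#'
#' @inheritParams node_strength
#' @return Scalar in `[0, 1]`.
#' @export
transitivity_w <- function(x) {
  w <- as_adjacency(x)
  n <- nrow(w)
  if (n < 3L || max(w) == 0) return(0)
  a <- (w > 0) + 0
  k <- rowSums(a)
  denom <- sum(k * (k - 1))
  if (denom == 0) return(0)
  wn <- (w / max(w))^(1 / 3)
  cyc3 <- diag(wn %*% wn %*% wn)
  sum(cyc3) / denom
}

#' Louvain community structure and modularity
#'
#' Detects communities by Louvain optimization at resolution `gamma` and
#' returns both the partition and the Newman weighted modularity Q of that
#' partition. Louvain is stochastic; the partition is made deterministic by
#' seeding the RNG with `seed`.
#'
#' @inheritParams node_strength
#' @param gamma Resolution parameter (1 = classic modularity).
#' @param seed Integer seed controlling the Louvain sweep order.
#' @return List with `membership` (integer labels starting at 1),
#'   `q` (modularity of the partition), `gamma`, `seed`.
#' @export
modularity_louvain <- function(x, gamma = 1, seed = 1L) {
  w <- as_adjacency(x)
  if (sum(w) == 0) stop("empty network: total weight is zero", call. = FALSE)
  g <- weighted_graph(w)
  memb <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    igraph::membership(igraph::cluster_louvain(g, resolution = gamma))
  })
  memb <- as.integer(memb)
  list(membership = memb, q = modularity_q(w, memb, gamma = gamma),
       gamma = gamma, seed = as.integer(seed))
}

#' Newman weighted modularity of a given partition
#'
#' Q = (1/2m) * sum_ij (w_ij - gamma * k_i k_j / 2m) * [c_i == c_j].
#'
#' @inheritParams node_strength
#' @param membership Integer community label per node.
#' @param gamma Resolution parameter.
#' @return Scalar Q.
#' @export
modularity_q <- function(x, membership, gamma = 1) {
  w <- as_adjacency(x)
  m2 <- sum(w)
  if (m2 == 0) stop("empty network: total weight is zero", call. = FALSE)
  k <- rowSums(w)
  same <- outer(membership, membership, "==")
  sum((w - gamma * outer(k, k) / m2) * same) / m2
}

#' Global efficiency of a weighted network
#'
#' Mean over ordered node pairs of the inverse shortest-path length, with
#' edge length 1/weight; unreachable pairs contribute 0. A network with
#' fewer than two nodes has efficiency 0.
#'
#' @inheritParams node_strength
#' @return Scalar >= 0.
#' @export
global_efficiency <- function(x) {
  w <- as_adjacency(x)
  n <- nrow(w)
  if (n < 2L) return(0)
  if (all(w == 0)) return(0)
  g <- weighted_graph(w)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Participation coefficient
#'
#' Diversity of a node's intermodular connections:
#' `PC_i = 1 - sum_s (kappa_is / k_i)^2`, where `kappa_is` is node i's
#' strength into community s and `k_i` its total strength. Nodes with zero
#' strength get 0.
#'
#' @inheritParams node_strength
#' @param membership Integer community label per node.
#' @return Numeric vector in `[0, 1]`.
#' @export
participation_coefficient <- function(x, membership) {
  w <- as_adjacency(x)
  if (length(membership) != nrow(w))
    stop("membership must cover all parcels", call. = FALSE)
  k <- rowSums(w)
  comms <- sort(unique(membership))
  frac2 <- matrix(0, nrow(w), length(comms))
  for (j in seq_along(comms)) {
    idx <- membership == comms[j]
    frac2[, j] <- rowSums(w[, idx, drop = FALSE])
  }
  pc <- 1 - rowSums((frac2 / ifelse(k == 0, 1, k))^2)
  pc[k == 0] <- 0
  pc
}

#' Eigenvector centrality
#'
#' Principal eigenvector of the weight matrix, computed by power iteration,
#' returned with nonnegative entries and unit Euclidean norm. For a
#' disconnected network this is the centrality of the spectrally dominant
#' component (other components get 0).
#'
#' @inheritParams node_strength
#' @param tol Convergence tolerance on the iterate change.
#' @param max_iter Iteration cap.
#' @return Numeric vector with unit Euclidean norm.
#' @export
eigenvector_centrality <- function(x, tol = 1e-13, max_iter = 10000L) {
  w <- as_adjacency(x)
  if (all(w == 0)) stop("no edges: eigenvector centrality undefined",
                        call. = FALSE)
  n <- nrow(w)
  # Spectral shift makes the Perron eigenvalue strictly dominant, so the
  # iteration also converges on bipartite graphs (eigenvectors unchanged).
  ws <- w + diag(max(rowSums(w)), n)
  v <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    nv <- drop(ws %*% v)
    nrm <- sqrt(sum(nv^2))
    if (nrm == 0) break
    nv <- nv / nrm
    if (max(abs(nv - v)) < tol) { v <- nv; break }
    v <- nv
  }
  v <- abs(v)
  v / sqrt(sum(v^2))
}

#' Local efficiency
#'
#' For each node, the global efficiency of the weighted subgraph induced by
#' its neighbours; 0 for nodes with fewer than two neighbours.
#'
#' @inheritParams node_strength
#' @return Numeric vector >= 0.
#' @export
local_efficiency <- function(x) {
  w <- as_adjacency(x)
  n <- nrow(w)
  vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2L) return(0)
    global_efficiency(w[nb, nb, drop = FALSE])
  }, numeric(1))
}

#' All six global network measures
#'
#' Mean degree, transitivity, modularity Q, global efficiency, and the
#' means of nodal average and modal controllability.
#'
#' @inheritParams modularity_louvain
#' @return Named list with elements `mean_degree`, `transitivity`,
#'   `modularity_q`, `global_efficiency`, `mean_average_controllability`,
#'   `mean_modal_controllability`.
#' @export
global_metrics <- function(x, gamma = 1, seed = 1L) {
  w <- as_adjacency(x)
  if (sum(w) == 0) stop("empty network: total weight is zero", call. = FALSE)
  lv <- modularity_louvain(w, gamma = gamma, seed = seed)
  a <- normalize_adjacency(w)
  list(mean_degree = mean_degree(w),
       transitivity = transitivity_w(w),
       modularity_q = lv$q,
       global_efficiency = global_efficiency(w),
       mean_average_controllability =
         mean_controllability(average_controllability(a)),
       mean_modal_controllability =
         mean_controllability(modal_controllability(a)))
}

#' All six nodal network measures
#'
#' Strength, participation coefficient (communities from the same
#' connectome's Louvain partition), eigenvector centrality, local
#' efficiency, and average and modal controllability.
#'
#' @inheritParams modularity_louvain
#' @return Data frame with one row per parcel and columns `parcel_id`,
#'   `strength`, `participation`, `eigenvector`, `local_efficiency`,
#'   `average_controllability`, `modal_controllability`.
#' @export
nodal_metrics <- function(x, gamma = 1, seed = 1L) {
  w <- as_adjacency(x)
  ids <- if (inherits(x, "connectome")) x$parcel_ids
         else sprintf("parcel_%03d", seq_len(nrow(w)))
  lv <- modularity_louvain(w, gamma = gamma, seed = seed)
  a <- normalize_adjacency(w)
  data.frame(parcel_id = ids,
             strength = node_strength(w),
             participation = participation_coefficient(w, lv$membership),
             eigenvector = eigenvector_centrality(w),
             local_efficiency = local_efficiency(w),
             average_controllability = average_controllability(a),
             modal_controllability = modal_controllability(a),
             stringsAsFactors = FALSE)
}
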