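# Linear network control metrics under discrete-time dynamics
# x(t+1) = A x(t) + B u(t), with A the streamline adjacency scaled by
# 1/(1 + lambda_max) so its spectral radius is below 1, and B = e_i a
# single-node input. Both measures reduce to closed forms in the
# eigendecomposition of the symmetric A, which is how they are computed:
# one eigendecomposition serves every node.

#' Normalize a connectome adjacency into a stable system matrix
#'
#' Scales the weight matrix W by `1/(1 + lambda_max(W))`, where
#' `lambda_max` is the largest eigenvalue. For nonnegative symmetric W the
#' spectral radius equals `lambda_max`, so the result has spectral radius
#' strictly below 1 (an all-zero matrix maps to itself, radius 0).
#'
#' @param x A `connectome` or square symmetric nonnegative matrix.
#' @return A `system_matrix`: list with the scaled matrix `a` and
#'   `normalization_constant` (`1 + lambda_max`).
#' @export
normalize_adjacency <- function(x) {
  w <- as_adjacency(x)
  if (relative_asymmetry(w) > 1e-9)
    stop("system matrix must be symmetric", call. = FALSE)
  lam <- if (all(w == 0)) 0 else max(eigen(w, symmetric = TRUE,
                                           only.values = TRUE)$values)
  structure(list(a = w / (1 + lam), normalization_constant = 1 + lam),
            class = "system_matrix")
}

as_system <- function(a) {
  if (inherits(a, "system_matrix")) return(a$a)
  m <- as.matrix(a)
  if (nrow(m) != ncol(m) || relative_asymmetry(m) > 1e-9)
    stop("system matrix must be square and symmetric", call. = FALSE)
  m
}

system_eigen <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  if (max(abs(e$values)) >= 1)
    stop("system matrix has spectral radius >= 1: Gramian diverges",
         call. = FALSE)
  e
}

#' Average controllability per node
#'
#' Trace of the infinite-horizon discrete controllability Gramian
#' `W_i = sum_{t>=0} A^t e_i e_i' (A')^t` for single-node input at node i.
#' For symmetric A with eigenpairs `(lambda_j, v_j)` this is
#' `sum_j v_ij^2 / (1 - lambda_j^2)`, the solution of the discrete
#' Lyapunov equation. Every entry is at least 1 (the t = 0 identity term),
#' with equality exactly for isolated nodes.
#'
#' @param a A `system_matrix` (see [normalize_adjacency()]) or symmetric
#'   matrix with spectral radius below 1.
#' @return Numeric vector, one value >= 1 per node.
#' @export
average_controllability <- function(a) {
  m <- as_system(a)
  e <- system_eigen(m)
  drop((e$vectors^2) %*% (1 / (1 - e$values^2)))
}

#' Modal controllability per node
#'
#' `phi_i = sum_j (1 - lambda_j^2) v_ij^2` over the eigenpairs of the
#' symmetric system matrix: nodes that load onto fast-decaying (small
#' `|lambda|`) modes can push the system into difficult-to-reach states.
#' Values lie in `(0, 1]`, with 1 for isolated nodes.
#'
#' @inheritParams average_controllability
#' @return Numeric vector, one value per node.
#' @export
modal_controllability <- function(a) {
  m <- as_system(a)
  e <- system_eigen(m)
  drop((e$vectors^2) %*% (1 - e$values^2))
}

#' Mean of a nodal controllability vector
#'
#' @param values Nonempty numeric vector.
#' @return Arithmetic mean.
#' @export
mean_controllability <- function(values) {
  if (!length(values)) stop("empty controllability vector", call. = FALSE)
  mean(values)
}
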