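# Weighted graph properties of directed connectivity matrices: Onnela
# clustering coefficient, characteristic path length and Latora-Marchiori
# global/local efficiency on 1/w edge lengths.

#' Weighted graph properties of a connectivity matrix
#'
#' Computes the clustering coefficient (C), characteristic path length (L),
#' global efficiency (Ge) and local efficiency (Le) of a nonnegative weight
#' matrix. Higher C, Ge and Le indicate stronger connectivity; L has the
#' opposite relationship. The diagonal (self-flow) is zeroed on entry.
#'
#' Definitions (weights scaled by the matrix maximum for clustering; edge
#' lengths `1/w` for paths):
#' * C: mean over nodes of the Onnela geometric-mean triangle intensity
#'   `sum_{jk} (w_ij w_ik w_jk)^{1/3} / (k_i (k_i - 1))`; nodes with fewer
#'   than 2 neighbours contribute 0.
#' * L: mean shortest-path length over connected ordered pairs (disconnected
#'   pairs are excluded and counted; an edgeless graph reports `Inf`).
#' * Ge: mean of `1/d_ij` over all ordered pairs; disconnected pairs
#'   contribute 0.
#' * Le: mean over nodes of the global efficiency of the node's neighbourhood
#'   subgraph.
#'
#' @param w Square nonnegative weight matrix (`n >= 2`).
#' @param directed_handling `"symmetrize"` (default: metrics on
#'   `(w + t(w)) / 2`) or `"directed"` (directed paths and the Fagiolo
#'   directed clustering coefficient).
#' @return A `network_properties` list: `C`, `L`, `Ge`, `Le`, `n_nodes`,
#'   `n_connected_pairs`, `directed_handling`.
#' @export
graph_properties <- function(w, directed_handling = c("symmetrize", "directed")) {
  directed_handling <- match.arg(directed_handling)
  w <- as.matrix(w)
  n <- nrow(w)
  if (n != ncol(w)) stop_docnet("parameter", "weight matrix must be square")
  if (n < 2) stop_docnet("parameter", "need at least 2 nodes")
  if (any(w < 0)) stop_docnet("parameter", "weights must be nonnegative")
  diag(w) <- 0

  if (directed_handling == "symmetrize") {
    ws <- (w + t(w)) / 2
    C <- onnela_clustering(ws)
    d <- graph_distances(ws, directed = FALSE)
    Le <- local_efficiency(ws, directed = FALSE)
  } else {
    ws <- w
    C <- fagiolo_clustering(ws)
    d <- graph_distances(ws, directed = TRUE)
    Le <- local_efficiency(ws, directed = TRUE)
  }

  off <- upper.tri(d) | lower.tri(d)
  dv <- d[off]
  conn <- is.finite(dv)
  L <- if (any(conn)) mean(dv[conn]) else Inf
  Ge <- mean(ifelse(is.finite(dv), 1 / dv, 0))
  structure(list(C = C, L = L, Ge = Ge, Le = Le, n_nodes = n,
                 n_connected_pairs = sum(conn),
                 directed_handling = directed_handling),
            class = "network_properties")
}

#' @export
print.network_properties <- function(x, ...) {
  cat(sprintf("<network_properties> C=%.4f L=%s Ge=%.4f Le=%.4f (%d nodes, %s)\n",
              x$C, format(x$L, digits = 4), x$Ge, x$Le, x$n_nodes,
              x$directed_handling))
  invisible(x)
}

# All-pairs shortest path lengths on edge lengths 1/w (Dijkstra via igraph).
graph_distances <- function(w, directed) {
  n <- nrow(w)
  mode <- if (directed) "directed" else "undirected"
  g <- igraph::graph_from_adjacency_matrix(w, mode = mode, weighted = TRUE,
                                           diag = FALSE)
  if (igraph::ecount(g) == 0) {
    d <- matrix(Inf, n, n)
    diag(d) <- 0
    return(d)
  }
  igraph::distances(g, weights = 1 / igraph::E(g)$weight,
                    mode = if (directed) "out" else "all",
                    algorithm = "dijkstra")
}

# Onnela et al. weighted clustering on a symmetric matrix. Weights are
# expected in [0, 1] (ADTF weights are by construction); larger weights are
# rescaled by the maximum so triangle intensities stay in [0, 1]. Not
# rescaling already-normalized weights keeps C monotone in coupling
# strength.
onnela_clustering <- function(ws) {
  mx <- max(ws, 1)
  if (max(ws) == 0) return(0)
  W3 <- (ws / mx)^(1 / 3)
  num <- diag(W3 %*% W3 %*% W3)
  k <- rowSums(ws > 0)
  ci <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  mean(ci)
}

# Fagiolo directed weighted clustering (total clustering).
fagiolo_clustering <- function(w) {
  mx <- max(w, 1)
  if (max(w) == 0) return(0)
  W3 <- (w / mx)^(1 / 3)
  S <- W3 + t(W3)
  num <- diag(S %*% S %*% S) / 2
  a <- (w > 0) * 1
  k_tot <- rowSums(a) + colSums(a)
  k_bidir <- diag(a %*% a)
  denom <- k_tot * (k_tot - 1) - 2 * k_bidir
  ci <- ifelse(denom > 0, num / denom, 0)
  mean(ci)
}

# Mean over nodes of the efficiency of each node's neighbourhood subgraph.
local_efficiency <- function(ws, directed) {
  n <- nrow(ws)
  eff <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(ws[i, ] > 0 | ws[, i] > 0)
    nb <- setdiff(nb, i)
    if (length(nb) < 2) next
    sub <- ws[nb, nb, drop = FALSE]
    d <- graph_distances(sub, directed = directed)
    off <- upper.tri(d) | lower.tri(d)
    eff[i] <- mean(ifelse(is.finite(d[off]), 1 / d[off], 0))
  }
  mean(eff)
}

#' Graph properties of a subject's time-varying network
#'
#' By default the weight matrix is first averaged over the analysis window
#' and the metrics are computed on the mean matrix; alternatively metrics can
#' be computed per time slice and then averaged.
#'
#' @param net A `tv_network`.
#' @param window_ms Averaging window, default `c(0, 1000)`.
#' @param method `"average_first"` (default) or `"per_slice"`.
#' @param directed_handling Passed to [graph_properties()].
#' @return A `network_properties` list with the averaging window attached.
#' @export
subject_properties <- function(net, window_ms = c(0, 1000),
                               method = c("average_first", "per_slice"),
                               directed_handling = c("symmetrize", "directed")) {
  method <- match.arg(method)
  directed_handling <- match.arg(directed_handling)
  if (method == "average_first") {
    props <- graph_properties(network_window_mean(net, window_ms), directed_handling)
  } else {
    idx <- which(net$times_ms >= window_ms[1] & net$times_ms <= window_ms[2])
    if (length(idx) == 0L) stop_docnet("parameter", "window contains no grid points")
    per <- lapply(idx, function(ti) graph_properties(net$w[, , ti], directed_handling))
    props <- per[[1]]
    for (f in c("C", "L", "Ge", "Le")) {
      props[[f]] <- mean(vapply(per, `[[`, numeric(1), f))
    }
  }
  props$averaging_window_ms <- window_ms
  props$method <- method
  props
}
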