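#' Fixed-density thresholding of an adjacency matrix
#'
#' Rank-orders the n(n-1)/2 unique off-diagonal weights and keeps the
#' `round(k_density * n(n-1)/2)` largest, zeroing the rest, so networks
#' from different subjects and conditions are always compared at the
#' same link count. Ties at the cut are broken by lexicographic pair
#' order (deterministic).
#'
#' @param adj A `bb_adjacency` or plain symmetric matrix.
#' @param k_density Fraction of links kept, in (0, 1].
#' @return List of class `bb_network`: `a` (thresholded matrix),
#'   `k_density`, `kept_links`, plus metadata carried from the input.
#' @export
threshold_fixed_density <- function(adj, k_density) {
  if (!(k_density > 0 && k_density <= 1)) {
    stop("k_density must be in (0, 1]")
  }
  meta <- list(method = NA_character_, band = NA_character_,
               condition = NA_character_, bb_band = NA_character_,
               subject_id = NA_character_)
  if (inherits(adj, "bb_adjacency")) {
    meta <- adj[names(meta)]
    a <- adj$a
  } else {
    a <- adj
  }
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  if (max(abs(a - t(a))) > 1e-12) stop("adjacency matrix must be symmetric")
  n <- nrow(a)
  ut <- which(upper.tri(a), arr.ind = TRUE)
  w <- a[ut]
  n_links <- n * (n - 1) / 2
  keep_n <- round(k_density * n_links)
  # order by weight descending, ties by (row, col) ascending
  ord <- order(-w, ut[, 1], ut[, 2])
  kept <- ord[seq_len(keep_n)]
  thr <- matrix(0, n, n, dimnames = dimnames(a))
  idx <- ut[kept, , drop = FALSE]
  thr[idx] <- w[kept]
  thr[idx[, c(2, 1), drop = FALSE]] <- w[kept]
  structure(c(list(a = thr, k_density = k_density, kept_links = keep_n),
              meta),
            class = "bb_network")
}

#' @export
print.bb_network <- function(x, ...) {
  cat(sprintf("<bb_network> %d nodes, %d/%d links kept (k=%g) | %s band=%s\n",
              nrow(x$a), x$kept_links, nrow(x$a) * (nrow(x$a) - 1) / 2,
              x$k_density, x$method, x$band))
  invisible(x)
}

as_weight_matrix <- function(net) {
  if (inherits(net, "bb_network")) net$a
  else if (inherits(net, "bb_adjacency")) net$a
  else net
}

#' Node and global strength
#'
#' The strength of a node is the sum of the weights of its links; the
#' global strength is the mean over nodes.
#'
#' @param net A `bb_network`, `bb_adjacency`, or symmetric matrix.
#' @return List with `node` (named vector S_i) and `global` (scalar S).
#' @export
strength <- function(net) {
  a <- as_weight_matrix(net)
  s <- rowSums(a)
  list(node = s, global = mean(s))
}

#' Weighted clustering coefficient
#'
#' Geometric-mean triangle intensity around each node:
#' `t_i = 1/2 * sum_{j,h} (a_ij a_ih a_jh)^(1/3)` and
#' `C_i = 2 t_i / (k_i (k_i - 1))` with `C_i = 0` when the degree
#' `k_i` (count of non-zero links) is below 2. Weights must lie in
#' [0, 1] so that `C_i` does too.
#'
#' @param net A `bb_network`, `bb_adjacency`, or symmetric matrix.
#' @return List with `node` (C_i) and `global` (mean C).
#' @export
clustering_coef <- function(net) {
  a <- as_weight_matrix(net)
  if (any(a < 0) || any(a > 1)) stop("weights must be in [0, 1]")
  w <- a^(1 / 3)
  t_i <- diag(w %*% w %*% w) / 2
  k_i <- rowSums(a > 0)
  c_i <- ifelse(k_i < 2, 0, 2 * t_i / (k_i * (k_i - 1)))
  names(c_i) <- rownames(a)
  list(node = c_i, global = mean(c_i))
}

#' Weighted local efficiency
#'
#' For each node, the subgraph induced by its neighbours is extracted;
#' distances on that subgraph are shortest paths with link lengths
#' `1/weight`, and the node's local efficiency is the mean of the
#' inverse distances over all neighbour pairs (0 when the node has
#' fewer than two neighbours; disconnected pairs contribute 0). The
#' global value is the mean over nodes. High local efficiency means a
#' node's neighbourhood remains well connected without the node —
#' the network-integration reading used for functional brain networks.
#'
#' @param net A `bb_network`, `bb_adjacency`, or symmetric matrix.
#' @return List with `node` (E_i) and `global` (mean E).
#' @export
local_efficiency <- function(net) {
  a <- as_weight_matrix(net)
  n <- nrow(a)
  e_i <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    if (length(nb) < 2) next
    sub <- a[nb, nb, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                             weighted = TRUE)
    d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
    inv <- 1 / d[upper.tri(d)]
    inv[!is.finite(inv)] <- 0
    e_i[i] <- mean(inv)
  }
  names(e_i) <- rownames(a)
  list(node = e_i, global = mean(e_i))
}

#' All network measures of a thresholded network
#'
#' @param net A `bb_network`.
#' @return List of class `bb_metrics`: data frame `node` (node, S_i,
#'   C_i, E_i) and one-row data frame `global` (S, C, E, k_density plus
#'   metadata).
#' @export
network_metrics <- function(net) {
  stopifnot(inherits(net, "bb_network"))
  s <- strength(net)
  cl <- clustering_coef(net)
  ef <- local_efficiency(net)
  labs <- rownames(net$a)
  if (is.null(labs)) labs <- sprintf("n%02d", seq_len(nrow(net$a)))
  node <- data.frame(node = labs, S_i = unname(s$node),
                     C_i = unname(cl$node), E_i = unname(ef$node),
                     stringsAsFactors = FALSE)
  global <- data.frame(S = s$global, C = cl$global, E = ef$global,
                       k_density = net$k_density, method = net$method,
                       band = net$band, condition = net$condition,
                       bb_band = net$bb_band, subject = net$subject_id,
                       stringsAsFactors = FALSE)
  structure(list(node = node, global = global), class = "bb_metrics")
}

#' @export
print.bb_metrics <- function(x, ...) {
  g <- x$global
  cat(sprintf("<bb_metrics> k=%g: S=%.4f C=%.4f E=%.4f (%s, band=%s, %s)\n",
              g$k_density, g$S, g$C, g$E, g$method, g$band, g$condition))
  invisible(x)
}
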