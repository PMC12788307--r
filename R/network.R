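#' Proportional sparsity threshold
#'
#' Binarizes a symmetric connectivity matrix by keeping the
#' round(s * n(n-1)/2) strongest off-diagonal connections as undirected
#' edges (round-half-to-even, as in base R). Ties at the cutoff weight
#' are broken by ascending (row, column) index so the result is
#' deterministic.
#'
#' @param w symmetric non-negative connectivity matrix
#' @param sparsity fraction of possible edges to retain, in (0, 1]
#' @return object of class `binary_graph`: list with `adjacency` (0/1
#'   symmetric, zero diagonal) and `sparsity`
#' @export
proportional_threshold <- function(w, sparsity) {
  w <- unclass(w)
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  if (!(sparsity > 0 && sparsity <= 1))
    stop("`sparsity` must be in (0, 1]")
  n <- nrow(w)
  ut <- which(upper.tri(w))
  k <- round(sparsity * n * (n - 1) / 2)
  ord <- ut[order(-w[ut], ut)]          # strongest first; index breaks ties
  adj <- matrix(0L, n, n, dimnames = dimnames(w))
  if (k > 0) {
    sel <- ord[seq_len(min(k, length(ord)))]
    adj[sel] <- 1L
    adj <- adj + t(adj)
  }
  structure(list(adjacency = adj, sparsity = sparsity), class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("<binary_graph> %d nodes, %d edges (sparsity %.2f)\n",
              nrow(x$adjacency), sum(x$adjacency) / 2, x$sparsity))
  invisible(x)
}

# all-pairs shortest path lengths of an unweighted graph by matrix BFS;
# Inf for disconnected pairs
.bfs_distances <- function(adj) {
  n <- nrow(adj)
  A <- adj > 0
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- A
  d <- 1
  D[A] <- 1
  repeat {
    nxt <- (reach %*% A) > 0
    new <- nxt & !reach
    diag(new) <- FALSE
    new[is.finite(D)] <- FALSE
    if (!any(new)) break
    d <- d + 1
    D[new] <- d
    reach <- reach | nxt
    if (d > n) break
  }
  D
}

.as_adj <- function(g) {
  if (inherits(g, "binary_graph")) g$adjacency else {
    stopifnot(is.matrix(g))
    (unclass(g) != 0) * 1L
  }
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over all ordered node pairs;
#' disconnected pairs contribute zero. Equals 1 on a complete graph.
#'
#' @param g a `binary_graph` or 0/1 adjacency matrix
#' @return scalar in [0, 1]
#' @export
global_efficiency <- function(g) {
  adj <- .as_adj(g)
  n <- nrow(adj)
  if (n < 2) stop("global efficiency needs at least 2 nodes")
  D <- .bfs_distances(adj)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Average local efficiency
#'
#' For each node, the global efficiency of the subgraph induced by its
#' (open) neighborhood; nodes with fewer than two neighbors contribute
#' zero. Returns the mean over all nodes.
#'
#' @param g a `binary_graph` or 0/1 adjacency matrix
#' @return scalar in [0, 1]
#' @export
local_efficiency_avg <- function(g) {
  adj <- .as_adj(g)
  n <- nrow(adj)
  if (n < 2) stop("local efficiency needs at least 2 nodes")
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) return(0)
    global_efficiency(adj[nb, nb, drop = FALSE])
  }, 0)
  mean(vals)
}

#' Average clustering coefficient
#'
#' Per node, the fraction of its neighbor pairs that are themselves
#' connected (triangles / k(k-1)/2); nodes of degree < 2 contribute zero.
#' Arithmetic mean over all nodes.
#'
#' @param g a `binary_graph` or 0/1 adjacency matrix
#' @return scalar in [0, 1]
#' @export
clustering_avg <- function(g) {
  adj <- .as_adj(g)
  n <- nrow(adj)
  if (n < 2) stop("clustering needs at least 2 nodes")
  k <- rowSums(adj)
  tri <- diag(adj %*% adj %*% adj) / 2     # triangles through each node
  ci <- ifelse(k < 2, 0, tri / (k * (k - 1) / 2))
  mean(ci)
}

#' Integrate a metric trajectory over the sparsity sweep
#'
#' Composite trapezoid rule over ascending thresholds; the standard way
#' to collapse a threshold sweep into one threshold-independent feature.
#'
#' @param values metric values, one per threshold
#' @param thresholds ascending sparsity grid (default 0.10-0.30 by 0.05)
#' @return scalar AUC
#' @export
auc_over_sparsity <- function(values, thresholds = sparsity_grid()) {
  if (length(thresholds) < 2) stop("need at least 2 thresholds")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("`thresholds` must be strictly ascending")
  if (length(values) != length(thresholds))
    stop("`values` and `thresholds` differ in length")
  sum(diff(thresholds) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}

#' Default sparsity grid: 10% to 30% in 5% steps
#' @export
sparsity_grid <- function() c(0.10, 0.15, 0.20, 0.25, 0.30)

#' Topological features of one connectivity matrix
#'
#' Thresholds the matrix at every sparsity in the grid, computes global
#' efficiency, average local efficiency and average clustering on each
#' binary graph, and integrates each trajectory to its AUC.
#'
#' @param w symmetric connectivity matrix
#' @param thresholds sparsity grid
#' @return list: `per_threshold` (data.frame sparsity x metric value) and
#'   `auc` (named vector: global_efficiency, local_efficiency, clustering)
#' @export
network_features <- function(w, thresholds = sparsity_grid()) {
  per <- lapply(thresholds, function(s) {
    g <- proportional_threshold(w, s)
    c(global_efficiency = global_efficiency(g),
      local_efficiency = local_efficiency_avg(g),
      clustering = clustering_avg(g))
  })
  per <- do.call(rbind, per)
  auc <- apply(per, 2L, auc_over_sparsity, thresholds = thresholds)
  list(per_threshold = data.frame(sparsity = thresholds, per),
       auc = auc)
}

#' Network AUC features for a whole cohort
#'
#' @param cohort an `eeg_cohort`
#' @param conn optional precomputed output of [cohort_connectivity()]
#' @param bands band table
#' @param thresholds sparsity grid
#' @param window,overlap Welch parameters (when `conn` is NULL)
#' @return data.frame: subject_id, group, age, task, band, metric,
#'   auc_value (long format); attribute `per_threshold` holds the raw
#'   per-threshold long table
#' @export
cohort_network_features <- function(cohort, conn = NULL,
                                    bands = band_definitions(),
                                    thresholds = sparsity_grid(),
                                    window = 2, overlap = 0.5) {
  if (is.null(conn))
    conn <- cohort_connectivity(cohort, bands, window, overlap)
  meta <- cohort$metadata
  rows <- list(); raw <- list()
  for (s in cohort$subjects) {
    for (task in names(conn[[s$subject_id]])) {
      for (band in names(conn[[s$subject_id]][[task]])) {
        nf <- network_features(conn[[s$subject_id]][[task]][[band]], thresholds)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = s$subject_id, group = s$group, age = s$age,
          task = task, band = band, metric = names(nf$auc),
          auc_value = unname(nf$auc), stringsAsFactors = FALSE)
        pt <- nf$per_threshold
        raw[[length(raw) + 1L]] <- data.frame(
          subject_id = s$subject_id, task = task, band = band,
          pt, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "per_threshold") <- do.call(rbind, raw)
  out
}
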