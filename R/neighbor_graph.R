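#' Neighbor graphs on the cell-state manifold
#'
#' A `neighbor_graph` stores, for every cell, the indices of its nearest
#' neighbours and the corresponding distances. It defines the neighbourhood
#' over which displacement bases, moment smoothing and all manifold scores
#' operate. Graphs built by [build_knn()] have a fixed neighbourhood size
#' `k`; graphs produced by [union_graph()] are ragged (per-cell variable
#' neighbour count), and downstream code never assumes a fixed `k`.
#'
#' @param indices list of integer vectors (one per cell) of neighbour
#'   positions, 1-based, self excluded.
#' @param distances list of numeric vectors matching `indices`.
#' @param n_cells number of cells (defaults to `length(indices)`).
#' @param source provenance tag: `"expression"`, `"spatial"`, `"union"` or
#'   `"external-wnn"`.
#' @return An object of class `neighbor_graph`.
#' @export
neighbor_graph <- function(indices, distances, n_cells = length(indices),
                           source = "external-wnn") {
  .gv_check(is.list(indices) && is.list(distances) &&
              length(indices) == length(distances),
            "indices and distances must be lists of equal length")
  .gv_check(length(indices) == n_cells, "one neighbour list per cell required")
  for (i in seq_len(n_cells)) {
    idx <- indices[[i]]; d <- distances[[i]]
    .gv_check(length(idx) == length(d),
              "indices/distances length mismatch for cell ", i)
    .gv_check(!anyNA(idx) && all(idx >= 1L) && all(idx <= n_cells),
              "neighbour index out of range for cell ", i)
    .gv_check(!any(idx == i), "self-neighbour found for cell ", i)
    .gv_check(all(is.finite(d)) && all(d >= 0),
              "distances must be finite and non-negative (cell ", i, ")")
    indices[[i]] <- as.integer(idx)
    distances[[i]] <- as.numeric(d)
  }
  structure(list(indices = indices, distances = distances,
                 n_cells = as.integer(n_cells), source = source),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  ks <- lengths(x$indices)
  cat("neighbor_graph (", x$source, "): ", x$n_cells, " cells, ",
      if (length(unique(ks)) == 1L) paste0("k = ", ks[1])
      else paste0("ragged k in [", min(ks), ", ", max(ks), "]"),
      "\n", sep = "")
  invisible(x)
}

#' Exact k-nearest-neighbour graph
#'
#' Euclidean kNN by exhaustive search, self excluded, with a deterministic
#' tie rule: equal distances are broken by ascending cell index. Exact
#' search keeps the graph fully reproducible, which the projection weights
#' inherit.
#'
#' @param coords cells x d numeric matrix of coordinates (any representation:
#'   expression, PCs, spatial). For expression data the conventional choice
#'   is a reduced space such as the top principal components, see
#'   [pca_embedding()]; the coordinate source is the caller's.
#' @param k neighbourhood size; must satisfy `k < nrow(coords)`. Default 30,
#'   the standard single-modality choice; spatial graphs conventionally use
#'   `k = 8`.
#' @param source provenance tag stored on the graph.
#' @return A `neighbor_graph` with `k` neighbours per cell, distances
#'   non-decreasing within each cell.
#' @export
build_knn <- function(coords, k = 30L, source = "expression") {
  coords <- .as_dense(coords)
  .gv_check(all(is.finite(coords)), "coords must be finite")
  n <- nrow(coords)
  k <- as.integer(k)
  .gv_check(k >= 1L, "k must be at least 1")
  if (k >= n) stop("k (", k, ") must be smaller than the number of cells (",
                   n, ")", call. = FALSE)
  d2 <- as.matrix(dist(coords))
  idx <- vector("list", n); dst <- vector("list", n)
  ord_base <- seq_len(n)
  for (i in seq_len(n)) {
    di <- d2[, i]
    di[i] <- Inf
    o <- order(di, ord_base)[seq_len(k)]
    idx[[i]] <- as.integer(o)
    dst[[i]] <- di[o]
  }
  neighbor_graph(idx, dst, n, source = source)
}

#' Union of two neighbour graphs
#'
#' Per-cell set union of neighbour lists (e.g. an expression kNN graph
#' combined with a spatial kNN graph). Distances are carried over from the
#' contributing graph; if a neighbour occurs in both, the smaller distance
#' is kept. The result is ragged.
#'
#' @param g1,g2 `neighbor_graph` objects over the same cells.
#' @return A ragged `neighbor_graph` with `source = "union"`.
#' @export
union_graph <- function(g1, g2) {
  .gv_check(inherits(g1, "neighbor_graph") && inherits(g2, "neighbor_graph"),
            "g1 and g2 must be neighbor_graph objects")
  if (g1$n_cells != g2$n_cells)
    stop("cell-count mismatch: ", g1$n_cells, " vs ", g2$n_cells,
         call. = FALSE)
  n <- g1$n_cells
  idx <- vector("list", n); dst <- vector("list", n)
  for (i in seq_len(n)) {
    i1 <- g1$indices[[i]]; i2 <- g2$indices[[i]]
    d1 <- g1$distances[[i]]; d2 <- g2$distances[[i]]
    all_idx <- c(i1, i2)
    all_d <- c(d1, d2)
    ## min distance per neighbour present in both graphs
    o <- order(all_idx, all_d)
    all_idx <- all_idx[o]; all_d <- all_d[o]
    keep <- !duplicated(all_idx)
    u_idx <- all_idx[keep]; u_d <- all_d[keep]
    o2 <- order(u_d, u_idx)
    idx[[i]] <- u_idx[o2]; dst[[i]] <- u_d[o2]
  }
  neighbor_graph(idx, dst, n, source = "union")
}

#' Neighbourhood first-moment smoothing
#'
#' Replaces each cell's row by the mean over its neighbourhood, the standard
#' noise-reduction step applied to raw velocity vectors (and optionally to
#' expression) before projection. Linear in its input.
#'
#' @param values cells x f numeric matrix.
#' @param g a `neighbor_graph`.
#' @param include_self logical; whether cell i itself enters the average
#'   (default `TRUE`, the convention for moment smoothing).
#' @return cells x f matrix of neighbourhood means.
#' @export
smooth_first_moments <- function(values, g, include_self = TRUE) {
  values <- .as_dense(values)
  .gv_check(inherits(g, "neighbor_graph"), "g must be a neighbor_graph")
  .gv_check(nrow(values) == g$n_cells,
            "values must have one row per cell in the graph")
  n <- g$n_cells
  members <- g$indices
  if (include_self)
    members <- lapply(seq_len(n), function(i) c(i, members[[i]]))
  counts <- lengths(members)
  .gv_check(all(counts > 0), "every cell needs a non-empty neighbourhood")
  grp <- rep.int(seq_len(n), counts)
  take <- unlist(members, use.names = FALSE)
  out <- matrix(0, n, ncol(values), dimnames = dimnames(values))
  ## block over features so the gathered matrix stays small
  block <- max(1L, min(ncol(values), 256L))
  starts <- seq(1L, ncol(values), by = block)
  for (s in starts) {
    cols <- s:min(s + block - 1L, ncol(values))
    acc <- rowsum(values[take, cols, drop = FALSE], group = grp, reorder = TRUE)
    out[, cols] <- acc / counts
  }
  out
}

#' Principal-component embedding of an expression matrix
#'
#' Convenience construction of the reduced space in which neighbour graphs
#' are conventionally computed: log1p-scaled expression projected on the top
#' principal components.
#'
#' @param X cells x features matrix.
#' @param d number of components (default 30, capped at the matrix rank).
#' @param log1p whether to apply `log1p` before centering.
#' @return A [linear_embedding()] together with the cell coordinates in the
#'   component space (element `coords`).
#' @export
pca_embedding <- function(X, d = 30L, log1p = TRUE) {
  X <- .as_dense(X)
  if (log1p) X <- log1p(X)
  d <- min(as.integer(d), nrow(X) - 1L, ncol(X))
  p <- prcomp(X, center = TRUE, scale. = FALSE, rank. = d)
  emb <- linear_embedding(p$rotation[, seq_len(d), drop = FALSE],
                          center = p$center,
                          explained_variance = p$sdev[seq_len(d)]^2)
  emb$coords <- p$x[, seq_len(d), drop = FALSE]
  emb
}
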