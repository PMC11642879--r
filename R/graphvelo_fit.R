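#' Fit manifold-projected velocities (the central model)
#'
#' `graphvelo()` learns, for every cell, sparse weights over its graph
#' neighbours such that the weighted sum of neighbour displacements
#' reproduces the cell's velocity vector while lying in the tangent space of
#' the data manifold:
#' \deqn{v^{\parallel}_i = \sum_{j \in N_i} \phi_{ij}\,\delta_{ij}, \qquad
#'       \delta_{ij} = x_j - x_i.}
#' The weights are fitted per cell by minimising the tangent-space-projection
#' loss (see [tsp_config()]); each cell is an independent small optimisation,
#' so results do not depend on cell order. Because the learned weights are
#' attached to *cells*, not to features, they transfer velocities to any
#' other representation of the same cells by swapping the displacement basis
#' — see [predict.graphvelo()] / [transform_velocity()].
#'
#' @param x coordinates of the representation in which velocities live: a
#'   cells x d matrix, or a [cell_population()] (whose `X`, restricted to
#'   `features`, is used).
#' @param ... passed between methods.
#' @return An object of class `graphvelo`; see Details.
#'
#' @details The returned object has elements `weights` and `phi_corr`
#'   (per-cell numeric vectors aligned with the graph's neighbour lists),
#'   `fitted` (cells x d matrix of projected velocities), `diagnostics`
#'   (per-cell loss at initialisation and convergence, iteration count, and
#'   flags for cells with no neighbours or an all-missing velocity), plus
#'   the inputs needed by the methods. Cells without neighbours keep their
#'   input velocity and are flagged. Supported methods: `print`, `summary`,
#'   `coef` (weights), `fitted` (projected velocities), `residuals`
#'   (input minus projection, over non-missing dimensions), and `predict`
#'   (velocity transfer to a new coordinate basis).
#' @export
graphvelo <- function(x, ...) UseMethod("graphvelo")

#' @rdname graphvelo
#' @param v cells x d matrix of velocity vectors (may contain `NA`;
#'   missing dimensions are masked during fitting and inferred by the
#'   projection).
#' @param graph a [neighbor_graph()]; if `NULL`, a kNN graph with `k`
#'   neighbours is built on `x`.
#' @param k neighbourhood size used when `graph` is `NULL`.
#' @param config a [tsp_config()].
#' @param smooth_velocity if `TRUE`, velocities are first-moment smoothed
#'   over the graph before fitting (displacements always use raw
#'   coordinates).
#' @export
graphvelo.default <- function(x, v, graph = NULL, k = 30L,
                              config = tsp_config(),
                              smooth_velocity = FALSE, ...) {
  x <- .as_dense(x)
  v <- .as_dense(v)
  .gv_check(identical(dim(x), dim(v)), "x and v must have identical shape")
  if (is.null(graph)) graph <- build_knn(x, k = k)
  .gv_check(inherits(graph, "neighbor_graph"), "graph must be a neighbor_graph")
  .gv_check(graph$n_cells == nrow(x), "graph does not match the cells in x")
  if (smooth_velocity) {
    vs <- v; vs[is.na(vs)] <- 0
    vs <- smooth_first_moments(vs, graph, include_self = TRUE)
    vs[is.na(v)] <- NA   # keep the missingness mask of the raw input
    v <- vs
  }
  n <- nrow(x); d <- ncol(x)
  deltas <- displacement_basis(x, graph)
  weights <- vector("list", n)
  phi_corr <- vector("list", n)
  fitted <- matrix(NA_real_, n, d, dimnames = dimnames(v))
  diag_df <- data.frame(loss0 = rep(NA_real_, n), loss = NA_real_,
                        iterations = NA_integer_, converged = NA,
                        no_neighbors = FALSE, missing_velocity = FALSE)
  for (i in seq_len(n)) {
    vi <- v[i, ]
    D <- deltas[[i]]
    if (ncol(D) == 0L) {
      diag_df$no_neighbors[i] <- TRUE
      fitted[i, ] <- vi
      next
    }
    if (all(is.na(vi))) {
      diag_df$missing_velocity[i] <- TRUE
      next
    }
    fit <- fit_tsp_weights(vi, D, config)
    weights[[i]] <- fit$phi
    phi_corr[[i]] <- fit$phi_corr
    fitted[i, ] <- as.numeric(D %*% fit$phi)
    diag_df$loss0[i] <- fit$loss0
    diag_df$loss[i] <- fit$loss
    diag_df$iterations[i] <- fit$iterations
    diag_df$converged[i] <- fit$converged
  }
  structure(list(x = x, v = v, graph = graph, config = config,
                 weights = weights, phi_corr = phi_corr, fitted = fitted,
                 diagnostics = diag_df, features = colnames(x),
                 call = match.call()),
            class = "graphvelo")
}

#' @rdname graphvelo
#' @param vkey name of the velocity layer (default `"velocity"`).
#' @param features feature subset defining the source space; defaults to the
#'   features with at least one non-missing velocity (the velocity genes).
#' @export
graphvelo.cell_population <- function(x, graph = NULL, vkey = "velocity",
                                      features = NULL,
                                      config = tsp_config(), ...) {
  pop <- validate_population(x)
  V <- .get_layer(pop, vkey)
  if (is.null(features)) {
    has_v <- colSums(!is.na(V)) > 0L
    .gv_check(any(has_v), "velocity layer '", vkey, "' is entirely missing")
    features <- which(has_v)
  } else {
    features <- .resolve_features(pop, features)
  }
  if (is.null(graph)) graph <- pop$graph
  fit <- graphvelo.default(pop$X[, features, drop = FALSE],
                           V[, features, drop = FALSE],
                           graph = graph, config = config, ...)
  fit$features <- colnames(pop$X)[features]
  fit$call <- match.call()
  fit
}

#' @export
print.graphvelo <- function(x, ...) {
  n <- nrow(x$x)
  cat("graphvelo fit: ", n, " cells, ", ncol(x$x),
      " source features, graph k ~ ",
      round(mean(lengths(x$graph$indices)), 1), "\n", sep = "")
  cat("  TSP loss: a = ", x$config$a, ", b = ", x$config$b,
      ", lambda = ", x$config$lambda, "\n", sep = "")
  ok <- !x$diagnostics$no_neighbors & !x$diagnostics$missing_velocity
  cat("  fitted cells: ", sum(ok), " / ", n, "\n", sep = "")
  invisible(x)
}

#' @export
summary.graphvelo <- function(object, ...) {
  d <- object$diagnostics
  ok <- !d$no_neighbors & !d$missing_velocity
  res <- residuals(object)
  rel <- .row_norms(replace(res, is.na(res), 0)) /
    pmax(.row_norms(replace(object$v, is.na(object$v), 0)), .Machine$double.eps)
  out <- list(n_cells = nrow(object$x), n_features = ncol(object$x),
              n_fitted = sum(ok),
              n_no_neighbors = sum(d$no_neighbors),
              n_missing_velocity = sum(d$missing_velocity),
              mean_loss = mean(d$loss[ok]),
              mean_loss0 = mean(d$loss0[ok]),
              median_relative_residual = median(rel[ok]),
              config = object$config)
  class(out) <- "summary.graphvelo"
  out
}

#' @export
print.summary.graphvelo <- function(x, ...) {
  cat("graphvelo fit over", x$n_cells, "cells x", x$n_features,
      "source features\n")
  cat(sprintf("  fitted %d cells (%d without neighbours, %d without velocity)\n",
              x$n_fitted, x$n_no_neighbors, x$n_missing_velocity))
  cat(sprintf("  mean TSP loss: %.4g (at initialisation %.4g)\n",
              x$mean_loss, x$mean_loss0))
  cat(sprintf("  median relative residual |v - v_par|/|v|: %.4g\n",
              x$median_relative_residual))
  invisible(x)
}

#' @export
coef.graphvelo <- function(object, ...) object$weights

#' @export
fitted.graphvelo <- function(object, ...) object$fitted

#' @export
residuals.graphvelo <- function(object, ...) object$v - object$fitted

#' Transfer fitted velocities to a new coordinate basis
#'
#' Applies the learned neighbour weights to the displacement basis of a
#' different representation of the same cells:
#' \eqn{v^{\parallel}(y_i) = \sum_j \phi_{ij} (y_j - y_i)}. This is exact
#' under any linear map of the coordinates and is the mechanism for
#' transferring velocities across embeddings, feature subsets and
#' modalities.
#'
#' @param object a fitted [graphvelo()] model.
#' @param newdata cells x d' matrix of target coordinates (same cells, same
#'   graph as the fit). If omitted, returns the fitted velocities.
#' @param ... unused.
#' @return cells x d' matrix of transferred velocities. Cells that could not
#'   be fitted (no neighbours or missing velocity) yield `NA` rows.
#' @export
predict.graphvelo <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  transform_velocity(object, newdata)
}

#' @rdname predict.graphvelo
#' @param fit a fitted `graphvelo` model (alias interface).
#' @param target_coords cells x d' matrix of target coordinates.
#' @export
transform_velocity <- function(fit, target_coords) {
  .gv_check(inherits(fit, "graphvelo"), "fit must be a graphvelo object")
  Y <- .as_dense(target_coords)
  if (nrow(Y) != fit$graph$n_cells)
    stop("target coordinates have ", nrow(Y), " rows but the fit covers ",
         fit$graph$n_cells, " cells", call. = FALSE)
  n <- nrow(Y)
  out <- matrix(NA_real_, n, ncol(Y),
                dimnames = list(rownames(fit$x), colnames(Y)))
  for (i in seq_len(n)) {
    w <- fit$weights[[i]]
    if (is.null(w)) next
    nbr <- fit$graph$indices[[i]]
    out[i, ] <- as.numeric(crossprod(Y[nbr, , drop = FALSE], w)) -
      sum(w) * Y[i, ]
  }
  out
}

#' Project a population's velocity layer onto the manifold
#'
#' Convenience wrapper around [graphvelo()] that writes the projected
#' velocities back into the container as a new layer (default
#' `"velocity_graphvelo"`; features outside the source set are `NA`).
#'
#' @param pop a [cell_population()] with a velocity layer.
#' @param graph optional [neighbor_graph()] (defaults to the population's).
#' @param config a [tsp_config()].
#' @param features source features; defaults to the velocity genes.
#' @param vkey input velocity layer name.
#' @param out_key output layer name.
#' @param ... passed to [graphvelo()].
#' @return List with elements `population` (the augmented container) and
#'   `fit` (the `graphvelo` model).
#' @export
project_velocities <- function(pop, graph = NULL, config = tsp_config(),
                               features = NULL, vkey = "velocity",
                               out_key = "velocity_graphvelo", ...) {
  fit <- graphvelo(pop, graph = graph, vkey = vkey, features = features,
                   config = config, ...)
  L <- matrix(NA_real_, nrow(pop$X), ncol(pop$X), dimnames = dimnames(pop$X))
  L[, fit$features] <- fit$fitted
  pop$layers[[out_key]] <- L
  list(population = pop, fit = fit)
}

#' Infer velocities of unmeasured features
#'
#' Fits projection weights in the source feature space (where upstream
#' velocities exist) and transfers them to target features by swapping the
#' displacement basis — the route by which velocities of genes without
#' splicing information, chromatin accessibility, or viral transcripts are
#' inferred from a reliable subset. Restricted to the source features the
#' result reproduces the direct projection exactly.
#'
#' @param pop a [cell_population()].
#' @param graph optional [neighbor_graph()] (defaults to the population's).
#' @param config a [tsp_config()].
#' @param source_features features with upstream velocities.
#' @param target_features features whose velocities are to be inferred
#'   (any modality present in `X`).
#' @param vkey velocity layer name.
#' @return cells x targets matrix of inferred velocities.
#' @export
infer_unmeasured_velocity <- function(pop, graph = NULL,
                                      config = tsp_config(),
                                      source_features, target_features,
                                      vkey = "velocity") {
  src <- .resolve_features(pop, source_features)
  tgt <- .resolve_features(pop, target_features)
  fit <- graphvelo(pop, graph = graph, vkey = vkey, features = src,
                   config = config)
  transform_velocity(fit, pop$X[, tgt, drop = FALSE])
}

#' Adaptive per-cell extrapolation step size
#'
#' The step used to propagate a cell state along its velocity while staying
#' within the neighbourhood scale of the manifold:
#' \eqn{dt_i = \mathrm{median}_j \|\delta_{ij}\| / \|v_i\|}. Cells with zero
#' speed get `NA` (undefined) and are excluded downstream.
#'
#' @param x cells x d coordinates, or a `cell_population`.
#' @param g a [neighbor_graph()]; defaults to the population's graph.
#' @param v cells x d velocity matrix (or `vkey` layer of the population).
#' @param vkey velocity layer name when `x` is a population.
#' @return Numeric vector of per-cell step sizes (`NA` where undefined).
#' @export
adaptive_step_size <- function(x, g = NULL, v = NULL, vkey = "velocity") {
  if (inherits(x, "cell_population")) {
    if (is.null(g)) g <- x$graph
    if (is.null(v)) v <- .get_layer(x, vkey)
    x <- x$X
  }
  x <- .as_dense(x); v <- .as_dense(v)
  .gv_check(inherits(g, "neighbor_graph"), "a neighbor_graph is required")
  .gv_check(nrow(x) == g$n_cells && identical(dim(x), dim(v)),
            "shape mismatch between coordinates, velocities and graph")
  n <- nrow(x)
  dt <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    nbr <- g$indices[[i]]
    if (!length(nbr)) next
    vi <- v[i, ]
    vn <- sqrt(sum(vi[!is.na(vi)]^2))
    if (vn == 0) next
    dnorm <- .row_norms(x[nbr, , drop = FALSE] -
                          matrix(x[i, ], length(nbr), ncol(x), byrow = TRUE))
    dt[i] <- median(dnorm) / vn
  }
  dt
}

#' Velocities in a linear embedding via finite propagation
#'
#' Propagates each cell by its adaptive step, maps current and propagated
#' states through the loading matrix, and divides by the step:
#' \eqn{v^{emb}_i = ((x_i + v_i dt_i)Q - x_i Q)/dt_i}. For a linear map this
#' equals \eqn{v_i Q} identically (the step cancels); the propagation form
#' is kept because it is the construction that generalises. Cells with an
#' undefined step emit a zero vector and are flagged in the
#' `"undefined_step"` attribute.
#'
#' @param x cells x d coordinates, or a `cell_population`.
#' @param embedding a [linear_embedding()].
#' @param g a [neighbor_graph()]; defaults to the population's graph.
#' @param v velocity matrix (or `vkey` layer). Missing dimensions are
#'   treated as zero contribution.
#' @param vkey velocity layer name when `x` is a population.
#' @return cells x d' matrix of embedded velocities.
#' @export
velocity_to_embedding <- function(x, embedding, g = NULL, v = NULL,
                                  vkey = "velocity") {
  if (inherits(x, "cell_population")) {
    if (is.null(g)) g <- x$graph
    if (is.null(v)) v <- .get_layer(x, vkey)
    x <- x$X
  }
  .gv_check(inherits(embedding, "linear_embedding"),
            "embedding must be a linear_embedding")
  x <- .as_dense(x); v <- .as_dense(v)
  v[is.na(v)] <- 0
  dt <- adaptive_step_size(x, g, v)
  Q <- embedding$loadings
  ctr <- embedding$center
  n <- nrow(x)
  out <- matrix(0, n, ncol(Q), dimnames = list(rownames(x), colnames(Q)))
  ok <- which(!is.na(dt))
  if (length(ok)) {
    x0 <- sweep(x[ok, , drop = FALSE], 2, ctr)
    x1 <- sweep(x[ok, , drop = FALSE] + v[ok, , drop = FALSE] * dt[ok], 2, ctr)
    out[ok, ] <- (x1 %*% Q - x0 %*% Q) / dt[ok]
  }
  attr(out, "undefined_step") <- which(is.na(dt))
  out
}

#' Cosine-kernel baseline projection
#'
#' The normalised cosine-kernel projection used as a comparator in
#' benchmarks: \eqn{v_i = \sum_j \phi^{corr}_{ij} \delta_{ij} /
#' \sum_j |\phi^{corr}_{ij}|}. Preserves direction asymptotically but not
#' magnitude.
#'
#' @inheritParams adaptive_step_size
#' @return cells x d matrix of baseline-projected velocities (zero rows
#'   where all weights vanish or a cell has no neighbours).
#' @export
baseline_cosine_projection <- function(x, g = NULL, v = NULL,
                                       vkey = "velocity") {
  if (inherits(x, "cell_population")) {
    if (is.null(g)) g <- x$graph
    if (is.null(v)) v <- .get_layer(x, vkey)
    x <- x$X
  }
  x <- .as_dense(x); v <- .as_dense(v)
  .gv_check(inherits(g, "neighbor_graph"), "a neighbor_graph is required")
  n <- nrow(x)
  out <- matrix(0, n, ncol(x), dimnames = dimnames(v))
  deltas <- displacement_basis(x, g)
  for (i in seq_len(n)) {
    D <- deltas[[i]]
    if (ncol(D) == 0L) next
    vi <- v[i, ]
    keep <- !is.na(vi)
    if (!any(keep)) next
    pc <- cosine_kernel_weights(vi[keep], D[keep, , drop = FALSE])
    s <- sum(abs(pc))
    if (s == 0) next
    out[i, ] <- as.numeric(D %*% pc) / s
  }
  out
}
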