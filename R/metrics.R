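#' Manifold-consistent kinetics (MacK) score
#'
#' For cell i and gene g, the fraction of neighbours j (with a pseudotime
#' difference) for which the sign of the finite difference
#' \eqn{\Delta x_{ij}(g)/\Delta t_{ij}} agrees with the sign of the gene's
#' velocity in cell i. Genes whose upstream velocity is concordant with the
#' manifold's temporal ordering score near 1; sign-flipped velocities score
#' near 0; uninformative velocities score near 1/2. Zero is treated as its
#' own sign symbol: a zero velocity matches only a zero finite difference.
#' Neighbours with \eqn{\Delta t = 0} are excluded; a cell with no usable
#' neighbour is excluded from the per-gene mean.
#'
#' @param x cells x features expression matrix, or a `cell_population`
#'   (whose `X` is used).
#' @param g a [neighbor_graph()]; defaults to the population's graph.
#' @param t per-cell pseudotime (or `tkey` column of `obs`), finite.
#' @param v velocity matrix (or `vkey` layer).
#' @param genes feature subset to score (default: all features with any
#'   non-missing velocity).
#' @param tkey,vkey annotation/layer names used when `x` is a population.
#' @return List with `cell_gene` (cells x genes matrix of per-cell scores,
#'   `NA` where excluded) and `gene` (named per-gene means, in \[0, 1\]).
#' @export
mack_score <- function(x, g = NULL, t = NULL, v = NULL, genes = NULL,
                       tkey = "pseudotime", vkey = "velocity") {
  if (inherits(x, "cell_population")) {
    if (is.null(g)) g <- x$graph
    if (is.null(v)) v <- .get_layer(x, vkey)
    if (is.null(t)) t <- x$obs[[tkey]]
    genes <- if (is.null(genes)) which(colSums(!is.na(v)) > 0L)
             else .resolve_features(x, genes)
    x <- x$X
  } else {
    x <- .as_dense(x)
    if (is.null(genes)) genes <- seq_len(ncol(x))
  }
  v <- .as_dense(v)
  .gv_check(inherits(g, "neighbor_graph"), "a neighbor_graph is required")
  .gv_check(!is.null(t) && all(is.finite(t)) && length(t) == nrow(x),
            "t must be a finite per-cell pseudotime")
  n <- nrow(x)
  xg <- x[, genes, drop = FALSE]
  vg <- v[, genes, drop = FALSE]
  cg <- matrix(NA_real_, n, length(genes),
               dimnames = list(rownames(x), colnames(xg)))
  for (i in seq_len(n)) {
    nbr <- g$indices[[i]]
    if (!length(nbr)) next
    dt <- t[nbr] - t[i]
    use <- dt != 0
    if (!any(use)) next
    nbr <- nbr[use]; dt <- dt[use]
    dx <- xg[nbr, , drop = FALSE] -
      matrix(xg[i, ], length(nbr), ncol(xg), byrow = TRUE)
    sg <- sign(dx) * sign(dt)             # sign of dx/dt
    vs <- matrix(sign(vg[i, ]), length(nbr), ncol(xg), byrow = TRUE)
    agree <- (sg == vs)
    agree[is.na(agree)] <- NA             # NA velocity -> excluded gene
    cg[i, ] <- colMeans(agree)
  }
  gene <- colMeans(cg, na.rm = TRUE)
  gene[!is.finite(gene)] <- NA_real_
  list(cell_gene = cg, gene = gene)
}

#' Rank genes by MacK score
#'
#' Descending score, ties broken by ascending feature index; the
#' conventional way of picking a robust source-gene subset for projection.
#'
#' @param scores named per-gene score vector (as returned in
#'   `mack_score()$gene`).
#' @param top_n number of genes to return.
#' @return Integer positions (named when `scores` is named) of the top
#'   genes, in rank order.
#' @export
select_mack_genes <- function(scores, top_n = length(scores)) {
  .gv_check(top_n <= length(scores), "top_n exceeds the number of genes")
  o <- order(-scores, seq_along(scores))
  o[seq_len(top_n)]
}

#' Cross-boundary correctness (CBC) score
#'
#' For a known transition from population A to population B, the mean (over
#' boundary cells of A, i.e. cells of A with at least one neighbour in B) of
#' the mean cosine between the cell's velocity and the displacements towards
#' its B neighbours. Positive values mean velocities point across the
#' boundary in the annotated direction. Computed by default in the full
#' expression space rather than a 2-D embedding, which can distort geometry.
#'
#' @param x cells x features coordinate matrix, or a `cell_population`.
#' @param g a [neighbor_graph()]; defaults to the population's graph.
#' @param labels per-cell category labels (or `labels_key` column of `obs`).
#' @param A,B source and target category.
#' @param v velocity matrix (or `vkey` layer); missing dimensions are
#'   masked pairwise.
#' @param labels_key,vkey annotation/layer names when `x` is a population.
#' @return Scalar score in \[-1, 1\], or `NA` (with a message) when no
#'   boundary cell exists.
#' @export
cbc_score <- function(x, g = NULL, labels = NULL, A, B, v = NULL,
                      labels_key = "category", vkey = "velocity") {
  if (inherits(x, "cell_population")) {
    if (is.null(g)) g <- x$graph
    if (is.null(v)) v <- .get_layer(x, vkey)
    if (is.null(labels)) labels <- x$obs[[labels_key]]
    x <- x$X
  }
  x <- .as_dense(x); v <- .as_dense(v)
  .gv_check(inherits(g, "neighbor_graph"), "a neighbor_graph is required")
  .gv_check(length(labels) == nrow(x), "one label per cell required")
  .gv_check(any(labels == A) && any(labels == B),
            "both categories must be populated")
  scores <- c()
  for (i in which(labels == A)) {
    nbr <- g$indices[[i]]
    nbr_b <- nbr[labels[nbr] == B]
    if (!length(nbr_b)) next
    vi <- v[i, ]
    keep <- !is.na(vi)
    if (!any(keep)) next
    cs <- vapply(nbr_b, function(j)
      .cosine(vi[keep], (x[j, ] - x[i, ])[keep]), numeric(1))
    scores <- c(scores, mean(cs))
  }
  if (!length(scores)) {
    message("no boundary cells between '", A, "' and '", B, "'")
    return(NA_real_)
  }
  mean(scores)
}

#' Velocity consistency score
#'
#' Per-cell mean cosine similarity between the cell's velocity and its
#' neighbours' velocities; coherent unidirectional flow scores near 1.
#' Zero vectors contribute cosine 0.
#'
#' @inheritParams cbc_score
#' @return Numeric per-cell vector in \[-1, 1\].
#' @export
velocity_consistency <- function(x, g = NULL, v = NULL, vkey = "velocity") {
  if (inherits(x, "cell_population")) {
    if (is.null(g)) g <- x$graph
    if (is.null(v)) v <- .get_layer(x, vkey)
    x <- x$X
  }
  v <- .as_dense(v)
  .gv_check(inherits(g, "neighbor_graph"), "a neighbor_graph is required")
  .gv_check(nrow(v) == g$n_cells, "velocity rows must match graph cells")
  n <- nrow(v)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    nbr <- g$indices[[i]]
    if (!length(nbr)) next
    vi <- v[i, ]
    out[i] <- mean(vapply(nbr, function(j) {
      vj <- v[j, ]
      keep <- !is.na(vi) & !is.na(vj)
      if (!any(keep)) 0 else .cosine(vi[keep], vj[keep])
    }, numeric(1)))
  }
  out
}

#' Per-cell speed
#'
#' The L2 norm of each cell's velocity over a feature subset; with the
#' subset restricted to viral features this is the infection speed, with all
#' features the cell-state transition speed.
#'
#' @param v cells x features velocity matrix (or a `cell_population` whose
#'   `vkey` layer is used). Missing entries contribute zero.
#' @param features optional feature subset.
#' @param vkey layer name when `v` is a population.
#' @return Non-negative numeric vector, one speed per cell.
#' @export
cell_speed <- function(v, features = NULL, vkey = "velocity") {
  if (inherits(v, "cell_population")) {
    features <- if (is.null(features)) seq_len(ncol(v$X))
                else .resolve_features(v, features)
    v <- .get_layer(v, vkey)
  } else {
    v <- .as_dense(v)
    if (is.null(features)) features <- seq_len(ncol(v))
  }
  vs <- v[, features, drop = FALSE]
  vs[is.na(vs)] <- 0
  .row_norms(vs)
}

#' Cell-specific kinetic rates from spliced/unspliced dynamics
#'
#' Under the splicing model \eqn{du/dt = \alpha - \beta u},
#' \eqn{ds/dt = \beta u - \gamma s} with the convention \eqn{\beta \equiv 1},
#' each cell's transcription rate and degradation rate constant follow from
#' its state and velocities:
#' \deqn{\alpha = u + du/dt, \qquad \gamma = (u - ds/dt)/s.}
#' `ds/dt` is the spliced velocity layer; `du/dt` is taken from an
#' unspliced-velocity layer when present, and otherwise inferred by fitting
#' projection weights on the spliced coordinates and transferring them to
#' the unspliced coordinates (basis swap). Entries with `s` below `eps` are
#' masked. A varying \eqn{\gamma} along a trajectory is the signature of
#' actively regulated degradation, which constant-rate estimators misread.
#'
#' @param pop a `cell_population` with layers `"spliced"`, `"unspliced"` and
#'   a spliced-velocity layer.
#' @param graph a [neighbor_graph()] (needed only when `du/dt` must be
#'   inferred); defaults to the population's graph.
#' @param config [tsp_config()] for the inference fit.
#' @param vkey spliced velocity layer name.
#' @param uvkey unspliced velocity layer name (used if present).
#' @param eps mask threshold on spliced abundance.
#' @return Object of class `kinetic_rates`: list with cells x features
#'   matrices `alpha` and `gamma` and a logical `mask` (TRUE = valid).
#' @export
cell_specific_rates <- function(pop, graph = NULL, config = tsp_config(),
                                vkey = "velocity", uvkey = "velocity_u",
                                eps = 1e-6) {
  validate_population(pop)
  s <- .get_layer(pop, "spliced")
  if (is.null(pop$layers$unspliced))
    stop("unspliced layer is required for kinetic rates", call. = FALSE)
  u <- pop$layers$unspliced
  ds <- .get_layer(pop, vkey)
  if (!is.null(pop$layers[[uvkey]])) {
    du <- pop$layers[[uvkey]]
  } else {
    if (is.null(graph)) graph <- pop$graph
    .gv_check(!is.null(graph),
              "a neighbor_graph is required to infer unspliced velocities")
    src <- which(colSums(!is.na(ds)) > 0L)
    fit <- graphvelo(pop$X[, src, drop = FALSE], ds[, src, drop = FALSE],
                     graph = graph, config = config)
    du <- matrix(NA_real_, nrow(u), ncol(u), dimnames = dimnames(u))
    du[, src] <- transform_velocity(fit, u[, src, drop = FALSE])
  }
  alpha <- u + du
  mask <- !is.na(ds) & !is.na(du) & (s >= eps)
  gamma <- matrix(NA_real_, nrow(s), ncol(s), dimnames = dimnames(s))
  gamma[mask] <- (u[mask] - ds[mask]) / s[mask]
  alpha[!mask] <- NA_real_
  structure(list(alpha = alpha, gamma = gamma, mask = mask),
            class = "kinetic_rates")
}

#' @export
print.kinetic_rates <- function(x, ...) {
  cat("kinetic_rates: ", nrow(x$alpha), " cells x ", ncol(x$alpha),
      " genes (", sum(x$mask), " valid entries)\n", sep = "")
  invisible(x)
}
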