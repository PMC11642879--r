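#' Penalized-spline fit of a velocity trend along a 1-D axis
#'
#' Smooths a gene's (projected) velocity along an ordering axis — pseudotime
#' or viral fraction — with a penalized cubic B-spline (P-spline: full
#' B-spline basis on equally spaced interior knots with a second-difference
#' coefficient penalty). The penalty weight is chosen by generalized
#' cross-validation over a fixed log-spaced candidate grid unless given.
#' Predictions are evaluated on a grid of `n_points` equally spaced points
#' covering the axis range; these smoothed trends feed clustering and
#' dynamic-time-warping comparisons.
#'
#' @param t per-cell axis values (finite, non-degenerate).
#' @param v per-cell velocity of one gene.
#' @param n_points evaluation grid size (default 100).
#' @param n_knots number of interior knots (default 10).
#' @param degree spline degree (default 3, cubic).
#' @param lambda penalty weight; `NULL` (default) selects by GCV from
#'   `10^seq(-6, 6, length.out = 25)`.
#' @param axis label stored on the fit.
#' @return Object of class `trend_fit`: `grid`, `values` (predictions on
#'   the grid), `coef`, `knots`, `degree`, `lambda`, `edf`, plus a
#'   `predict` method for arbitrary axis values.
#' @export
fit_velocity_trend <- function(t, v, n_points = 100L, n_knots = 10L,
                               degree = 3L, lambda = NULL,
                               axis = "pseudotime") {
  t <- as.numeric(t); v <- as.numeric(v)
  .gv_check(length(t) == length(v), "t and v must have equal length")
  .gv_check(all(is.finite(t)) && all(is.finite(v)), "t and v must be finite")
  .gv_check(length(t) >= 20L, "at least 20 cells are required")
  rng <- range(t)
  if (diff(rng) == 0)
    stop("degenerate axis: all values equal", call. = FALSE)
  knots <- .pspline_knots(rng, n_knots, degree)
  B <- splines::splineDesign(knots, t, ord = degree + 1L)
  p <- ncol(B)
  D <- diff(diag(p), differences = 2L)
  P <- crossprod(D)
  BtB <- crossprod(B)
  Btv <- as.numeric(crossprod(B, v))
  n <- length(t)
  if (is.null(lambda)) {
    grid_l <- 10^seq(-6, 6, length.out = 25L)
    gcv <- vapply(grid_l, function(l) {
      H <- solve(BtB + l * P, BtB)      # hat-matrix core; edf = tr(H)
      beta <- solve(BtB + l * P, Btv)
      rss <- sum((v - as.numeric(B %*% beta))^2)
      edf <- sum(diag(H))
      n * rss / (n - edf)^2
    }, numeric(1))
    lambda <- grid_l[which.min(gcv)]
  }
  A <- BtB + lambda * P
  beta <- solve(A, Btv)
  edf <- sum(diag(solve(A, BtB)))
  grid <- seq(rng[1], rng[2], length.out = n_points)
  Bg <- splines::splineDesign(knots, grid, ord = degree + 1L)
  structure(list(axis = axis, grid = grid,
                 values = as.numeric(Bg %*% beta),
                 coef = as.numeric(beta), knots = knots,
                 degree = as.integer(degree), lambda = lambda, edf = edf,
                 range = rng),
            class = "trend_fit")
}

.pspline_knots <- function(rng, n_knots, degree) {
  interior <- seq(rng[1], rng[2], length.out = n_knots + 2L)
  c(rep(rng[1], degree), interior, rep(rng[2], degree))
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("trend_fit on ", x$axis, ": degree ", x$degree, " P-spline, lambda = ",
      signif(x$lambda, 4), ", edf = ", signif(x$edf, 3), "\n", sep = "")
  invisible(x)
}

#' @export
predict.trend_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$values)
  newdata <- pmin(pmax(as.numeric(newdata), object$range[1]), object$range[2])
  Bg <- splines::splineDesign(object$knots, newdata, ord = object$degree + 1L)
  as.numeric(Bg %*% object$coef)
}

#' Smoothed velocity trends for many genes
#'
#' Applies [fit_velocity_trend()] to each column of a velocity matrix and
#' stacks the grid predictions.
#'
#' @param t per-cell axis values.
#' @param V cells x genes velocity matrix.
#' @param ... passed to [fit_velocity_trend()].
#' @return genes x n_points matrix of smoothed trends.
#' @export
velocity_trends <- function(t, V, ...) {
  V <- .as_dense(V)
  out <- t(apply(V, 2, function(col) fit_velocity_trend(t, col, ...)$values))
  rownames(out) <- colnames(V)
  out
}

#' Cluster velocity trends into kinetic modules
#'
#' Builds a kNN graph on the Euclidean distances between per-gene trend
#' vectors and partitions it with the Leiden algorithm (modularity
#' objective), grouping genes that share a kinetic pattern along the axis
#' (e.g. acceleration vs deceleration along an infection trajectory).
#'
#' @param trends genes x n_points matrix of smoothed trends.
#' @param k neighbourhood size of the trend graph (default 15).
#' @param resolution Leiden resolution parameter (default 0.3, favouring
#'   coarse modules).
#' @param seed RNG seed (the partition is seed-deterministic).
#' @return Integer cluster labels, one per gene (1-based).
#' @export
cluster_trends <- function(trends, k = 15L, resolution = 0.3, seed = 0L) {
  trends <- .as_dense(trends)
  n <- nrow(trends)
  .gv_check(n >= k + 1L, "need at least k + 1 genes to cluster")
  g <- build_knn(trends, k = k)
  edges <- cbind(rep.int(seq_len(n), lengths(g$indices)),
                 unlist(g$indices, use.names = FALSE))
  ig <- igraph::graph_from_edgelist(edges, directed = FALSE)
  ig <- igraph::simplify(ig)
  set.seed(seed)
  cl <- igraph::cluster_leiden(ig, objective_function = "modularity",
                               resolution = resolution, n_iterations = 5L)
  labels <- igraph::membership(cl)
  as.integer(labels)
}

#' Pointwise cluster summaries of trends
#'
#' @param trends genes x n_points matrix.
#' @param labels per-gene cluster labels.
#' @return Named list per cluster with `mean` and `sd` vectors (pointwise;
#'   population convention, so a singleton cluster has sd 0) and `size`.
#' @export
summarize_cluster <- function(trends, labels) {
  trends <- .as_dense(trends)
  .gv_check(length(labels) == nrow(trends), "one label per trend required")
  out <- list()
  for (cl in sort(unique(labels))) {
    sub <- trends[labels == cl, , drop = FALSE]
    mu <- colMeans(sub)
    sdv <- sqrt(colMeans(sweep(sub, 2, mu)^2))
    out[[as.character(cl)]] <- list(mean = mu, sd = sdv, size = nrow(sub))
  }
  out
}

#' Dynamic-time-warping distance between two sequences
#'
#' Classic DTW (symmetric step pattern, no window, absolute-difference local
#' cost) by the O(n m) dynamic program. Satisfies `dtw_distance(a, a) == 0`,
#' symmetry and non-negativity.
#'
#' @param a,b numeric sequences.
#' @return Non-negative scalar alignment cost.
#' @export
dtw_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a); m <- length(b)
  .gv_check(n >= 1L && m >= 1L, "sequences must be non-empty")
  prev <- c(0, rep(Inf, m))
  for (i in seq_len(n)) {
    cur <- rep(Inf, m + 1L)
    cost <- abs(a[i] - b)
    for (j in seq_len(m)) {
      cur[j + 1L] <- cost[j] + min(prev[j], prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[m + 1L]
}

## min-max normalisation to [0, 1]; constant sequences map to zeros
.minmax <- function(x) {
  r <- range(x)
  if (diff(r) == 0) return(rep(0, length(x)))
  (x - r[1]) / diff(r)
}

#' Detect transcription/chromatin decoupling by DTW distance
#'
#' Compares, per gene, the max-normalised RNA-velocity trend with the
#' max-normalised chromatin-velocity trend by DTW distance. Genes are ranked
#' by descending distance; the elbow of the ranked curve (point of maximum
#' perpendicular distance to the chord between its endpoints) sets the
#' cutoff, and genes with distance strictly above the cutoff are flagged as
#' decoupled — loci whose accessibility dynamics and transcription dynamics
#' disagree (e.g. cell-cycle genes staying open while transcription falls).
#'
#' @param rna_trends,chrom_trends genes x n_points matrices over matched
#'   genes.
#' @param genes optional gene names (defaults to `rownames(rna_trends)`).
#' @return Object of class `decoupling_report`: data.frame `table`
#'   (`gene`, `distance`, `rank`, `decoupled`), `elbow` (rank index of the
#'   elbow), `cutoff` (distance at the elbow), `decoupled` (character
#'   vector of flagged genes).
#' @export
dtw_decoupling <- function(rna_trends, chrom_trends, genes = NULL) {
  rna_trends <- .as_dense(rna_trends)
  chrom_trends <- .as_dense(chrom_trends)
  .gv_check(identical(dim(rna_trends), dim(chrom_trends)),
            "trend matrices must have identical shape (matched genes)")
  ng <- nrow(rna_trends)
  if (is.null(genes)) genes <- rownames(rna_trends)
  if (is.null(genes)) genes <- paste0("gene_", seq_len(ng))
  .gv_check(length(genes) == ng, "one gene name per trend required")
  d <- vapply(seq_len(ng), function(i)
    dtw_distance(.minmax(rna_trends[i, ]), .minmax(chrom_trends[i, ])),
    numeric(1))
  o <- order(-d, seq_len(ng))
  ranked <- d[o]
  elbow <- .elbow_index(ranked)
  cutoff <- ranked[elbow]
  decoupled_mask <- d > cutoff
  tab <- data.frame(gene = genes, distance = d,
                    rank = match(seq_len(ng), o),
                    decoupled = decoupled_mask,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, elbow = elbow, cutoff = cutoff,
                 decoupled = genes[decoupled_mask]),
            class = "decoupling_report")
}

## index of maximum perpendicular distance to the chord of a ranked curve;
## on step-like curves the distance is nearly flat along the lower plateau,
## so the first index within 1% of the maximum is taken (a tie-tolerant
## argmax that anchors the cutoff at the top of the plateau)
.elbow_index <- function(y) {
  n <- length(y)
  if (n < 3L) return(n)
  x <- seq_len(n)
  dx <- n - 1; dy <- y[n] - y[1]
  nrm <- sqrt(dx^2 + dy^2)
  if (nrm == 0) return(1L)
  dist <- abs(dy * (x - 1) - dx * (y - y[1])) / nrm
  which(dist >= max(dist) * (1 - 0.01))[1]
}

#' @export
print.decoupling_report <- function(x, ...) {
  cat("decoupling_report: ", nrow(x$table), " genes, ",
      length(x$decoupled), " decoupled (cutoff DTW = ",
      signif(x$cutoff, 4), " at rank ", x$elbow, ")\n", sep = "")
  if (length(x$decoupled))
    cat("  decoupled: ", paste(head(x$decoupled, 10), collapse = ", "),
        if (length(x$decoupled) > 10) ", ..." else "", "\n", sep = "")
  invisible(x)
}
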