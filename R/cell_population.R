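#' Annotated cell-by-feature container
#'
#' The central data structure: an expression (or accessibility) matrix `X`
#' of cells x features together with same-shaped layers (e.g. `"spliced"`,
#' `"unspliced"`, `"velocity"`), per-cell annotations `obs` (categories,
#' pseudotime, viral fraction, spatial coordinates), per-feature annotations
#' `var` (modality tag, velocity-gene flag, scores), named low-dimensional
#' embeddings `obsm`, an optional [neighbor_graph()], and a free-form `uns`
#' list.
#'
#' Velocity layers may contain `NA` for features that the upstream estimator
#' did not handle (non-velocity genes); those entries are masked everywhere
#' downstream. All other matrices must be finite.
#'
#' @param X cells x features numeric matrix.
#' @param layers named list of matrices with the same shape as `X`.
#' @param obs data.frame of per-cell annotations (`nrow(obs) == nrow(X)`).
#' @param var data.frame of per-feature annotations (`nrow(var) == ncol(X)`).
#' @param obsm named list of cells x d embedding matrices.
#' @param graph optional `neighbor_graph`.
#' @param uns free-form named list.
#' @return A validated object of class `cell_population`.
#' @export
cell_population <- function(X, layers = list(), obs = NULL, var = NULL,
                            obsm = list(), graph = NULL, uns = list()) {
  X <- .as_dense(X)
  n <- nrow(X); f <- ncol(X)
  df_named <- function(df) is.data.frame(df) &&
    !is.integer(attr(df, "row.names"))
  if (is.null(rownames(X)))
    rownames(X) <- if (df_named(obs) && nrow(obs) == n) rownames(obs)
                   else paste0("cell_", seq_len(n))
  if (is.null(colnames(X)))
    colnames(X) <- if (df_named(var) && nrow(var) == f) rownames(var)
                   else paste0("feature_", seq_len(f))
  if (is.null(obs)) obs <- data.frame(row.names = rownames(X))
  else rownames(obs) <- rownames(X)[seq_len(nrow(obs))]
  if (is.null(var)) var <- data.frame(row.names = colnames(X))
  else rownames(var) <- colnames(X)[seq_len(nrow(var))]
  layers <- lapply(layers, function(L) {
    L <- .as_dense(L)
    if (identical(dim(L), dim(X))) dimnames(L) <- dimnames(X)
    L
  })
  obsm <- lapply(obsm, function(M) {
    M <- .as_dense(M)
    if (nrow(M) == n) rownames(M) <- rownames(X)
    M
  })
  pop <- structure(list(X = X, layers = layers, obs = obs, var = var,
                        obsm = obsm, graph = graph, uns = uns),
                   class = "cell_population")
  validate_population(pop)
  pop
}

#' Validate a cell_population
#'
#' Checks every container invariant: `X` finite with no missing values,
#' layers shaped like `X` (missing values allowed only in velocity layers,
#' and, when a `velocity_gene` flag is present in `var`, only for features
#' not flagged as velocity genes), annotation row counts, embedding row
#' counts, and neighbour-graph index ranges. A violated invariant raises an
#' error naming the offending slot.
#'
#' @param pop a `cell_population`.
#' @return `pop`, invisibly.
#' @export
validate_population <- function(pop) {
  .gv_check(inherits(pop, "cell_population"), "not a cell_population")
  X <- pop$X
  n <- nrow(X); f <- ncol(X)
  .gv_check(!anyNA(X) && all(is.finite(X)),
            "X contains missing or non-finite values")
  .gv_check(is.data.frame(pop$obs) && nrow(pop$obs) == n,
            "obs must have one row per cell")
  .gv_check(is.data.frame(pop$var) && nrow(pop$var) == f,
            "var must have one row per feature")
  if (length(pop$layers))
    .gv_check(!is.null(names(pop$layers)) && all(nzchar(names(pop$layers))),
              "layers must be named")
  for (nm in names(pop$layers)) {
    L <- pop$layers[[nm]]
    if (!identical(dim(L), dim(X)))
      stop("layer '", nm, "' has shape ", nrow(L), "x", ncol(L),
           " but X is ", n, "x", f, call. = FALSE)
    is_velocity <- startsWith(nm, "velocity")
    if (!is_velocity) {
      .gv_check(!anyNA(L) && all(is.finite(L)),
                "layer '", nm, "' contains missing or non-finite values")
    } else {
      .gv_check(all(is.finite(L) | is.na(L)),
                "layer '", nm, "' contains non-finite (non-missing) values")
      if (!is.null(pop$var$velocity_gene)) {
        bad <- is.na(L) & rep(pop$var$velocity_gene, each = n)
        if (any(bad))
          stop("layer '", nm, "' has missing velocities for features ",
               "flagged velocity_gene = TRUE", call. = FALSE)
      }
    }
  }
  for (nm in names(pop$obsm)) {
    if (nrow(pop$obsm[[nm]]) != n)
      stop("embedding '", nm, "' has ", nrow(pop$obsm[[nm]]),
           " rows but there are ", n, " cells", call. = FALSE)
  }
  if (!is.null(pop$graph)) {
    .gv_check(inherits(pop$graph, "neighbor_graph"),
              "graph slot must be a neighbor_graph")
    .gv_check(pop$graph$n_cells == n,
              "graph is over ", pop$graph$n_cells, " cells but X has ", n)
  }
  invisible(pop)
}

#' @export
print.cell_population <- function(x, ...) {
  cat("cell_population: ", nrow(x$X), " cells x ", ncol(x$X), " features\n",
      sep = "")
  if (length(x$layers))
    cat("  layers: ", paste(names(x$layers), collapse = ", "), "\n", sep = "")
  if (ncol(x$obs)) cat("  obs: ", paste(names(x$obs), collapse = ", "), "\n",
                       sep = "")
  if (ncol(x$var)) cat("  var: ", paste(names(x$var), collapse = ", "), "\n",
                       sep = "")
  if (length(x$obsm))
    cat("  obsm: ", paste(names(x$obsm), collapse = ", "), "\n", sep = "")
  if (!is.null(x$graph))
    cat("  graph: ", x$graph$source, ", n = ", x$graph$n_cells, "\n", sep = "")
  invisible(x)
}

#' Dimensions of a cell_population
#' @param x a `cell_population`.
#' @export
dim.cell_population <- function(x) dim(x$X)

## internal: fetch a layer or fail with a clear message
.get_layer <- function(pop, name) {
  L <- pop$layers[[name]]
  if (is.null(L))
    stop("layer '", name, "' not found (available: ",
         paste(names(pop$layers), collapse = ", "), ")", call. = FALSE)
  L
}

## internal: resolve a feature selection (names, logical, or integer) to
## integer positions in column order
.resolve_features <- function(pop, features) {
  f <- ncol(pop$X)
  if (is.null(features)) return(seq_len(f))
  if (is.character(features)) {
    pos <- match(features, colnames(pop$X))
    .gv_check(!anyNA(pos), "unknown feature names: ",
              paste(features[is.na(pos)], collapse = ", "))
    return(pos)
  }
  if (is.logical(features)) {
    .gv_check(length(features) == f, "logical feature mask of wrong length")
    return(which(features))
  }
  features <- as.integer(features)
  .gv_check(all(features >= 1L & features <= f), "feature index out of range")
  features
}
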