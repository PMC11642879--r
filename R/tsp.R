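#' Configuration of the tangent-space-projection loss
#'
#' The per-cell loss minimised when projecting a velocity vector onto the
#' local tangent space spanned by neighbour displacements is
#' \deqn{L(\phi) = a\,\|v - \sum_j \phi_j \delta_j\|^2
#'       - b\,\cos(\phi, \phi^{corr}) + \lambda\,\|\phi\|^2,}
#' where the first term preserves the velocity magnitude, the cosine term
#' anchors the weights to the direction-correct cosine-kernel heuristic
#' \eqn{\phi^{corr}}, and the ridge term bounds the (possibly redundant)
#' weights. Defaults `a = 1`, `b = 10`, `lambda = 1` are the standard
#' settings.
#'
#' @param a magnitude weight, `>= 0`.
#' @param b direction (cosine) weight, `>= 0`.
#' @param lambda L2 regularisation weight, `>= 0`.
#' @param max_iter maximum quasi-Newton iterations per cell.
#' @param tol relative tolerance on the loss for convergence.
#' @param init initialisation: the closed-form ridge least-squares solution
#'   of the `b = 0` problem (default), the cosine-kernel weights, or zeros.
#' @return A list of class `tsp_config`.
#' @export
tsp_config <- function(a = 1, b = 10, lambda = 1, max_iter = 200L,
                       tol = 1e-6, init = c("least-squares", "cosine", "zeros")) {
  init <- match.arg(init)
  .gv_check(a >= 0 && b >= 0 && lambda >= 0, "a, b, lambda must be >= 0")
  .gv_check(a > 0 || b > 0 || lambda > 0, "a, b, lambda cannot all be zero")
  structure(list(a = a, b = b, lambda = lambda,
                 max_iter = as.integer(max_iter), tol = tol, init = init),
            class = "tsp_config")
}

#' Linear embedding (loading matrix)
#'
#' A linear map from feature space to a reduced representation, defined by a
#' loading matrix with orthonormal columns and a center vector, as produced
#' by PCA.
#'
#' @param loadings features x d matrix with orthonormal columns
#'   (checked to 1e-8).
#' @param center optional feature-space center (defaults to zeros).
#' @param explained_variance optional per-component variance.
#' @return An object of class `linear_embedding`.
#' @export
linear_embedding <- function(loadings, center = NULL,
                             explained_variance = NULL) {
  loadings <- .as_dense(loadings)
  gram <- crossprod(loadings)
  .gv_check(max(abs(gram - diag(ncol(loadings)))) < 1e-8,
            "loading columns must be orthonormal (tolerance 1e-8)")
  if (is.null(center)) center <- rep(0, nrow(loadings))
  .gv_check(length(center) == nrow(loadings), "center of wrong length")
  structure(list(loadings = loadings, center = as.numeric(center),
                 explained_variance = explained_variance),
            class = "linear_embedding")
}

#' Displacement basis vectors of each neighbourhood
#'
#' For cell i with neighbours j, the displacements
#' \eqn{\delta_{ij} = x_j - x_i} (restricted to `features`) form a complete
#' albeit redundant basis of the local tangent space.
#'
#' @param x cells x features coordinate matrix (or a `cell_population`,
#'   whose `X` is used).
#' @param g a [neighbor_graph()].
#' @param features optional feature subset (names, logical or positions).
#' @return A list with one d x k matrix per cell (columns are the
#'   \eqn{\delta_{ij}}, ordered as the graph's neighbour lists); cells with
#'   an empty neighbourhood get a zero-column matrix.
#' @export
displacement_basis <- function(x, g, features = NULL) {
  if (inherits(x, "cell_population")) {
    features <- .resolve_features(x, features)
    x <- x$X
  } else {
    x <- .as_dense(x)
    if (is.null(features)) features <- seq_len(ncol(x))
  }
  .gv_check(length(features) >= 1L, "feature subset must be non-empty")
  .gv_check(inherits(g, "neighbor_graph"), "g must be a neighbor_graph")
  .gv_check(nrow(x) == g$n_cells, "x rows must match graph cells")
  xs <- x[, features, drop = FALSE]
  lapply(seq_len(g$n_cells), function(i) {
    nbr <- g$indices[[i]]
    if (!length(nbr))
      return(matrix(0, length(features), 0))
    t(xs[nbr, , drop = FALSE]) - xs[i, ]
  })
}

#' Cosine-kernel weights
#'
#' The heuristic neighbour weights used throughout velocity-graph analyses:
#' \eqn{\phi^{corr}_{j} = \cos(v, \delta_j)}, with 0 wherever either vector
#' is all-zero. Direction-correct in the dense-sampling limit, but
#' magnitude-free.
#'
#' @param v velocity vector of one cell (length d).
#' @param deltas d x k matrix of displacement basis vectors (columns), as
#'   produced by [displacement_basis()].
#' @return Numeric weight vector of length k, values in \[-1, 1\].
#' @export
cosine_kernel_weights <- function(v, deltas) {
  deltas <- as.matrix(deltas)
  .gv_check(ncol(deltas) >= 1L, "at least one displacement required")
  .gv_check(length(v) == nrow(deltas), "v and deltas dimension mismatch")
  nv <- sqrt(sum(v^2))
  nd <- sqrt(colSums(deltas^2))
  w <- numeric(ncol(deltas))
  ok <- nd > 0 & nv > 0
  if (any(ok))
    w[ok] <- as.numeric(crossprod(deltas[, ok, drop = FALSE], v)) /
      (nd[ok] * nv)
  w
}

## loss and analytic gradient of the TSP objective for one cell.
## D: d x k displacement matrix, v: length-d velocity, pc: phi_corr.
.tsp_loss <- function(phi, v, D, pc, a, b, lambda, pc_norm) {
  r <- v - as.numeric(D %*% phi)
  out <- a * sum(r^2) + lambda * sum(phi^2)
  if (b > 0 && pc_norm > 0) {
    np <- sqrt(sum(phi^2))
    if (np > 0)
      out <- out - b * sum(phi * pc) / (np * pc_norm)
  }
  out
}

.tsp_grad <- function(phi, v, D, pc, a, b, lambda, pc_norm) {
  r <- v - as.numeric(D %*% phi)
  gr <- -2 * a * as.numeric(crossprod(D, r)) + 2 * lambda * phi
  if (b > 0 && pc_norm > 0) {
    np <- sqrt(sum(phi^2))
    if (np > 0) {
      cosv <- sum(phi * pc) / (np * pc_norm)
      gr <- gr - b * (pc / (np * pc_norm) - cosv * phi / np^2)
    }
  }
  gr
}

## closed-form minimiser of a||v - D phi||^2 + lambda||phi||^2 (the convex
## part); min-norm pseudo-inverse solution when the system is singular.
.tsp_ridge <- function(v, D, a, lambda) {
  k <- ncol(D)
  A <- a * crossprod(D) + diag(lambda, k)
  rhs <- a * as.numeric(crossprod(D, v))
  phi <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (is.null(phi)) phi <- as.numeric(MASS::ginv(A) %*% rhs)
  phi
}

#' Fit tangent-space-projection weights for one neighbourhood
#'
#' Minimises the TSP loss (see [tsp_config()]) for a single cell by a
#' quasi-Newton (BFGS) search with analytic gradient, initialised at the
#' closed-form ridge solution of the quadratic part. With `b = 0` the
#' objective is quadratic and the closed form is returned directly. Velocity
#' dimensions that are missing (`NA`) are dropped from both `v` and the
#' displacement rows before fitting; the returned weights still apply to the
#' full basis.
#'
#' @param v velocity vector of one cell (may contain `NA`).
#' @param deltas d x k displacement matrix (columns are neighbours).
#' @param config a [tsp_config()].
#' @return List with elements `phi` (length k), `phi_corr`, `loss`
#'   (final objective), `loss0` (objective at initialisation), `iterations`,
#'   `converged`. Non-convergence after `max_iter` produces a warning and
#'   the best iterate, never an error. An all-zero `v` short-circuits to
#'   `phi = 0`.
#' @export
fit_tsp_weights <- function(v, deltas, config = tsp_config()) {
  D <- as.matrix(deltas)
  .gv_check(ncol(D) >= 1L, "at least one displacement required")
  keep <- !is.na(v)
  .gv_check(any(keep), "velocity vector entirely missing")
  v_f <- as.numeric(v[keep])
  D_f <- D[keep, , drop = FALSE]
  .gv_check(all(is.finite(v_f)), "velocity vector must be finite where present")
  k <- ncol(D)
  pc <- cosine_kernel_weights(v_f, D_f)
  a <- config$a; b <- config$b; lambda <- config$lambda
  pc_norm <- sqrt(sum(pc^2))
  if (all(v_f == 0)) {
    return(list(phi = numeric(k), phi_corr = pc, loss = 0, loss0 = 0,
                iterations = 0L, converged = TRUE))
  }
  phi0 <- switch(config$init,
                 "least-squares" = .tsp_ridge(v_f, D_f, a, lambda),
                 "cosine" = pc,
                 "zeros" = numeric(k))
  loss0 <- .tsp_loss(phi0, v_f, D_f, pc, a, b, lambda, pc_norm)
  if (b == 0 || pc_norm == 0) {
    ## purely quadratic objective: the ridge solution is the exact optimum
    phi <- if (config$init == "least-squares") phi0
           else .tsp_ridge(v_f, D_f, a, lambda)
    loss <- .tsp_loss(phi, v_f, D_f, pc, a, b, lambda, pc_norm)
    return(list(phi = phi, phi_corr = pc, loss = loss, loss0 = loss0,
                iterations = 0L, converged = TRUE))
  }
  opt <- optim(phi0, fn = .tsp_loss, gr = .tsp_grad,
               v = v_f, D = D_f, pc = pc, a = a, b = b, lambda = lambda,
               pc_norm = pc_norm,
               method = "BFGS",
               control = list(maxit = config$max_iter, reltol = config$tol))
  if (opt$convergence == 1L)
    warning("TSP optimisation did not converge within ", config$max_iter,
            " iterations; returning best iterate", call. = FALSE)
  loss <- opt$value
  phi <- opt$par
  ## BFGS starts at phi0, so the final loss can never exceed loss0
  if (loss > loss0) { phi <- phi0; loss <- loss0 }
  list(phi = phi, phi_corr = pc, loss = loss, loss0 = loss0,
       iterations = as.integer(opt$counts[["function"]]),
       converged = opt$convergence == 0L)
}
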