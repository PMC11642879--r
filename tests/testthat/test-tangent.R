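test_that("displacement bases are the neighbour differences", {
  x <- rbind(c(0, 0), c(1, 2))
  g <- neighbor_graph(list(2L, 1L), list(sqrt(5), sqrt(5)), 2)
  d <- displacement_basis(x, g)
  expect_equal(d[[1]], matrix(c(1, 2), 2, 1))
  expect_equal(d[[2]], matrix(c(-1, -2), 2, 1))
  ## single-feature subsets give scalars; fixture vs direct subtraction
  set.seed(6)
  x <- matrix(rnorm(15 * 4), 15, 4)
  g <- build_knn(x, k = 4)
  d1 <- displacement_basis(x, g, features = 2)
  dall <- displacement_basis(x, g)
  for (i in c(1, 7, 15)) {
    expect_identical(nrow(d1[[i]]), 1L)
    for (jpos in seq_along(g$indices[[i]])) {
      j <- g$indices[[i]][jpos]
      expect_equal(dall[[i]][, jpos], x[j, ] - x[i, ])
    }
  }
})

test_that("cosine-kernel weights reproduce cosine identities", {
  v <- c(2, 0)
  deltas <- cbind(c(1, 0), c(0, 3))      # parallel and orthogonal
  expect_equal(cosine_kernel_weights(v, deltas), c(1, 0))
  expect_equal(cosine_kernel_weights(v, cbind(c(-4, 0))), -1)
  ## zero vectors contribute weight 0
  expect_equal(cosine_kernel_weights(c(0, 0), deltas), c(0, 0))
  expect_equal(cosine_kernel_weights(v, cbind(c(0, 0), c(1, 1)))[1], 0)
  ## random instance vs dot-product oracle
  set.seed(7)
  v <- rnorm(6); D <- matrix(rnorm(30), 6, 5)
  expect_equal(cosine_kernel_weights(v, D),
               apply(D, 2, function(d)
                 sum(v * d) / sqrt(sum(v^2) * sum(d^2))))
})

test_that("TSP weights solve the projection problem", {
  set.seed(8)
  ## exact representability: v in span(deltas), pure least squares
  D <- matrix(rnorm(12), 4, 3)
  v <- as.numeric(D %*% c(0.3, -1, 2))
  fit <- fit_tsp_weights(v, D, tsp_config(a = 1, b = 0, lambda = 0))
  expect_lt(sqrt(sum((as.numeric(D %*% fit$phi) - v)^2)), 1e-6 * sqrt(sum(v^2)))
  ## orthogonal v projects to (almost) nothing
  qr_D <- qr(D)
  v_orth <- rnorm(4)
  v_orth <- v_orth - qr.fitted(qr_D, v_orth)
  fit2 <- fit_tsp_weights(v_orth, D, tsp_config(a = 1, b = 0, lambda = 1e-8))
  expect_lt(sqrt(sum(as.numeric(D %*% fit2$phi)^2)),
            1e-4 * sqrt(sum(v_orth^2)))
  ## all-zero velocity short-circuits to zero weights
  fit0 <- fit_tsp_weights(c(0, 0, 0, 0), D, tsp_config())
  expect_identical(fit0$phi, numeric(3))
  ## final loss never exceeds the loss at initialisation
  for (rep in 1:20) {
    v <- rnorm(5); D2 <- matrix(rnorm(5 * 4), 5, 4)
    f <- fit_tsp_weights(v, D2, tsp_config())
    expect_lte(f$loss, f$loss0 + 1e-12)
  }
})

test_that("TSP optimum matches a dense grid search on a small instance", {
  set.seed(9)
  v <- c(1, 0.5, -0.2)
  D <- matrix(rnorm(9), 3, 3)
  cfg <- tsp_config(a = 1, b = 10, lambda = 1)
  fit <- fit_tsp_weights(v, D, cfg)
  pc <- cosine_kernel_weights(v, D)
  pcn <- sqrt(sum(pc^2))
  step <- 0.01
  gr <- seq(-3, 3, by = step)
  ## chunked exhaustive evaluation of the loss over the phi grid
  g23 <- as.matrix(expand.grid(gr, gr))
  base23 <- g23 %*% t(D[, 2:3])            # contribution of phi2, phi3
  n2 <- rowSums(g23^2)
  cos_part <- g23 %*% pc[2:3]
  best <- Inf
  for (p1 in gr) {
    R <- base23 + matrix(p1 * D[, 1], nrow(g23), 3, byrow = TRUE)
    R <- sweep(R, 2, v)
    l <- rowSums(R^2) + (n2 + p1^2)
    np <- sqrt(n2 + p1^2)
    cosv <- (cos_part + p1 * pc[1]) / (np * pcn)
    cosv[np == 0] <- 0
    best <- min(best, min(l - 10 * cosv))
  }
  ## optimiser at least as good as the grid, and the grid bounds it closely
  expect_lte(fit$loss, best + 1e-8)
  expect_lte(best - fit$loss, step)
})

test_that("with b = 0, lambda = 0 the projection is ordinary least squares", {
  set.seed(10)
  cfg <- tsp_config(a = 1, b = 0, lambda = 0)
  for (rep in 1:30) {
    d <- sample(2:10, 1); k <- sample(1:10, 1)
    D <- matrix(rnorm(d * k), d, k)
    v <- rnorm(d)
    fit <- fit_tsp_weights(v, D, cfg)
    vproj <- as.numeric(D %*% fit$phi)
    oracle <- ls_projection(v, D)
    expect_lt(sqrt(sum((vproj - oracle)^2)),
              1e-6 * max(sqrt(sum(oracle^2)), 1e-8))
  }
})

test_that("projected velocities reconstruct from their own weights", {
  sp <- sphere_fixture(n_cells = 300, seed = 12)
  g <- build_knn(sp$states, k = 15)
  fit <- graphvelo(sp$states, sp$velocities, graph = g)
  ## tangency: fitted vectors equal the weighted displacement sums exactly
  deltas <- displacement_basis(sp$states, g)
  recon <- t(vapply(seq_len(300), function(i)
    as.numeric(deltas[[i]] %*% fit$weights[[i]]), numeric(3)))
  expect_equal(unname(fitted(fit)), recon, tolerance = 1e-8)
  ## noise-free tangent field is faithfully recovered
  cs <- cosine_rows(fitted(fit), sp$velocities_true)
  expect_gte(median(cs), 0.99)
  ## residual accessor is consistent
  expect_equal(residuals(fit), fit$v - fitted(fit))
})

test_that("velocities already in displacement form are a fixed point", {
  set.seed(13)
  x <- matrix(rnorm(40 * 3), 40, 3)
  g <- build_knn(x, k = 6)
  deltas <- displacement_basis(x, g)
  v <- t(vapply(seq_len(40), function(i)
    as.numeric(deltas[[i]] %*% rnorm(6, sd = 0.3)), numeric(3)))
  fit <- graphvelo(x, v, graph = g, config = tsp_config(a = 1, b = 0, lambda = 0))
  expect_equal(unname(fitted(fit)), unname(v), tolerance = 1e-6)
})

test_that("velocity transfer is exactly equivariant under linear maps", {
  set.seed(14)
  x <- matrix(rnorm(30 * 4), 30, 4)
  g <- build_knn(x, k = 5)
  v <- matrix(rnorm(30 * 4), 30, 4)
  fit <- graphvelo(x, v, graph = g)
  ## identity map reproduces the fitted velocities
  expect_equal(unname(predict(fit, x)), unname(fitted(fit)), tolerance = 1e-12)
  ## arbitrary linear map commutes exactly
  A <- matrix(rnorm(4 * 6), 4, 6)
  expect_equal(unname(predict(fit, x %*% A)), unname(fitted(fit) %*% A),
               tolerance = 1e-12)
  expect_error(predict(fit, x[1:10, ]), "rows")
})

test_that("subspace fits transfer to linearly dependent features exactly", {
  set.seed(15)
  n <- 25
  base <- matrix(rnorm(n * 2), n, 2)
  ## five-feature space where feature 3 = feature 1 + feature 2
  X <- cbind(base, base[, 1] + base[, 2], matrix(rnorm(n * 2), n, 2))
  colnames(X) <- paste0("g", 1:5)
  v <- matrix(rnorm(n * 5), n, 5)
  v[, 3:5] <- NA
  pop <- cell_population(X, layers = list(velocity = v))
  g <- build_knn(X, k = 5)
  out <- infer_unmeasured_velocity(pop, g, source_features = 1:2,
                                   target_features = 1:3)
  expect_equal(out[, 3], out[, 1] + out[, 2], tolerance = 1e-10)
  ## restricted to the source it reproduces the direct projection
  pr <- project_velocities(pop, g)
  direct <- fitted(pr$fit)
  expect_equal(unname(out[, 1:2]), unname(direct), tolerance = 1e-10)
  expect_equal(unname(pr$population$layers$velocity_graphvelo[, 1:2]),
               unname(direct))
  ## constant target feature implies zero inferred velocity
  Xc <- cbind(base, 3)
  out2 <- infer_unmeasured_velocity(
    cell_population(Xc, layers = list(velocity = cbind(v[, 1:2], NA))),
    g, source_features = 1:2, target_features = 3)
  expect_equal(unname(out2), matrix(0, n, 1), tolerance = 1e-12)
})

test_that("adaptive step size follows the local scale over speed", {
  ## regular 1-d grid: dt = spacing / speed for interior cells
  x <- matrix(seq(0, 9), ncol = 1)
  g <- build_knn(x, k = 2)
  v <- matrix(2, 10, 1)
  dt <- adaptive_step_size(x, g, v)
  expect_equal(dt[3:8], rep(0.5, 6))
  ## zero speed is undefined
  v[4, ] <- 0
  expect_true(is.na(adaptive_step_size(x, g, v)[4]))
  ## random fixture vs direct median computation
  set.seed(16)
  x <- matrix(rnorm(20 * 3), 20, 3)
  g <- build_knn(x, k = 4)
  v <- matrix(rnorm(20 * 3), 20, 3)
  dt <- adaptive_step_size(x, g, v)
  i <- 9
  dn <- sqrt(colSums((t(x[g$indices[[i]], ]) - x[i, ])^2))
  expect_equal(dt[i], median(dn) / sqrt(sum(v[i, ]^2)))
})

test_that("embedding velocities equal the loading-matrix image", {
  set.seed(17)
  x <- matrix(rnorm(25 * 5), 25, 5)
  g <- build_knn(x, k = 4)
  v <- matrix(rnorm(25 * 5), 25, 5)
  Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  ## algebraic identity: the adaptive step cancels
  emb2 <- linear_embedding(Q[, 1:2], center = rnorm(5))
  out <- velocity_to_embedding(x, emb2, g, v)
  expect_equal(unname(out), unname(v %*% Q[, 1:2]), tolerance = 1e-8,
               ignore_attr = TRUE)
  ## full-rank orthonormal loading preserves speeds exactly
  embf <- linear_embedding(Q)
  outf <- velocity_to_embedding(x, embf, g, v)
  expect_equal(sqrt(rowSums(outf^2)), sqrt(rowSums(v^2)), tolerance = 1e-8)
  ## rank-2 projection contracts speeds
  expect_true(all(sqrt(rowSums(out^2)) <= sqrt(rowSums(v^2)) + 1e-10))
  ## zero velocity -> undefined step -> zero embedded vector, flagged
  v[3, ] <- 0
  out0 <- velocity_to_embedding(x, emb2, g, v)
  expect_equal(out0[3, ], c(0, 0), ignore_attr = TRUE)
  expect_true(3 %in% attr(out0, "undefined_step"))
})

test_that("the cosine baseline keeps direction but not magnitude", {
  ## single neighbour, parallel velocity: output parallel to the displacement
  x <- rbind(c(0, 0), c(2, 0))
  g <- neighbor_graph(list(2L, 1L), list(2, 2), 2)
  v <- rbind(c(5, 0), c(-1, 0))
  bl <- baseline_cosine_projection(x, g, v)
  expect_equal(bl[1, ], c(2, 0))    # direction of delta, magnitude |delta|
  ## symmetric opposing neighbours, orthogonal velocity: cancellation
  x3 <- rbind(c(-1, 0), c(0, 0), c(1, 0))
  g3 <- neighbor_graph(list(2L, c(1L, 3L), 2L), list(1, c(1, 1), 1), 3)
  v3 <- rbind(c(0, 1), c(0, 1), c(0, 1))
  expect_equal(baseline_cosine_projection(x3, g3, v3)[2, ], c(0, 0))
  ## magnitude is not preserved while the TSP projection preserves it
  sp <- sphere_fixture(n_cells = 400, seed = 18)
  g <- build_knn(sp$states, k = 20)
  bl <- baseline_cosine_projection(sp$states, g, sp$velocities)
  fit <- graphvelo(sp$states, sp$velocities, graph = g)
  expect_gte(median(cosine_rows(bl, sp$velocities_true)), 0.9)
  r_tsp <- cor(sqrt(rowSums(fitted(fit)^2)),
               sqrt(rowSums(sp$velocities_true^2)))
  r_bl <- cor(sqrt(rowSums(bl^2)), sqrt(rowSums(sp$velocities_true^2)))
  expect_gte(r_tsp, 0.99)
  expect_lt(r_bl, r_tsp)
})

test_that("fits are deterministic and independent of cell order", {
  set.seed(19)
  x <- matrix(rnorm(30 * 3), 30, 3)
  g <- build_knn(x, k = 5)
  v <- matrix(rnorm(30 * 3), 30, 3)
  f1 <- graphvelo(x, v, graph = g)
  f2 <- graphvelo(x, v, graph = g)
  expect_identical(fitted(f1), fitted(f2))
  ## permuting the cells permutes the result
  perm <- sample(30)
  gp <- build_knn(x[perm, ], k = 5)
  fp <- graphvelo(x[perm, ], v[perm, ], graph = gp)
  expect_equal(unname(fitted(fp)), unname(fitted(f1)[perm, ]),
               tolerance = 1e-6)
})
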