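test_that("MacK scores reach the concordant and anti-concordant extremes", {
  n <- 60
  t <- seq(0, 1, length.out = n)
  x <- cbind(gene_up = t, gene_down = 1 - t)
  g <- build_knn(cbind(t), k = 4)
  v_good <- cbind(rep(1, n), rep(-1, n))
  ms <- mack_score(x, g, t, v_good)
  expect_equal(unname(ms$gene), c(1, 1))
  ## negated velocities score zero
  ms_bad <- mack_score(x, g, t, -v_good)
  expect_equal(unname(ms_bad$gene), c(0, 0))
  ## zero velocity only matches a zero finite difference
  ms_zero <- mack_score(x, g, t, 0 * v_good)
  expect_equal(unname(ms_zero$gene), c(0, 0))
})

test_that("MacK is 1/2 under a random-sign null and handles tied pseudotime", {
  set.seed(20)
  n <- 500
  t <- runif(n)
  x <- apply(matrix(rnorm(n * 4), n, 4), 2, cumsum)
  g <- build_knn(cbind(t), k = 10)
  v <- matrix(sample(c(-1, 1), n * 4, replace = TRUE), n, 4)
  ms <- mack_score(x, g, t, v)
  expect_true(all(abs(ms$gene - 0.5) < 0.05))
  ## all neighbours tied in t: the cell is excluded, not scored
  t2 <- rep(1, 5)
  g2 <- neighbor_graph(list(2L, 1L, 2L, 5L, 4L), as.list(rep(1, 5)), 5)
  ms2 <- mack_score(matrix(rnorm(5), 5, 1), g2, t2,
                    matrix(1, 5, 1))
  expect_true(all(is.na(ms2$cell_gene)))
  expect_true(is.na(ms2$gene))
})

test_that("MacK gene selection ranks by score with index tie-breaks", {
  expect_identical(select_mack_genes(c(0.9, 0.1, 0.9), top_n = 2), c(1L, 3L))
  sc <- c(0.3, 0.8, 0.1, 0.8)
  expect_identical(select_mack_genes(sc), c(2L, 4L, 1L, 3L))
  expect_error(select_mack_genes(sc, top_n = 9), "exceeds")
  ## constructed cohort: concordant genes outrank sign-flipped ones exactly
  set.seed(21)
  n <- 120
  t <- seq(0, 1, length.out = n)
  x <- matrix(rep(t, 20), n, 20) + matrix(rnorm(n * 20, 0, 0.01), n, 20)
  g <- build_knn(cbind(t), k = 6)
  v <- cbind(matrix(1, n, 10), matrix(-1, n, 10))
  ms <- mack_score(x, g, t, v)
  expect_setequal(select_mack_genes(ms$gene, 10), 1:10)
})

test_that("CBC reaches +/-1 on constructed boundaries and 0 on a null", {
  ## hand-built boundary fixture: every A cell has exactly one B neighbour
  ## and a velocity pointing straight at it
  set.seed(22)
  xs <- matrix(rnorm(6 * 3), 6, 3)
  lab_s <- rep(c("A", "B"), each = 3)
  gs <- neighbor_graph(
    indices = list(c(4L, 2L), c(5L, 3L), c(6L, 1L),
                   c(5L, 6L), c(4L, 6L), c(4L, 5L)),
    distances = rep(list(c(1, 2)), 6), 6)
  vs <- rbind(xs[4, ] - xs[1, ], xs[5, ] - xs[2, ], xs[6, ] - xs[3, ],
              matrix(0, 3, 3))
  expect_equal(cbc_score(xs, gs, lab_s, "A", "B", v = vs), 1)
  expect_equal(cbc_score(xs, gs, lab_s, "A", "B", v = -vs), -1)
  ## antisymmetry holds on any fixture
  n <- 40; d <- 3
  x <- matrix(rnorm(n * d), n, d)
  labels <- rep(c("A", "B"), each = n / 2)
  g <- build_knn(x, k = 5)
  v_r <- matrix(rnorm(n * d), n, d)
  expect_equal(cbc_score(x, g, labels, "A", "B", v = v_r) +
                 cbc_score(x, g, labels, "A", "B", v = -v_r), 0)
  ## isotropic null in 10-d
  set.seed(23)
  n2 <- 400
  x2 <- matrix(rnorm(n2 * 10), n2, 10)
  lab2 <- rep(c("A", "B"), each = n2 / 2)
  g2 <- build_knn(x2, k = 15)
  v2 <- matrix(rnorm(n2 * 10), n2, 10)
  expect_lt(abs(cbc_score(x2, g2, lab2, "A", "B", v = v2)), 0.05)
  ## missing boundary yields NA with a message
  far <- rbind(matrix(0, 5, 2) + rnorm(10, 0, 0.1),
               matrix(100, 5, 2) + rnorm(10, 0, 0.1))
  gf <- build_knn(far, k = 2)
  expect_message(
    res <- cbc_score(far, gf, rep(c("A", "B"), each = 5), "A", "B",
                     v = matrix(1, 10, 2)),
    "no boundary")
  expect_true(is.na(res))
})

test_that("velocity consistency matches the pairwise-cosine oracle", {
  ## identical velocities are perfectly consistent
  set.seed(24)
  x <- matrix(rnorm(20 * 3), 20, 3)
  g <- build_knn(x, k = 4)
  v_same <- matrix(rep(c(1, 2, -1), each = 20), 20, 3)
  expect_equal(velocity_consistency(x, g, v_same), rep(1, 20))
  ## alternating opposite velocities on a mutual pair
  g2 <- neighbor_graph(list(2L, 1L), list(1, 1), 2)
  v2 <- rbind(c(1, 0), c(-1, 0))
  expect_equal(velocity_consistency(matrix(0, 2, 2), g2, v2), c(-1, -1))
  ## random fixture vs direct oracle
  v <- matrix(rnorm(20 * 3), 20, 3)
  ci <- velocity_consistency(x, g, v)
  for (i in c(2, 11, 20)) {
    oracle <- mean(vapply(g$indices[[i]], function(j)
      sum(v[i, ] * v[j, ]) / sqrt(sum(v[i, ]^2) * sum(v[j, ]^2)), numeric(1)))
    expect_equal(ci[i], oracle)
  }
  ## invariance under positive rescaling of the velocities
  expect_equal(velocity_consistency(x, g, 17 * v), ci)
})

test_that("cell speed is the restricted L2 norm", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(3, 4, 12))
  expect_equal(cell_speed(v), c(0, 1, 13))
  expect_equal(cell_speed(v, features = 1:2), c(0, 1, 5))
  ## NA entries (non-velocity genes) contribute nothing
  v[2, 3] <- NA
  expect_equal(cell_speed(v), c(0, 1, 13))
})

test_that("cell-specific rates recover the generating kinetics", {
  ## steady state: alpha = u, gamma = u/s
  n <- 25
  mk <- function(val) matrix(val, n, 1)
  pop <- cell_population(mk(4), layers = list(
    spliced = mk(4), unspliced = mk(2),
    velocity = mk(0), velocity_u = mk(0)))
  kr <- cell_specific_rates(pop)
  expect_equal(unname(kr$alpha[, 1]), rep(2, n))
  expect_equal(unname(kr$gamma[, 1]), rep(0.5, n))
  ## zero spliced abundance is masked
  pop2 <- cell_population(mk(0), layers = list(
    spliced = mk(0), unspliced = mk(2), velocity = mk(0), velocity_u = mk(0)))
  kr2 <- cell_specific_rates(pop2)
  expect_true(all(is.na(kr2$gamma)))
  ## missing unspliced layer is an error
  pop3 <- cell_population(mk(1), layers = list(spliced = mk(1),
                                               velocity = mk(0)))
  expect_error(cell_specific_rates(pop3), "unspliced")
  ## variable-degradation trajectory with exact derivatives: gamma(t)
  ## tracks gamma0 + k_gamma * m(t); alpha tracks alpha0 - k_alpha * m(t)
  traj <- simulate_variable_degradation()
  popk <- kinetics_population(traj)
  krk <- cell_specific_rates(popk)
  ok <- krk$mask[, 1]
  expect_true(all(abs(krk$gamma[ok, 1] - traj$gamma_t[ok]) <=
                    0.05 * traj$gamma_t[ok]))
  expect_true(all(abs(krk$alpha[ok, 1] - traj$alpha_t[ok]) <=
                    0.05 * traj$alpha_t[ok] + 1e-9))
})

test_that("cosine-based scores are scale-invariant and order-equivariant", {
  set.seed(25)
  n <- 50
  x <- matrix(rnorm(n * 4), n, 4)
  t <- runif(n)
  g <- build_knn(x, k = 6)
  v <- matrix(rnorm(n * 4), n, 4)
  labels <- rep(c("A", "B"), length.out = n)
  expect_equal(cbc_score(x, g, labels, "A", "B", v = 3 * v),
               cbc_score(x, g, labels, "A", "B", v = v))
  ## permuting cells permutes MacK per-cell scores and leaves means intact
  ms <- mack_score(x, g, t, v)
  perm <- sample(n)
  gp <- build_knn(x[perm, ], k = 6)
  msp <- mack_score(x[perm, ], gp, t[perm], v[perm, ])
  expect_equal(unname(msp$cell_gene), unname(ms$cell_gene[perm, ]))
  expect_equal(msp$gene, ms$gene)
})
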