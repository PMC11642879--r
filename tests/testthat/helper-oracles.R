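## Shared independent oracles and fixture builders for the suite.

## exhaustive kNN oracle: all-pairs distances, ties by ascending index
brute_knn <- function(coords, k) {
  n <- nrow(coords)
  lapply(seq_len(n), function(i) {
    d <- sqrt(colSums((t(coords) - coords[i, ])^2))
    d[i] <- Inf
    order(d, seq_len(n))[seq_len(k)]
  })
}

## per-row cosine similarity between two matrices (0 for zero rows)
cosine_rows <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    na <- sqrt(sum(a[i, ]^2)); nb <- sqrt(sum(b[i, ]^2))
    if (na == 0 || nb == 0) 0 else sum(a[i, ] * b[i, ]) / (na * nb)
  }, numeric(1))
}

## adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

## ordinary least-squares projection of v onto span of the columns of D
## (normal equations with pseudo-inverse for rank deficiency)
ls_projection <- function(v, D) {
  phi <- MASS::ginv(crossprod(D)) %*% crossprod(D, v)
  as.numeric(D %*% phi)
}

## memoised recursive DTW oracle (symmetric step, |.| local cost)
dtw_recursive <- function(a, b) {
  n <- length(a); m <- length(b)
  memo <- matrix(NA_real_, n, m)
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    if (i == 0 || j == 0) return(Inf)
    if (!is.na(memo[i, j])) return(memo[i, j])
    val <- abs(a[i] - b[j]) + min(rec(i - 1, j), rec(i, j - 1),
                                  rec(i - 1, j - 1))
    memo[i, j] <<- val
    val
  }
  rec(n, m)
}

## standard noise-free sphere benchmark fixture (shared across files)
sphere_fixture <- function(n_cells = 500, seed = 11) {
  res <- simulate_toggle_switch(n_cells = n_cells, seed = seed)
  embed_on_sphere(res)
}

## random annotated population fixture
random_population <- function(n = 12, f = 6, seed = 42, with_graph = TRUE) {
  set.seed(seed)
  X <- matrix(runif(n * f, 0, 10), n, f)
  v <- matrix(rnorm(n * f), n, f)
  v[, f] <- NA   # one non-velocity gene
  g <- if (with_graph) build_knn(X, k = 3) else NULL
  cell_population(
    X,
    layers = list(spliced = X, unspliced = X / 2, velocity = v),
    obs = data.frame(category = rep(c("A", "B"), length.out = n),
                     pseudotime = seq(0, 1, length.out = n)),
    var = data.frame(modality = rep("rna", f),
                     velocity_gene = c(rep(TRUE, f - 1), FALSE)),
    obsm = list(pca = matrix(rnorm(n * 2), n, 2)),
    graph = g)
}
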