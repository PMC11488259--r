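test_that("exact KNN matches hand geometry and a brute-force oracle", {
  # collinear points at 0, 1, 3: nearest neighbours are (2, 1, 2)
  emb <- matrix(c(0, 1, 3), ncol = 1)
  g <- build_knn(emb, K = 1)
  expect_equal(as.vector(g$nn), c(2L, 1L, 2L))

  set.seed(4)
  coords <- matrix(rnorm(50 * 3), 50, 3)
  g5 <- build_knn(coords, K = 5)
  d <- as.matrix(dist(coords))
  for (i in 1:50) {
    di <- d[i, ]; di[i] <- Inf
    oracle <- order(di, seq_len(50))[1:5]
    expect_identical(g5$nn[i, ], oracle)
    expect_true(all(diff(g5$dist[i, ]) >= -1e-12))
    expect_false(i %in% g5$nn[i, ])
  }
  expect_error(build_knn(coords, K = 0), "positive")
  expect_error(build_knn(coords, K = 50), "smaller")
})

test_that("local NB background reproduces the quadratic variance fit", {
  tp <- two_population_counts(genes = 30, cells = 40, n_shift = 10, seed = 2)
  g <- build_knn(compute_pca(normalize_counts(tp$counts), 5), K = 8)
  model <- fit_local_background(tp$counts, g, cell = 3)
  members <- c(3, g$nn[3, ])
  mat <- as.matrix(tp$counts$values[, members])
  lib <- colSums(mat)
  mat <- round(sweep(mat, 2, median(lib[lib > 0]) / lib, "*"))
  mu <- rowMeans(mat)
  expect_equal(model$mu, mu, tolerance = 1e-12)
  # independent quadratic least squares on (log mu, log var)
  v <- apply(mat, 1, var)
  ok <- mu > 0 & v > 0
  co <- unname(coef(lm(log(v[ok]) ~ log(mu[ok]) + I(log(mu[ok])^2))))
  expect_equal(model$coef, co, tolerance = 1e-10)
  v_fit <- pmax(exp(co[1] + co[2] * log(mu[ok]) + co[3] * log(mu[ok])^2),
                mu[ok] * (1 + 1e-6))
  expect_equal(model$size[ok], mu[ok]^2 / (v_fit - mu[ok]), tolerance = 1e-8)
  expect_true(all(model$size > 0))
})

test_that("identical neighbourhood columns give a near-Poisson model", {
  m <- matrix(rep(c(5, 2, 0, 7, 1, 3), 10), ncol = 10,
              dimnames = list(paste0("g", 1:6), paste0("c", 1:10)))
  cm <- count_matrix(m)
  g <- structure(list(nn = matrix(rep(2:10, each = 10), 10, 9, byrow = TRUE),
                      dist = matrix(0, 10, 9), K = 9L), class = "knn_graph")
  model <- fit_local_background(cm, g, cell = 1)
  # zero empirical variance -> clipped at Poisson; size very large
  expect_true(all(model$size[model$mu > 0] > 1e5))
  # doubling all counts doubles every mu
  cm2 <- count_matrix(2 * m)
  model2 <- fit_local_background(cm2, g, cell = 1)
  expect_equal(model2$mu, 2 * model$mu, tolerance = 1e-12)
})

test_that("NB tail probability agrees with explicit pmf summation", {
  cases <- expand.grid(mu = c(0.5, 2, 5, 20), size = c(0.5, 2, 50),
                       x = c(0, 1, 3, 10, 60, 200))
  for (i in seq_len(nrow(cases))) {
    mu <- cases$mu[i]; size <- cases$size[i]; x <- cases$x[i]
    Fx <- sum(dnbinom(0:x, size = size, mu = mu))
    Fx1 <- if (x >= 1) sum(dnbinom(0:(x - 1), size = size, mu = mu)) else 0
    oracle <- min(1, 2 * min(Fx, 1 - Fx1))
    expect_lt(abs(metagrn:::nb_tail_probability(x, mu, size) - oracle), 1e-10)
  }
})

test_that("Poisson limit tail is tiny for an extreme count", {
  # mu = 5, size -> Inf, x = 50: compare to an explicit Poisson sum
  p <- metagrn:::nb_tail_probability(50, 5, Inf)
  oracle <- min(1, 2 * min(sum(dpois(0:50, 5)), 1 - sum(dpois(0:49, 5))))
  expect_equal(p, oracle, tolerance = 1e-12)
  expect_lt(p, 1e-10)
})

test_that("tail probability is monotone above the mode and ~1 at the median", {
  p_seq <- metagrn:::nb_tail_probability(10:60, rep(10, 51), rep(5, 51))
  expect_true(all(diff(p_seq) <= 1e-12))
  med <- qnbinom(0.5, size = 5, mu = 10)
  expect_gt(metagrn:::nb_tail_probability(med, 10, 5), 0.5)
})

test_that("link probabilities equal the brute-force three-smallest geomean", {
  tp <- two_population_counts(genes = 10, cells = 30, n_shift = 4, seed = 6)
  emb <- compute_pca(normalize_counts(tp$counts), 5)
  g <- build_knn(emb, K = 6)
  probs <- link_probabilities(tp$counts, g, cells = c(2, 9))
  for (j in c(2, 9)) {
    model <- fit_local_background(tp$counts, g, j)
    members <- c(j, g$nn[j, ])
    mat <- as.matrix(tp$counts$values[, members])
    lib <- colSums(mat)
    mat <- round(sweep(mat, 2, median(lib[lib > 0]) / lib, "*"))
    for (l in 1:6) {
      pg <- vapply(seq_len(10), function(i) {
        gene_count_probability(model, i, mat[i, l + 1])
      }, numeric(1))
      oracle <- exp(mean(log(sort(pg)[1:3])))
      expect_equal(probs[l, j], oracle, tolerance = 1e-10)
    }
  }
  # all probabilities 1 -> link probability 1 (identical constant columns)
  cm <- count_matrix(matrix(5, 4, 8, dimnames = list(paste0("g", 1:4),
                                                     paste0("c", 1:8))))
  gg <- structure(list(nn = matrix(rep(setdiff(1:8, 1), 8), 8, 7, byrow = TRUE),
                       dist = matrix(0, 8, 7), K = 7L), class = "knn_graph")
  gg$nn <- t(vapply(1:8, function(j) setdiff(1:8, j), integer(7)))
  pr <- link_probabilities(cm, gg, cells = 1)
  expect_true(all(pr[, 1] > 0.999))
})

test_that("pruning applies the threshold and keeps conservation", {
  g <- structure(list(nn = matrix(c(2L, 3L, 1L, 3L, 1L, 2L), 3, 2, byrow = TRUE),
                      dist = matrix(1, 3, 2), K = 2L), class = "knn_graph")
  probs <- structure(matrix(c(0.005, 0.02, 0.5, 0.009, 0.011, 1), 2, 3),
                     class = "link_prob_matrix", evaluated = 1:3)
  pruned <- prune_graph(probs, g, p_tr = 0.01)
  expect_equal(nrow(pruned$edges), sum(probs >= 0.01))
  expect_true(all(pruned$edges$prob >= 0.01))
  # p_tr = 0 keeps every link
  pruned0 <- prune_graph(probs, g, p_tr = 0)
  expect_equal(nrow(pruned0$edges), 6)
  expect_error(prune_graph(probs, g, p_tr = 1.2), "p_tr")
})

test_that("cross-population links get lower probabilities than within-population", {
  tp <- two_population_counts(genes = 120, cells = 100, n_shift = 50, seed = 42)
  emb <- compute_pca(normalize_counts(tp$counts), 10)
  g <- build_knn(emb, K = 10)
  # force mixed neighbourhoods: replace each cell's last 4 neighbours
  # with cells of the other population
  set.seed(42)
  for (j in 1:100) {
    other <- setdiff(which(tp$pop != tp$pop[j]), j)
    g$nn[j, 7:10] <- sample(other, 4)
  }
  probs <- link_probabilities(tp$counts, g, cells = 1:100)
  same <- mapply(function(l, j) tp$pop[g$nn[j, l]] == tp$pop[j],
                 rep(1:10, times = 100), rep(1:100, each = 10))
  p <- as.vector(probs)
  expect_gt(median(p[same]), median(p[!same]))
})
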