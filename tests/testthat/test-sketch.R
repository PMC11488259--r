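test_that("sketching is deterministic and saturates at all cells", {
  tc <- two_cluster_embedding(n = 200, seed = 3)
  s1 <- geometric_sketch(tc$coords, 40, rng_seed = 9)
  s2 <- geometric_sketch(tc$coords, 40, rng_seed = 9)
  expect_identical(s1$seed_indices, s2$seed_indices)
  expect_length(s1$seed_indices, 40)
  expect_false(anyDuplicated(s1$seed_indices) > 0)

  s_all <- geometric_sketch(tc$coords, 200, rng_seed = 1)
  expect_identical(s_all$seed_indices, 1:200)
  expect_warning(geometric_sketch(tc$coords, 300, rng_seed = 1), "exceeds")
})

test_that("geometric sketch over-represents the rare cluster", {
  tc <- two_cluster_embedding(n = 1000, frac_b = 0.05, seed = 5)
  frac_geo <- frac_rand <- numeric(30)
  for (r in 1:30) {
    sg <- geometric_sketch(tc$coords, 100, rng_seed = r)
    sr <- random_sample(1000, 100, rng_seed = r)
    frac_geo[r] <- mean(tc$is_b[sg$seed_indices])
    frac_rand[r] <- mean(tc$is_b[sr$seed_indices])
  }
  expect_gt(mean(frac_geo), mean(frac_rand))
  expect_gt(mean(frac_geo), 0.05)  # above the population fraction
})

test_that("random sampling has near-uniform inclusion probabilities", {
  cells <- 40; S <- 10; reps <- 5000
  inc <- numeric(cells)
  for (r in seq_len(reps)) {
    inc[random_sample(cells, S, rng_seed = r)$seed_indices] <-
      inc[random_sample(cells, S, rng_seed = r)$seed_indices] + 1
  }
  p_hat <- inc / reps
  se <- sqrt((S / cells) * (1 - S / cells) / reps)
  expect_true(all(abs(p_hat - S / cells) < 3 * se + 1e-9))
  expect_identical(random_sample(40, 40, 1)$seed_indices, 1:40)
})

test_that("directed Hausdorff distance matches the brute-force double loop", {
  set.seed(8)
  coords <- matrix(rnorm(30 * 2), 30, 2)
  seeds <- c(3L, 11L, 17L, 22L, 29L)
  h <- hausdorff_distance(coords, seeds)
  d <- as.matrix(dist(coords))[, seeds]
  expect_equal(h, max(apply(d, 1, min)), tolerance = 1e-12)
  # seeds = all cells -> 0
  expect_lt(hausdorff_distance(coords, 1:30), 1e-6)
  # single seed -> max distance from it
  expect_equal(hausdorff_distance(coords, 7L),
               max(as.matrix(dist(coords))[, 7]), tolerance = 1e-12)
  expect_error(hausdorff_distance(coords, integer(0)), "empty")
})

test_that("geometric sketch covers the manifold at least as well as random", {
  tc <- two_cluster_embedding(n = 600, frac_b = 0.05, seed = 12)
  better <- 0
  for (r in 1:30) {
    hg <- hausdorff_distance(tc$coords, geometric_sketch(tc$coords, 60, r))
    hr <- hausdorff_distance(tc$coords, random_sample(600, 60, r))
    if (hg <= hr) better <- better + 1
  }
  expect_gte(better, 24)  # >= 80% of paired repeats
})

test_that("EEV matches per-component least-squares R2 and its limits", {
  cm <- random_counts(genes = 40, cells = 20, lambda = 6, seed = 10)
  norm <- normalize_counts(cm)
  emb <- compute_pca(norm, 12)
  seeds <- c(2L, 5L, 9L, 14L, 19L)
  res <- explained_expression_variance(norm, emb, seeds, K_pcs = 6)
  lam <- emb$eigenvalues[1:6]
  for (i in 1:6) {
    y <- emb$rotation[, i]
    X <- cbind(1, norm[, seeds])
    beta <- solve(crossprod(X), crossprod(X, y))
    r2 <- 1 - sum((y - X %*% beta)^2) / sum((y - mean(y))^2)
    expect_equal(res$r2[i], r2, tolerance = 1e-8)
  }
  expect_equal(res$eev, sum(lam / sum(lam) * res$r2), tolerance = 1e-12)
  expect_equal(sum(res$weights), 1)

  # seeds spanning the full expression column space -> EEV = 1
  res_all <- suppressWarnings(
    explained_expression_variance(norm, emb, 1:20, K_pcs = 6))
  expect_equal(res_all$eev, 1, tolerance = 1e-8)

  # loadings orthogonal to the seed profiles and the intercept -> EEV = 0
  set.seed(1)
  X <- cbind(1, norm[, seeds])
  qrX <- qr(X)
  y0 <- qr.resid(qrX, rnorm(40))  # orthogonal to span(intercept, seeds)
  emb0 <- emb
  emb0$rotation <- matrix(rep(y0, 12), 40)
  res0 <- explained_expression_variance(norm, emb0, seeds, K_pcs = 6)
  expect_equal(res0$eev, 0, tolerance = 1e-8)
})

test_that("seed-number scoring reproduces the worked normalization", {
  sweep <- data.frame(S = c(50, 500, 1000), n_s = c(21, 10, 2))
  res <- optimal_seed_number(sweep)
  expect_equal(res$table$S_star, c(0, 450 / 950, 1), tolerance = 1e-12)
  expect_equal(res$table$n_s_star,
               c(1, (3 - 1) / (sqrt(20) - 1), 0), tolerance = 1e-12)
  expect_equal(res$table$score, res$table$S_star * res$table$n_s_star)
  expect_equal(res$table$score[2], (9 / 19) * 2 / (sqrt(20) - 1),
               tolerance = 1e-12)  # ~ 0.2729
  expect_equal(res$optimal_S, 500)
  # score is 0 at min S and at min n_s by construction
  expect_equal(res$table$score[1], 0)
  expect_equal(res$table$score[3], 0)
})

test_that("argmax of the sweep score agrees with brute force on random sweeps", {
  set.seed(20)
  for (r in 1:100) {
    k <- sample(3:8, 1)
    S <- sort(sample(50:1000, k))
    n_s <- runif(k, 1.01, 30)
    res <- optimal_seed_number(data.frame(S = S, n_s = n_s))
    r_ns <- sqrt(n_s - 1)
    score <- (S - min(S)) / (max(S) - min(S)) *
      (r_ns - min(r_ns)) / (max(r_ns) - min(r_ns))
    best <- S[order(-score, S)[1]]
    expect_equal(res$optimal_S, best)
    expect_equal(res$table$score, score, tolerance = 1e-12)
  }
  expect_error(optimal_seed_number(data.frame(S = c(1, 2), n_s = c(2, 3))),
               "at least 3")
  expect_error(optimal_seed_number(data.frame(S = c(5, 5, 5), n_s = 1:3)),
               "constant S")
})

test_that("a seed-number sweep composes the pipeline stages step by step", {
  sim <- small_sim(n_cells = 120, seed = 5)
  norm <- normalize_counts(sim$counts)
  emb <- compute_pca(norm, 15)
  graph <- build_knn(emb, 8)
  sw <- sweep_seed_numbers(sim$counts, emb, graph, candidates = c(10, 20, 30),
                           rng_seed = 3)
  expect_equal(sw$S, c(10, 20, 30))
  # manual re-run of the middle candidate
  seeds <- geometric_sketch(emb, 20, metagrn:::child_seed(3, 2))
  probs <- link_probabilities(sim$counts, graph, cells = seeds$seed_indices)
  asg <- assign_partners(prune_graph(probs, graph, 0.01), seeds)
  expect_equal(sw$n_s[2], mean(asg$partner_counts))
  expect_error(sweep_seed_numbers(sim$counts, emb, graph, candidates = c(10, 500)),
               "at least 3")
})
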