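test_that("fate matrices validate, renormalize, and lift to metacells", {
  f <- fate_matrix(cbind(CT1 = c(1, 0, 0.5), CT2 = c(0, 1, 0.5)))
  expect_equal(rowSums(f), c(1, 1, 1), ignore_attr = TRUE)
  expect_error(fate_matrix(cbind(a = c(-0.1, 1), b = c(0.5, 0))), "0, 1")

  mc <- structure(list(values = matrix(0, 1, 2),
                       member_lists = list(MC_1 = c(1L, 2L), MC_2 = 3L),
                       seed_cells = c(1L, 3L), min_partners = 0),
                  class = "metacell_matrix")
  lifted <- metacell_fate_probabilities(f, mc)
  expect_equal(unname(lifted["MC_1", ]), c(0.5, 0.5))
  expect_equal(unname(lifted["MC_2", ]), c(0.5, 0.5))
  expect_equal(rowSums(lifted), c(MC_1 = 1, MC_2 = 1))
  # single-member metacell is that cell's row
  f2 <- fate_matrix(cbind(CT1 = c(0.9, 0.2, 0.3), CT2 = c(0.1, 0.8, 0.7)))
  lifted2 <- metacell_fate_probabilities(f2, mc)
  expect_equal(unname(lifted2["MC_2", ]), c(0.3, 0.7))
})

test_that("fate clustering applies the fold-change dominance rules", {
  set.seed(1)
  # two tight clusters around (0.9, 0.1) and (0.1, 0.9)
  p1 <- c(runif(30, 0.85, 0.95), runif(30, 0.05, 0.15))
  f <- fate_matrix(cbind(CT1 = p1, CT2 = 1 - p1))
  asg <- cluster_fates(f, fold_k = 2, rng_seed = 3)
  expect_equal(sort(asg$lineage_members$CT1), 1:30)
  expect_equal(sort(asg$lineage_members$CT2), 31:60)
  expect_length(asg$uncertain, 0)

  # balanced rows are uncertain and enter both lineages
  pm <- c(runif(30, 0.85, 0.95), runif(30, 0.05, 0.15), runif(20, 0.47, 0.53))
  fm <- fate_matrix(cbind(CT1 = pm, CT2 = 1 - pm))
  asg2 <- cluster_fates(fm, fold_k = 2, rng_seed = 3)
  expect_true(all(61:80 %in% asg2$uncertain))
  expect_true(all(61:80 %in% asg2$lineage_members$CT1))
  expect_true(all(61:80 %in% asg2$lineage_members$CT2))
  expect_false(any(1:30 %in% asg2$lineage_members$CT2))
})

test_that("a cluster biased to a strict fate subset joins each subset fate", {
  set.seed(2)
  jitter <- function(n, c1, c2, c3) {
    cbind(f1 = rnorm(n, c1, 0.01), f2 = rnorm(n, c2, 0.01),
          f3 = rnorm(n, c3, 0.01))
  }
  X <- rbind(jitter(25, 0.45, 0.45, 0.10),
             jitter(25, 0.80, 0.10, 0.10),
             jitter(25, 0.10, 0.10, 0.80))
  X[X < 0] <- 0.001
  f <- fate_matrix(X)
  asg <- cluster_fates(f, fold_k = 2, max_components = 6, rng_seed = 5)
  # 0.45 >= 2 x 0.10 but not >= 2 x 0.45: cluster joins fates 1 and 2 only
  expect_true(all(1:25 %in% asg$lineage_members$f1))
  expect_true(all(1:25 %in% asg$lineage_members$f2))
  expect_false(any(1:25 %in% asg$lineage_members$f3))
  expect_true(all(26:50 %in% asg$lineage_members$f1))
  expect_true(all(51:75 %in% asg$lineage_members$f3))
})

test_that("lineage ordering sorts by fate probability with index ties", {
  mc_expr <- matrix(seq_len(12), 2, 6,
                    dimnames = list(c("gA", "gB"), paste0("MC_", 1:6)))
  fates <- fate_matrix(cbind(CT1 = c(0.2, 0.9, 0.5, 0.5, 0.1, 0.95),
                             CT2 = c(0.8, 0.1, 0.5, 0.5, 0.9, 0.05)))
  asg <- structure(list(lineage_members = list(CT1 = c(1L, 2L, 3L, 4L, 6L)),
                        uncertain = integer(0)),
                   class = "lineage_assignment")
  ser <- order_lineage_metacells(mc_expr, fates, asg, "CT1")
  expect_equal(ser$metacell_ids, c(1L, 3L, 4L, 2L, 6L))  # tie 3 before 4
  expect_equal(ncol(ser$expr), 5)
  expect_equal(ser$expr[, 1], mc_expr[, 1])
  expect_error(order_lineage_metacells(mc_expr, fates, asg, "CTX"), "unknown")
})

test_that("ridge Granger matches the closed-form oracle on random fixtures", {
  set.seed(9)
  for (r in 1:20) {
    P <- sample(1:5, 1); L <- sample(1:10, 1); T_len <- 100
    lambda <- runif(1, 1, 300)
    mat <- matrix(rnorm((P + 1) * T_len), P + 1, T_len,
                  dimnames = list(c(paste0("r", seq_len(P)), "y"), NULL))
    ser <- as_series(mat)
    fit <- fit_granger(ser, paste0("r", seq_len(P)), "y", L = L,
                       lambda_reg = lambda, standardize = FALSE)
    # independent design construction + closed-form solve
    rows <- (L + 1):T_len
    X <- NULL
    for (j in seq_len(P)) for (l in seq_len(L)) {
      X <- cbind(X, mat[j, rows - l])
    }
    y <- mat["y", rows]
    Xc <- scale(X, center = TRUE, scale = FALSE)
    yc <- y - mean(y)
    a <- solve(crossprod(Xc) + lambda * diag(ncol(Xc)), crossprod(Xc, yc))
    expect_equal(as.vector(t(fit$coef)), as.vector(a), tolerance = 1e-8)
  }
})

test_that("Granger limits: exact recovery at lambda 0, collapse at huge lambda", {
  set.seed(3)
  x <- rnorm(80)
  y <- c(0, 0.8 * x[-80])
  mat <- rbind(r1 = x, y = y)
  ser <- as_series(mat)
  fit0 <- fit_granger(ser, "r1", "y", L = 1, lambda_reg = 0,
                      standardize = FALSE)
  expect_equal(unname(fit0$coef[1, 1]), 0.8, tolerance = 1e-8)

  fit_inf <- fit_granger(ser, "r1", "y", L = 1, lambda_reg = 1e9,
                         standardize = FALSE)
  expect_lt(max(abs(fit_inf$coef)), 1e-4)
})

test_that("lag reduction guards short lineages", {
  mat <- matrix(rnorm(2 * 20), 2, 20, dimnames = list(c("r1", "y"), NULL))
  ser <- as_series(mat)
  fit <- fit_granger(ser, "r1", "y", L = 30, lambda_reg = 1)
  expect_equal(fit$L, max(1, floor((20 - 1) / 3)))
  tiny <- as_series(mat[, 1:4, drop = FALSE])
  expect_error(fit_granger(tiny, "r1", "y", L = 30, lambda_reg = 1), "short")
})

test_that("edge weights sum lags inside the absolute value", {
  co <- structure(list(coef = matrix(c(0.5, -0.2, 0.1), 1, 3,
                                     dimnames = list("r1", NULL))),
                  class = "granger_coeffs")
  expect_equal(unname(granger_edge_weights(co)), 0.4)
  co$coef <- matrix(c(0.5, -0.5), 1, 2, dimnames = list("r1", NULL))
  expect_equal(unname(granger_edge_weights(co)), 0)  # cancellation
  co$coef <- matrix(0, 1, 5, dimnames = list("r1", NULL))
  expect_equal(unname(granger_edge_weights(co)), 0)
})

test_that("rank transform yields exactly 1/i^2 per ranked target", {
  G <- rbind(a = c(0.9, 0.5, 0.2, 0), b = c(0, 0, 0, 0),
             c = c(0.5, 0.5, 0, 0.1))
  colnames(G) <- paste0("t", 1:4)
  Gt <- rank_transform(G)
  expect_equal(unname(Gt["a", ]), c(1, 0.25, 1 / 9, 0))
  expect_equal(unname(Gt["b", ]), rep(0, 4))
  # tie at 0.5 resolved toward the lower target index
  expect_equal(unname(Gt["c", ]), c(1, 0.25, 0, 1 / 9))
  # every nonzero row is exactly {1/i^2 : i = 1..degree}
  for (r in seq_len(nrow(Gt))) {
    nz <- sort(Gt[r, Gt[r, ] > 0], decreasing = TRUE)
    expect_equal(unname(nz), 1 / seq_along(nz)^2)
  }
  expect_error(rank_transform(matrix(-1, 1, 1)), "non-negative")
})

test_that("Markov fate fallback solves the gambler's-ruin chain", {
  # 5-node chain with unit-weight links, terminals at both ends
  edges <- data.frame(seed = c(1L, 2L, 3L, 4L), neighbor = c(2L, 3L, 4L, 5L),
                      prob = 1)
  pruned <- structure(list(edges = edges, p_tr = 0.01, n_cells = 5,
                           seeds = 1:5), class = "pruned_knn")
  f <- markov_fate_probabilities(pruned, list(left = 1L, right = 5L))
  expect_equal(unname(f[, "left"]), c(1, 0.75, 0.5, 0.25, 0), tolerance = 1e-10)
  expect_equal(rowSums(f), rep(1, 5), ignore_attr = TRUE)
  expect_error(markov_fate_probabilities(pruned, list(a = 1L, b = 1L)),
               "disjoint")
})

test_that("lineage GRN assembly fills G only for skeleton edges", {
  set.seed(11)
  mat <- matrix(rnorm(4 * 60), 4, 60,
                dimnames = list(c("r1", "r2", "t1", "t2"), NULL))
  mat["t1", ] <- c(0, 0.9 * mat["r1", -60]) + rnorm(60, 0, 0.05)
  adj <- matrix(FALSE, 2, 4, dimnames = list(c("r1", "r2"),
                                             c("r1", "r2", "t1", "t2")))
  adj["r1", "t1"] <- TRUE; adj["r2", "t1"] <- TRUE; adj["r1", "t2"] <- TRUE
  sk <- structure(list(adj = adj, provenance = "genie3",
                       weight_threshold = 0.001, top_n = 50),
                  class = "skeleton_network")
  lg <- infer_lineage_grn(as_series(mat), sk, L = 2, lambda_reg = 1)
  expect_true(lg$G["r1", "t1"] > 0)
  expect_equal(unname(lg$G["r2", "r1"]), 0)  # not a skeleton edge
  expect_true(all(lg$G[!adj] == 0))
  expect_true(all(lg$G_tilde[lg$G == 0] == 0))
})
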