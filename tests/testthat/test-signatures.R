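test_that("cosine similarity matches the closed form and is scale-invariant", {
  a <- c(1, 2, 2); b <- c(2, 1, 2)
  expect_equal(cos_sim(a, b), 8 / 9)
  expect_equal(cos_sim(a, a), 1)
  expect_equal(cos_sim(c(1, 0), c(0, 2)), 0)
  for (c_ in c(0.1, 3, 1000)) expect_equal(cos_sim(a, c_ * a), 1)
  expect_equal(cos_sim(a, b), cos_sim(b, a))
  expect_error(cos_sim(c(0, 0), a[1:2]), "all-zero")
  expect_error(cos_sim(a, b[1:2]), "length")
})

test_that("pairwise similarity matrices agree with elementwise cos_sim", {
  set.seed(5)
  A <- random_stochastic_matrix(96, 2)
  B <- random_stochastic_matrix(96, 2)
  rownames(A) <- rownames(B) <- channel_labels()
  cs <- cos_sim_matrix(A, B)
  for (i in 1:2) for (j in 1:2) {
    expect_equal(cs[i, j], cos_sim(A[, i], B[, j]))
  }
  expect_equal(unname(diag(cos_sim_matrix(A, A))), c(1, 1))
  perm <- cos_sim_matrix(A, B[, 2:1])
  expect_equal(unname(perm), unname(cs[, 2:1]))
  rownames(B) <- rev(rownames(B))
  expect_error(cos_sim_matrix(A, B), "channel order")
})

test_that("NNLS recovers exact mixtures and rejects orthogonal targets", {
  # orthogonal unit columns
  S <- diag(2)
  f <- nnls_fit(S, 0.3 * S[, 1] + 0.7 * S[, 2])
  expect_equal(unname(f$x), c(0.3, 0.7), tolerance = 1e-12)

  f2 <- nnls_fit(matrix(c(1, 0), 2, 1), c(0, 1))
  expect_equal(unname(f2$x), 0)
  expect_equal(sqrt(f2$rss), 1)

  set.seed(42)
  S <- random_stochastic_matrix(96, 5)
  x_true <- c(120, 0, 55, 310, 0)
  f3 <- nnls_fit(S, as.numeric(S %*% x_true))
  expect_lt(max(abs(f3$x - x_true)), 1e-6)

  expect_error(nnls_fit(S, rep(1, 95)), "shape")
  expect_error(nnls_fit(-S, rep(1, 96)), "negative")
})

test_that("NNLS satisfies KKT conditions and matches the simplex-grid oracle", {
  set.seed(7)
  for (i in 1:50) {
    k <- sample(2:3, 1)
    S <- random_stochastic_matrix(96, k)
    total <- runif(1, 50, 500)
    x_true <- as.numeric(rmultinom(1, 1000, rep(1, k))) / 1000 * total
    d <- as.numeric(S %*% x_true)
    f <- nnls_fit(S, d)
    # KKT: zero gradient on support, non-negative elsewhere
    tol <- 1e-8 * sqrt(sum(d^2))
    expect_lt(max(abs(f$gradient[f$x > 0])), tol)
    if (any(f$x == 0)) expect_gt(min(f$gradient[f$x == 0]), -tol)
    # grid oracle at step 1e-3 on the scaled simplex
    x_grid <- grid_nnls_oracle(S, d, total = total, step = 1e-3)
    expect_lt(max(abs(f$x - x_grid)), 2e-3 * total)
    expect_lte(nnls_objective(S, f$x, d), nnls_objective(S, x_grid, d) + 1e-9)
  }
})

test_that("NNLS agrees with an independent active-set implementation on noisy data", {
  skip_if_not_installed("pracma")
  set.seed(8)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    S <- random_stochastic_matrix(96, k)
    d <- as.numeric(S %*% (runif(k) * 100)) + abs(rnorm(96, 0, 0.5))
    ours <- nnls_fit(S, d)
    ref <- pracma::lsqnonneg(S, d)
    expect_equal(unname(ours$x), unname(ref$x), tolerance = 1e-6)
  }
})

test_that("refitting reconstructs exact mixtures and is per-sample independent", {
  set.seed(9)
  S <- random_stochastic_matrix(96, 4)
  rownames(S) <- channel_labels(); colnames(S) <- paste0("sig", 1:4)
  X <- matrix(c(100, 0, 40, 0,
                0, 250, 0, 10,
                30, 30, 30, 30), 4, 3)
  M <- S %*% X
  rownames(M) <- channel_labels(); colnames(M) <- paste0("s", 1:3)
  fit <- fit_to_signatures(M, S)
  expect_equal(unname(fit$contribution), unname(X), tolerance = 1e-6)
  expect_true(all(abs(fit$diagnostics$cosine - 1) < 1e-9))
  expect_true(all(fit$diagnostics$rss < 1e-9))
  expect_false(any(fit$diagnostics$flagged))

  # single signature scaled by 500
  M1 <- S[, 2, drop = FALSE] * 500
  colnames(M1) <- "solo"
  fit1 <- fit_to_signatures(M1, S)
  expect_equal(fit1$contribution["sig2", "solo"], 500, tolerance = 1e-6)
  expect_lt(max(fit1$contribution[-2, "solo"]), 1e-6)

  # fitting a sample alone equals fitting it within a cohort
  fit_alone <- fit_to_signatures(M[, 2, drop = FALSE], S)
  expect_equal(fit_alone$contribution[, 1], fit$contribution[, 2])

  # absolute contributions of an exactly reconstructable sample sum to its
  # mutation count (signature columns sum to 1)
  expect_equal(unname(colSums(fit$contribution)), unname(colSums(M)),
               tolerance = 1e-6)
})

test_that("refitting recovers generating weights from multinomial counts", {
  sigs <- make_signature_set(4, seed = 33)
  set.seed(10)
  W <- random_stochastic_matrix(4, 8)
  M <- simulate_mut_matrix(sigs, W, 5000, seed = 12)
  fit <- fit_to_signatures(M, sigs)
  rel <- sweep(fit$contribution, 2, colSums(fit$contribution), "/")
  expect_gt(cor(as.vector(rel), as.vector(W)), 0.95)
})

test_that("NMF recovers a rank-1 factorisation and is deterministic under seed", {
  set.seed(13)
  w <- rgamma(96, 2) + 0.1
  h <- rgamma(12, 2) + 0.1
  M <- outer(w, h)
  res <- extract_signatures(M, rank = 1, nrun = 2, seed = 3)
  recon <- res$signatures %*% res$contribution
  expect_lt(sum((M - recon)^2) / sum(M^2), 1e-6)
  expect_gt(cos_sim(res$signatures[, 1], w), 0.999)

  res2 <- extract_signatures(M, rank = 1, nrun = 2, seed = 3)
  expect_identical(res, res2)

  expect_error(extract_signatures(M, rank = 20), "rank")
  M0 <- M; M0[, 1] <- 0
  expect_error(extract_signatures(M0, rank = 1), "all-zero")
})

test_that("NMF objective is monotone non-increasing for both objectives", {
  set.seed(14)
  M <- matrix(rpois(96 * 10, 4) + 0.0, 96, 10)
  M[M == 0] <- 0  # counts may contain zeros; updates must stay finite
  for (obj in c("kl", "frobenius")) {
    run <- somaticsigs:::nmf_run(M, rank = 3, seed = 5, objective = obj,
                                 max_iter = 300, rel_tol = 0)
    tr <- run$trace
    expect_true(all(diff(tr) <= 1e-8 * abs(tr[1])))
  }
})

test_that("NMF signature columns sum to 1 and the product is preserved", {
  set.seed(15)
  M <- matrix(rpois(96 * 10, 6), 96, 10)
  res <- extract_signatures(M, rank = 2, nrun = 3, seed = 8)
  expect_equal(unname(colSums(res$signatures)), c(1, 1), tolerance = 1e-12)
  # restart bookkeeping: best run has the lowest objective
  expect_equal(res$objective, min(res$run_objectives))
})

test_that("rank survey summarises ranks in order with an elbow at the true rank", {
  sigs <- make_signature_set(3, seed = 7)
  set.seed(16)
  W <- random_stochastic_matrix(3, 20)
  M <- simulate_mut_matrix(sigs, W, 2000, seed = 17)
  sv <- rank_survey(M, ranks = c(2, 3, 4), nrun = 3, seed = 6)
  expect_equal(sv$rank, c(2, 3, 4))
  rc <- sv$mean_reconstruction_cosine
  # reconstruction improves sharply up to the true rank, marginally after
  expect_gt(rc[2] - rc[1], rc[3] - rc[2])
  expect_error(rank_survey(M, ranks = 1), ">= 2")
})

test_that("sample clustering uses average-linkage Euclidean distance deterministically", {
  X <- rbind(a = c(0, 0), b = c(0, 0), c = c(10, 10))
  cl <- cluster_samples(X)
  # identical rows merge first at height 0
  expect_equal(cl$hclust$height[1], 0)
  expect_equal(sort(-cl$hclust$merge[1, ]), match(c("a", "b"), rownames(X)))
  # the outlier merges last: hand-computed average-linkage height
  expect_equal(cl$hclust$height[2], sqrt(200))
  expect_match(cl$newick, "^\\(")

  # permuting rows preserves topology (same merge heights, same partition)
  X2 <- X[c(3, 1, 2), ]
  cl2 <- cluster_samples(X2)
  expect_equal(cl2$hclust$height, cl$hclust$height)
  ct1 <- cutree(cl$hclust, 2); ct2 <- cutree(cl2$hclust, 2)
  for (ct in list(ct1, ct2)) {
    expect_equal(ct[["a"]], ct[["b"]])
    expect_false(ct[["a"]] == ct[["c"]])
  }
  expect_error(cluster_samples(X[1, , drop = FALSE]), "2 samples")
})
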