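#' Cosine similarity between two mutation profiles
#'
#' `cos_sim(a, b) = sum(a*b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))`. The measure
#' is scale-invariant, so profiles need not be normalised for total mutation
#' load; for non-negative profiles it lies in \[0, 1\], with 1 for identical
#' direction and 0 for disjoint (independent) profiles.
#'
#' @param a,b Non-negative numeric vectors of equal length, each with at
#'   least one nonzero entry.
#' @return The similarity, a number in \[0, 1\].
#' @export
#' @examples
#' cos_sim(c(1, 2, 2), c(2, 1, 2))  # 8/9
cos_sim <- function(a, b) {
  if (length(a) != length(b)) stop("profiles must have equal length")
  if (any(a < 0) || any(b < 0)) stop("profiles must be non-negative")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("all-zero profile")
  min(1, sum(a * b) / (na * nb))
}

#' Pairwise cosine similarity between the columns of two matrices
#'
#' @param A,B Channel x profile matrices over the same channels in the same
#'   order (checked via row names when both are labelled).
#' @return `ncol(A)` x `ncol(B)` matrix; entry (i, j) is
#'   `cos_sim(A[, i], B[, j])`.
#' @export
cos_sim_matrix <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B)) stop("channel dimension mismatch")
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B))) {
    stop("channel order mismatch between A and B")
  }
  num <- crossprod(A, B)
  den <- outer(sqrt(colSums(A^2)), sqrt(colSums(B^2)))
  if (any(den == 0)) stop("all-zero profile column")
  out <- pmin(num / den, 1)
  dimnames(out) <- list(colnames(A), colnames(B))
  out
}

#' Non-negative least squares by the Lawson-Hanson active-set method
#'
#' Solves `min_x || S x - d ||_2^2 subject to x >= 0`. At the solution the
#' Karush-Kuhn-Tucker conditions hold: the gradient `g = t(S) (S x - d)` is
#' zero on the active (positive) coordinates and non-negative elsewhere.
#'
#' The active-set iteration moves one variable at a time into the passive set
#' (the one with the most negative gradient), solving an unconstrained least
#' squares on the passive set and backtracking along the line segment towards
#' feasibility whenever the unconstrained solution leaves the cone.
#'
#' @param S Numeric matrix (channels x signatures), e.g. a column-stochastic
#'   signature matrix.
#' @param d Non-negative vector of observed counts or frequencies,
#'   `length(d) == nrow(S)`.
#' @param tol Gradient tolerance for entering the passive set; defaults to a
#'   small multiple of `||t(S) d||_inf`.
#' @return Named list: `x` (the weights), `residual` (`d - S x`), `rss`
#'   and `gradient`.
#' @export
nnls_fit <- function(S, d, tol = NULL) {
  S <- as.matrix(S)
  d <- as.numeric(d)
  if (nrow(S) != length(d)) stop("shape mismatch: nrow(S) != length(d)")
  if (any(S < 0) || any(d < 0)) stop("negative input")
  k <- ncol(S)
  if (is.null(tol)) tol <- 1e-10 * max(1, max(abs(crossprod(S, d))))
  x <- numeric(k)
  passive <- rep(FALSE, k)
  g <- as.numeric(crossprod(S, d))          # gradient of -0.5*rss at x = 0
  iter <- 0L; max_iter <- 30L * max(k, 3L)
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- as.numeric(crossprod(S, d - S %*% x))
    cand <- which(!passive & w > tol)
    if (!length(cand)) break
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      P <- which(passive)
      z <- numeric(k)
      fit <- stats::lm.fit(S[, P, drop = FALSE], d)
      z[P] <- fit$coefficients
      z[P][is.na(z[P])] <- 0       # rank-deficient passive set
      if (all(z[P] > 0)) { x <- z; break }
      neg <- P[z[P] <= 0]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      x[x < .Machine$double.eps * max(x)] <- 0
      passive[P[x[P] <= 0]] <- FALSE
      x[!passive] <- 0
    }
  }
  res <- d - as.numeric(S %*% x)
  grad <- as.numeric(crossprod(S, -res))
  names(x) <- colnames(S)
  list(x = x, residual = res, rss = sum(res^2), gradient = grad)
}

#' Refit a mutation matrix against known signatures
#'
#' Finds, for every sample independently, the non-negative linear combination
#' of the provided signatures that best reconstructs its 96-channel profile
#' (per-sample [nnls_fit()]). With column-stochastic signatures the fitted
#' weights are on the mutation-count scale ("absolute" contributions).
#' Reconstruction quality is reported per sample as the cosine similarity
#' between the original and reconstructed profile and the RSS between their
#' sum-1 normalised versions; samples below `cosine_threshold` are flagged as
#' incompletely explained by the provided signatures.
#'
#' @param M Channel x sample count matrix (96 or 192 channels).
#' @param S Channel x signature matrix over the same channels.
#' @param cosine_threshold Flagging threshold for reconstruction cosine
#'   similarity (default 0.95).
#' @return List with `contribution` (K x S weights), `reconstructed`
#'   (channel x sample) and `diagnostics` (data.frame: `sample`, `cosine`,
#'   `rss`, `flagged`).
#' @export
fit_to_signatures <- function(M, S, cosine_threshold = 0.95) {
  M <- as.matrix(M); S <- as.matrix(S)
  if (nrow(M) != nrow(S)) stop("channel dimension mismatch")
  if (!is.null(rownames(M)) && !is.null(rownames(S)) &&
      !identical(rownames(M), rownames(S))) {
    stop("channel order mismatch between matrix and signatures")
  }
  ns <- ncol(M)
  contrib <- matrix(0, ncol(S), ns, dimnames = list(colnames(S), colnames(M)))
  recon <- matrix(0, nrow(M), ns, dimnames = dimnames(M))
  cosv <- numeric(ns); rssv <- numeric(ns)
  for (j in seq_len(ns)) {
    f <- nnls_fit(S, M[, j])
    contrib[, j] <- f$x
    r <- as.numeric(S %*% f$x)
    recon[, j] <- r
    if (sum(M[, j]) == 0 || sum(r) == 0) {
      cosv[j] <- NA_real_; rssv[j] <- NA_real_
    } else {
      cosv[j] <- cos_sim(M[, j], r)
      rssv[j] <- sum((M[, j] / sum(M[, j]) - r / sum(r))^2)
    }
  }
  diagnostics <- data.frame(
    sample = colnames(M) %||% as.character(seq_len(ns)),
    cosine = cosv, rss = rssv,
    flagged = !is.na(cosv) & cosv < cosine_threshold,
    stringsAsFactors = FALSE
  )
  list(contribution = contrib, reconstructed = recon, diagnostics = diagnostics)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one NMF run with multiplicative updates; returns W, H, objective trace
nmf_run <- function(V, rank, seed, objective, max_iter, rel_tol, eps = 1e-12) {
  n <- nrow(V); m <- ncol(V)
  with_seed(seed, {
    W <- matrix(runif(n * rank, 0.1, 1), n, rank)
    H <- matrix(runif(rank * m, 0.1, 1), rank, m)
  })
  obj <- function(WH) {
    if (objective == "kl") {
      sum(ifelse(V > 0, V * log(V / pmax(WH, eps)), 0) - V + WH)
    } else {
      0.5 * sum((V - WH)^2)
    }
  }
  WH <- W %*% H
  trace <- numeric(0)
  prev <- obj(WH)
  trace <- prev
  for (it in seq_len(max_iter)) {
    if (objective == "kl") {
      Q <- V / pmax(WH, eps)
      H <- H * (crossprod(W, Q) / pmax(colSums(W), eps))
      WH <- W %*% H
      Q <- V / pmax(WH, eps)
      W <- W * (tcrossprod(Q, H) / rep(pmax(rowSums(H), eps), each = n))
      WH <- W %*% H
    } else {
      H <- H * (crossprod(W, V) / pmax(crossprod(W, WH), eps))
      WH <- W %*% H
      W <- W * (tcrossprod(V, H) / pmax(tcrossprod(WH, H), eps))
      WH <- W %*% H
    }
    cur <- obj(WH)
    trace <- c(trace, cur)
    if (abs(prev - cur) <= rel_tol * max(abs(prev), eps)) break
    prev <- cur
  }
  list(W = W, H = H, objective = cur, trace = trace, iterations = it)
}

#' De novo signature extraction by non-negative matrix factorization
#'
#' Factorises the channel x sample count matrix `M ~ W H` with non-negative
#' factors, using multiplicative updates under the generalised
#' Kullback-Leibler divergence (the natural objective for count data;
#' Frobenius available via `objective = "frobenius"`). `nrun` random restarts
#' are seeded deterministically as `seed + run`, and the run with the lowest
#' final objective is kept (ties broken by lowest run index). The returned
#' signature columns are normalised to sum 1 with contributions rescaled so
#' the product `W H` is unchanged.
#'
#' @param M Non-negative channel x sample matrix (no all-zero columns).
#' @param rank Number of signatures to extract; must be `< min(dim(M))`.
#' @param nrun Number of random restarts (default 10).
#' @param seed Base RNG seed.
#' @param objective `"kl"` (default) or `"frobenius"`.
#' @param max_iter,rel_tol Convergence controls: stop when the relative
#'   objective change drops below `rel_tol` (default 1e-8) or after
#'   `max_iter` iterations (default 5000).
#' @return An object of class `nmf_result`: list with `signatures` (channel x
#'   rank, columns sum to 1), `contribution` (rank x sample), `objective`
#'   (best run's final objective), `run_objectives`, `best_run`, `seed` and
#'   `trace` (objective per iteration of the best run).
#' @export
extract_signatures <- function(M, rank, nrun = 10, seed = 1,
                               objective = c("kl", "frobenius"),
                               max_iter = 5000, rel_tol = 1e-8) {
  objective <- match.arg(objective)
  M <- as.matrix(M)
  if (any(M < 0)) stop("negative entry in mutation matrix")
  if (any(colSums(M) == 0)) stop("all-zero sample column in mutation matrix")
  if (rank >= min(dim(M))) stop("rank must be smaller than both matrix dimensions")
  if (nrun < 1) stop("nrun must be >= 1")
  runs <- vector("list", nrun)
  for (r in seq_len(nrun)) {
    runs[[r]] <- nmf_run(M, rank, seed + r, objective, max_iter, rel_tol)
  }
  objs <- vapply(runs, `[[`, 0, "objective")
  best <- which.min(objs)            # which.min takes the first on ties
  W <- runs[[best]]$W; H <- runs[[best]]$H
  cs <- colSums(W)
  W <- sweep(W, 2, cs, "/")
  H <- sweep(H, 1, cs, "*")
  sig_names <- paste0("Signature_", LETTERS[seq_len(rank)])
  dimnames(W) <- list(rownames(M), sig_names)
  dimnames(H) <- list(sig_names, colnames(M))
  structure(list(signatures = W, contribution = H, objective = objs[best],
                 run_objectives = objs, best_run = best, seed = seed,
                 trace = runs[[best]]$trace,
                 iterations = runs[[best]]$iterations,
                 objective_type = objective),
            class = "nmf_result")
}

#' @export
print.nmf_result <- function(x, ...) {
  cat(sprintf("<nmf_result> %d signatures x %d samples; %s objective %.6g (best of %d runs)\n",
              ncol(x$signatures), ncol(x$contribution), x$objective_type,
              x$objective, length(x$run_objectives)))
  invisible(x)
}

# best one-to-one matching of columns of A to columns of B maximising total
# cosine; exact over permutations for small k, greedy otherwise
match_signatures <- function(A, B) {
  k <- ncol(A)
  stopifnot(ncol(B) == k)
  cs <- cos_sim_matrix(A, B)
  if (k <= 7) {
    perms <- permutations_of(k)
    scores <- vapply(perms, function(p) sum(cs[cbind(seq_len(k), p)]), 0)
    p <- perms[[which.max(scores)]]
  } else {
    p <- integer(k); taken <- rep(FALSE, k)
    ord <- order(apply(cs, 1, max), decreasing = TRUE)
    for (i in ord) {
      j <- which.max(ifelse(taken, -Inf, cs[i, ]))
      p[i] <- j; taken[j] <- TRUE
    }
  }
  list(assignment = p, cosines = cs[cbind(seq_len(k), p)])
}

permutations_of <- function(k) {
  if (k == 1) return(list(1L))
  sub <- permutations_of(k - 1L)
  out <- list()
  for (p in sub) for (i in seq_len(k)) {
    out[[length(out) + 1L]] <- append(p, k, after = i - 1L)
  }
  out
}

#' Survey candidate factorization ranks
#'
#' Runs [extract_signatures()] for each candidate rank and summarises the
#' best objective, the mean reconstruction cosine over samples, and signature
#' stability (the mean cosine between each restart's signatures and the best
#' run's signatures under optimal one-to-one matching). The preferred rank is
#' usually where reconstruction stops improving sharply while stability
#' remains high.
#'
#' @inheritParams extract_signatures
#' @param ranks Integer vector of ranks to try (each >= 2).
#' @return data.frame with one row per rank: `rank`, `objective`,
#'   `mean_reconstruction_cosine`, `stability`.
#' @export
rank_survey <- function(M, ranks, nrun = 10, seed = 1,
                        objective = c("kl", "frobenius")) {
  objective <- match.arg(objective)
  if (any(ranks < 2)) stop("ranks must be >= 2")
  out <- lapply(ranks, function(rk) {
    res <- extract_signatures(M, rk, nrun = nrun, seed = seed, objective = objective)
    recon <- res$signatures %*% res$contribution
    mc <- mean(vapply(seq_len(ncol(M)), function(j) cos_sim(M[, j], recon[, j]), 0))
    # stability: rerun each restart and match to the kept factorisation
    stab <- mean(vapply(seq_along(res$run_objectives), function(r) {
      run <- nmf_run(as.matrix(M), rk, seed + r, objective, 5000, 1e-8)
      W <- sweep(run$W, 2, colSums(run$W), "/")
      mean(match_signatures(W, res$signatures)$cosines)
    }, 0))
    data.frame(rank = rk, objective = res$objective,
               mean_reconstruction_cosine = mc, stability = stab)
  })
  do.call(rbind, out)
}

#' Hierarchically cluster samples on their similarity profiles
#'
#' Average-linkage agglomerative clustering of the rows (samples) using
#' Euclidean distance between their similarity (or contribution) vectors —
#' the standard way to group samples by mutational-process activity.
#' `stats::hclust` is deterministic for a given input; ties in merge height
#' are resolved by its fixed scan order, so the leaf order is reproducible.
#'
#' @param X Samples x signatures numeric matrix (e.g. a cosine-similarity
#'   matrix from [cos_sim_matrix()] with samples as rows).
#' @return List with `hclust` (the tree), `order` (leaf order indices),
#'   `labels` (leaf labels in dendrogram order) and `newick` (Newick string).
#' @export
cluster_samples <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 samples to cluster")
  if (is.null(rownames(X))) rownames(X) <- paste0("sample", seq_len(nrow(X)))
  hc <- hclust(dist(X, method = "euclidean"), method = "average")
  phy <- ape::as.phylo(hc)
  list(hclust = hc, order = hc$order, labels = hc$labels[hc$order],
       newick = ape::write.tree(phy))
}
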