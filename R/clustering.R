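#' PCA of a genotype matrix
#'
#' Missing dosages are mean-imputed per locus, the matrix is centered
#' (and optionally scaled), and the top principal components are
#' extracted with [stats::prcomp()].
#'
#' @param g A [genotype_matrix].
#' @param n_components Number of components to return; must not exceed
#'   the available dimensions.
#' @param scale. Scale loci to unit variance; default `FALSE`.
#' @return Object of class `pca_result`: list with `scores` (samples x
#'   components), `explained` (variance fractions, non-increasing),
#'   `rotation`, and `zero_variance` (`TRUE` when the matrix carries no
#'   variance at all, in which case scores are all zero).
#' @export
pca_genotypes <- function(g, n_components = 10, scale. = FALSE) {
  g <- as_gm(g)
  x <- impute_mean(g$calls)
  max_comp <- min(nrow(x) - 1, ncol(x))
  if (n_components > max_comp) {
    stop("n_components (", n_components, ") exceeds available dimensions (",
         max_comp, ")")
  }
  v <- apply(x, 2, stats::var)
  if (all(v == 0)) {
    warning("all genotypes identical: zero variance, PCA degenerate")
    scores <- matrix(0, nrow(x), n_components,
                     dimnames = list(g$samples, paste0("PC", seq_len(n_components))))
    return(structure(list(scores = scores,
                          explained = rep(0, n_components),
                          rotation = NULL, zero_variance = TRUE),
                     class = "pca_result"))
  }
  if (scale.) x[, v == 0] <- x[, v == 0]  # constant loci stay unscaled
  pc <- stats::prcomp(x, center = TRUE, scale. = if (scale.) v > 0 else FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  k <- seq_len(n_components)
  structure(list(scores = pc$x[, k, drop = FALSE],
                 explained = expl[k],
                 rotation = pc$rotation[, k, drop = FALSE],
                 zero_variance = FALSE),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "samples,",
      ncol(x$scores), "components;",
      "explained:", paste(sprintf("%.1f%%", 100 * x$explained), collapse = " "),
      "\n")
  invisible(x)
}

impute_mean <- function(x) {
  x <- matrix(as.numeric(x), nrow(x), ncol(x), dimnames = dimnames(x))
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(x))
    x[idx] <- mu[(idx - 1) %/% nrow(x) + 1]
  }
  x
}

#' Least-squares admixture estimator
#'
#' Alternating minimization of the squared reconstruction error between
#' the observed allele-dosage fractions (dosage / 2) and `Q %*% F`, where
#' `Q` (samples x K) holds per-individual membership proportions
#' constrained to the probability simplex and `F` (K x loci) holds
#' per-cluster allele frequencies constrained to [0, 1]. Missing calls
#' are masked out of the objective (not imputed). The Q-step solves each
#' row's simplex-constrained least-squares problem exactly (active-set);
#' the F-step runs exact coordinate descent under box constraints, so the
#' objective is non-increasing across iterations. Initialization is
#' K-means on PCA scores with k-means++ seeding; the whole fit is
#' deterministic given `seed`.
#'
#' This estimator is a deliberately simple, non-spatial stand-in for
#' Bayesian admixture machinery: the downstream pipeline needs membership
#' proportions and a cluster count, not posterior samples.
#'
#' @param g A [genotype_matrix].
#' @param K Number of clusters (>= 1, <= number of samples).
#' @param seed Integer seed.
#' @param max_iter Maximum alternating iterations; default 100.
#' @param tol Relative objective-change convergence tolerance; default 1e-6.
#' @return Object of class `admixture_model`: list with `Q`, `F`,
#'   `objective` (final masked mean squared error), `objective_trace`,
#'   `K`, `seed`, `converged`, `iterations`.
#' @export
estimate_admixture <- function(g, K, seed = 1L, max_iter = 100, tol = 1e-6) {
  g <- as_gm(g)
  x <- g$calls
  n <- nrow(x)
  L <- ncol(x)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K (", K, ") exceeds the number of samples (", n, ")")
  m <- !is.na(x)
  y <- x / 2
  y[!m] <- 0
  w <- matrix(as.numeric(m), n, L)
  n_obs <- sum(w)

  if (K == 1) {
    f <- colSums(y) / pmax(colSums(w), 1)
    Q <- matrix(1, n, 1, dimnames = list(g$samples, "C1"))
    Fm <- matrix(f, 1, L, dimnames = list("C1", g$loci))
    obj <- sum((w * (y - Q %*% Fm))^2) / n_obs
    return(structure(list(Q = Q, F = Fm, objective = obj,
                          objective_trace = obj, K = 1L, seed = seed,
                          converged = TRUE, iterations = 0L),
                     class = "admixture_model"))
  }

  set.seed(seed)
  init <- admixture_init(g, K)
  Q <- init$Q
  Fm <- init$F

  obj <- function(Q, Fm) sum((w * (y - Q %*% Fm))^2) / n_obs
  trace <- numeric(0)
  prev <- obj(Q, Fm)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    Fm <- update_frequencies(y, w, Q, Fm, sweeps = 2)
    Q <- update_memberships(y, w, Q, Fm)
    cur <- obj(Q, Fm)
    trace <- c(trace, cur)
    if (prev - cur < tol * max(prev, .Machine$double.eps)) {
      converged <- TRUE
      prev <- cur
      break
    }
    prev <- cur
  }
  dimnames(Q) <- list(g$samples, paste0("C", seq_len(K)))
  dimnames(Fm) <- list(paste0("C", seq_len(K)), g$loci)
  structure(list(Q = Q, F = Fm, objective = prev, objective_trace = trace,
                 K = as.integer(K), seed = seed, converged = converged,
                 iterations = it),
            class = "admixture_model")
}

#' @export
print.admixture_model <- function(x, ...) {
  cat(sprintf("admixture model: K = %d, %d samples, objective = %.6g (%s in %d iter)\n",
              x$K, nrow(x$Q), x$objective,
              ifelse(x$converged, "converged", "max_iter"), x$iterations))
  invisible(x)
}

# K-means++ style initialization on PCA scores; hard assignments softened
# to Q, F from per-cluster masked mean frequencies.
admixture_init <- function(g, K) {
  x <- impute_mean(g$calls)
  n <- nrow(x)
  n_comp <- min(max(K, 5), n - 1, ncol(x))
  v <- apply(x, 2, stats::var)
  if (all(v == 0)) {
    hard <- rep(seq_len(K), length.out = n)
  } else {
    pc <- stats::prcomp(x, center = TRUE)
    sc <- pc$x[, seq_len(min(n_comp, ncol(pc$x))), drop = FALSE]
    centers <- kmeanspp_centers(sc, K)
    km <- suppressWarnings(stats::kmeans(sc, centers = centers, iter.max = 50))
    hard <- km$cluster
  }
  eps <- 0.05
  Q <- matrix(eps / K, n, K)
  Q[cbind(seq_len(n), hard)] <- 1 - eps + eps / K
  m <- !is.na(g$calls)
  y <- g$calls / 2
  y[!m] <- 0
  w <- matrix(as.numeric(m), n, ncol(y))
  num <- rowsum(y * w, hard)
  den <- rowsum(w, hard)
  Fm <- matrix(0.5, K, ncol(y))
  got <- as.integer(rownames(num))
  Fm[got, ] <- as.matrix(num / pmax(den, 1))
  Fm[Fm < 0] <- 0
  Fm[Fm > 1] <- 1
  list(Q = Q, F = Fm)
}

kmeanspp_centers <- function(sc, K) {
  n <- nrow(sc)
  idx <- integer(K)
  idx[1] <- sample.int(n, 1)
  if (K > 1) {
    d2 <- rowSums((sc - matrix(sc[idx[1], ], n, ncol(sc), byrow = TRUE))^2)
    for (k in 2:K) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx[k] <- sample.int(n, 1, prob = prob)
      d2k <- rowSums((sc - matrix(sc[idx[k], ], n, ncol(sc), byrow = TRUE))^2)
      d2 <- pmin(d2, d2k)
    }
  }
  sc[idx, , drop = FALSE]
}

# Exact box-constrained coordinate descent on F (vectorized across loci).
update_frequencies <- function(y, w, Q, Fm, sweeps = 2) {
  K <- nrow(Fm)
  r <- w * (y - Q %*% Fm)   # masked residual
  qsq <- Q^2
  for (s in seq_len(sweeps)) {
    for (k in seq_len(K)) {
      qk <- Q[, k]
      denom <- drop(crossprod(qsq[, k], w))
      numer <- drop(crossprod(qk, r)) + denom * Fm[k, ]
      fk_new <- ifelse(denom > 0, numer / pmax(denom, .Machine$double.eps), Fm[k, ])
      fk_new <- pmin(pmax(fk_new, 0), 1)
      delta <- fk_new - Fm[k, ]
      changed <- delta != 0
      if (any(changed)) {
        r[, changed] <- r[, changed] -
          w[, changed] * tcrossprod(qk, delta[changed])
        Fm[k, ] <- fk_new
      }
    }
  }
  Fm
}

# Exact simplex-constrained least squares per sample row (active set).
update_memberships <- function(y, w, Q, Fm) {
  n <- nrow(y)
  K <- nrow(Fm)
  FFt <- tcrossprod(Fm)                     # K x K over all loci
  B <- Fm %*% t(y * w)                      # K x n right-hand sides
  miss_per_sample <- which(rowSums(w == 0) > 0)
  for (i in seq_len(n)) {
    A <- FFt
    if (i %in% miss_per_sample) {
      mi <- which(w[i, ] == 0)
      Fmi <- Fm[, mi, drop = FALSE]
      A <- FFt - tcrossprod(Fmi)
    }
    Q[i, ] <- simplex_ls(A, B[, i], Q[i, ])
  }
  Q
}

# Minimize q'Aq/2 - b'q subject to q >= 0, sum(q) = 1 (active set on the
# nonnegativity constraints; equality handled by a Lagrange multiplier).
simplex_ls <- function(A, b, start) {
  K <- length(b)
  free <- rep(TRUE, K)
  for (pass in seq_len(2 * K)) {
    nf <- sum(free)
    if (nf == 1) {
      q <- numeric(K)
      q[free] <- 1
      return(q)
    }
    Af <- A[free, free, drop = FALSE]
    bf <- b[free]
    M <- rbind(cbind(Af, 1), c(rep(1, nf), 0))
    rhs <- c(bf, 1)
    sol <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (is.null(sol)) {
      sol <- c(MASS_ginv_solve(M, rhs))
    }
    qf <- sol[seq_len(nf)]
    if (all(qf >= -1e-12)) {
      q <- numeric(K)
      q[free] <- pmax(qf, 0)
      q <- q / sum(q)
      return(q)
    }
    worst <- which.min(qf)
    free[which(free)[worst]] <- FALSE
  }
  q <- pmax(start, 0)
  q / sum(q)
}

# Minimal pseudo-inverse solve (avoids importing MASS for one corner case).
MASS_ginv_solve <- function(M, rhs) {
  sv <- svd(M)
  pos <- sv$d > max(dim(M)) * .Machine$double.eps * sv$d[1]
  sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% rhs) / sv$d[pos])
}

#' Select the number of clusters by masked-entry cross-validation
#'
#' For each candidate K, a random fraction of the non-missing calls is
#' masked, the admixture model is fitted to the remainder, and the
#' prediction error (mean squared error between the masked dosage
#' fractions and `Q %*% F`) is scored, averaged over seeds. The chosen K
#' is the smallest K whose mean error lies within one standard error of
#' the minimum (one-SE rule).
#'
#' @param g A [genotype_matrix].
#' @param K_range Candidate K values; default `1:5`.
#' @param seeds Integer seeds, one fit per seed per K; default `1:3`.
#' @param holdout_fraction Fraction of non-missing calls masked; default
#'   0.05.
#' @param max_iter,tol Passed to [estimate_admixture()].
#' @return List with `K` (chosen), `curve` (`data.frame` with `K`,
#'   `mean_error`, `se_error`), and `errors` (seeds x K matrix).
#' @export
select_k <- function(g, K_range = 1:5, seeds = 1:3, holdout_fraction = 0.05,
                     max_iter = 50, tol = 1e-5) {
  g <- as_gm(g)
  if (length(K_range) == 0) stop("K_range must be non-empty")
  K_range <- sort(unique(as.integer(K_range)))
  x <- g$calls
  obs_idx <- which(!is.na(x))
  n_hold <- floor(holdout_fraction * length(obs_idx))
  if (n_hold < 1) stop("holdout_fraction leaves no calls to mask")
  errors <- matrix(NA_real_, length(seeds), length(K_range),
                   dimnames = list(NULL, paste0("K", K_range)))
  for (si in seq_along(seeds)) {
    set.seed(seeds[si])
    hold <- sample(obs_idx, n_hold)
    x_train <- x
    x_train[hold] <- NA_integer_
    g_train <- genotype_matrix(x_train, g$samples, g$loci)
    truth <- x[hold] / 2
    for (ki in seq_along(K_range)) {
      fit <- estimate_admixture(g_train, K_range[ki], seed = seeds[si],
                                max_iter = max_iter, tol = tol)
      pred <- (fit$Q %*% fit$F)[hold]
      errors[si, ki] <- mean((truth - pred)^2)
    }
  }
  mean_err <- colMeans(errors)
  se_err <- apply(errors, 2, stats::sd) / sqrt(nrow(errors))
  se_err[is.na(se_err)] <- 0
  best <- which.min(mean_err)
  within <- which(mean_err <= mean_err[best] + se_err[best])
  chosen <- K_range[min(within)]
  list(K = chosen,
       curve = data.frame(K = K_range, mean_error = unname(mean_err),
                          se_error = unname(se_err)),
       errors = errors)
}
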