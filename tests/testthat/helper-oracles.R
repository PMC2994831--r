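# Independent oracles used across the suite. These deliberately use naive,
# enumerative formulations so they share no code path with the package.

# Is a set of 0-based voxel coordinates face-connected? Flood fill.
flood_fill_connected <- function(coords) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n <= 1L) return(TRUE)
  key <- function(v) paste(v, collapse = ",")
  members <- new.env(parent = emptyenv())
  for (r in seq_len(n)) assign(key(coords[r, ]), TRUE, members)
  seen <- new.env(parent = emptyenv())
  queue <- list(coords[1L, ])
  assign(key(coords[1L, ]), TRUE, seen)
  count <- 0L
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  while (length(queue) > 0L) {
    v <- queue[[1L]]; queue <- queue[-1L]
    count <- count + 1L
    for (r in seq_len(6L)) {
      nb <- v + offs[r, ]
      k <- key(nb)
      if (!is.null(get0(k, members)) && is.null(get0(k, seen))) {
        assign(k, TRUE, seen)
        queue[[length(queue) + 1L]] <- nb
      }
    }
  }
  count == n
}

# Exact soft-margin linear SVM by enumerating active-set partitions of the
# dual QP: min 1/2 a'Qa - 1'a, 0 <= a <= C, y'a = 0, with Q = (yy') * (XX').
# For every partition of samples into {a=0}, {a=C}, {free}, solve the
# stationarity system on the free block; every feasible candidate's dual
# objective upper-bounds the optimum, and the optimum's own partition is
# among them, so the minimum over candidates is exact.
qp_svm_oracle <- function(X, y, C) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(n <= 8L, all(y %in% c(-1, 1)))
  Q <- tcrossprod(X) * tcrossprod(y)
  best <- Inf; best_a <- NULL
  states <- expand.grid(rep(list(0:2), n))  # 0: a=0, 1: a=C, 2: free
  for (s in seq_len(nrow(states))) {
    st <- as.integer(states[s, ])
    a <- ifelse(st == 1L, C, 0)
    Fr <- which(st == 2L)
    if (length(Fr) > 0L) {
      # [Q_FF y_F; y_F' 0] [a_F; mu] = [1 - Q_FU a_U; -y_U' a_U]
      A <- rbind(cbind(Q[Fr, Fr, drop = FALSE], y[Fr]), c(y[Fr], 0))
      rhs <- c(1 - Q[Fr, -Fr, drop = FALSE] %*% a[-Fr][seq_len(n - length(Fr))],
               -sum(y[-Fr] * a[-Fr][seq_len(n - length(Fr))]))
      if (length(Fr) == n) rhs <- c(rep(1, n), 0)
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      a[Fr] <- sol[seq_along(Fr)]
    }
    if (any(a < -1e-9 | a > C + 1e-9)) next
    if (abs(sum(y * a)) > 1e-8) next
    obj <- 0.5 * as.numeric(t(a) %*% Q %*% a) - sum(a)
    if (obj < best - 1e-12) { best <- obj; best_a <- a }
  }
  w <- as.numeric(crossprod(X, best_a * y))
  sv <- which(best_a > 1e-7 & best_a < C - 1e-7)
  b <- if (length(sv)) mean(y[sv] - X[sv, , drop = FALSE] %*% w) else {
    # no margin vectors: any b in the subgradient-optimal interval works;
    # pick the midpoint of the feasible interval for the hinge subgradient
    stats::optimize(function(b) svm_primal_objective(w, b, X, y, C),
                    c(-10, 10), tol = 1e-10)$minimum
  }
  list(alpha = best_a, w = w, b = b, dual_objective = -best)
}

svm_primal_objective <- function(w, b, X, y, C) {
  margins <- 1 - y * (as.matrix(X) %*% w + b)
  0.5 * sum(w^2) + C * sum(pmax(0, margins))
}

# Tie-corrected Mann-Whitney AUC from ranks.
mwu_auc <- function(weights, truth) {
  r <- rank(weights)
  n1 <- sum(truth); n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Joint log-likelihood ratio by multiplying per-voxel Gaussian densities.
gnb_oracle <- function(model, x) {
  log(prod(stats::dnorm(x, model$mu[1, ], sqrt(model$var[1, ])))) -
    log(prod(stats::dnorm(x, model$mu[2, ], sqrt(model$var[2, ])))) +
    as.numeric(model$log_prior_ratio)
}
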