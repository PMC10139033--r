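# Independent oracles used to cross-check the implementation. These are
# written from the definitions (explicit sums, pair counting, rotation-space
# search) and deliberately share no code with the package internals.

# direct-summation validation statistics
oracle_metrics <- function(y, yh, train_mean = NULL, train_ss = NULL,
                           n_train = NULL) {
  n <- length(y)
  ybar <- sum(y) / n
  yhbar <- sum(yh) / n
  if (is.null(train_mean)) train_mean <- ybar
  if (is.null(train_ss)) train_ss <- sum((y - ybar)^2)
  if (is.null(n_train)) n_train <- n
  press <- sum((y - yh)^2)
  sstot <- sum((y - ybar)^2)
  sspred <- sum((yh - yhbar)^2)
  r2 <- 1 - press / sstot
  k <- sum(y * yh) / sum(yh^2)
  kp <- sum(y * yh) / sum(y^2)
  r2_0 <- 1 - sum((y - k * yh)^2) / sstot
  r2_0p <- 1 - sum((yh - kp * y)^2) / sspred
  ccc <- 2 * sum((y - ybar) * (yh - yhbar)) /
    (sstot + sspred + n * (ybar - yhbar)^2)
  qf1 <- 1 - press / sum((y - train_mean)^2)
  qf2 <- 1 - press / sstot
  qf3 <- 1 - (press / n) / (train_ss / n_train)
  rm2 <- r2 * (1 - sqrt(abs(r2 - r2_0)))
  rm2p <- r2 * (1 - sqrt(abs(r2 - r2_0p)))
  list(r2 = r2, mae = sum(abs(y - yh)) / n, k_slope = k, k_prime = kp,
       r2_0 = r2_0, r2_0_prime = r2_0p, ccc = ccc,
       qf1 = qf1, qf2 = qf2, qf3 = qf3,
       rm2 = rm2, rm2_prime = rm2p, rm2_bar = (rm2 + rm2p) / 2)
}

# exhaustive pair-counting AUC (ties count one half)
brute_auc <- function(score, label) {
  pos <- score[as.logical(label)]
  neg <- score[!as.logical(label)]
  s <- 0
  for (p in pos) for (q in neg) {
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

# exhaustive CFS optimum with merit computed from the definition
oracle_cfs_best <- function(bits, activity) {
  keep <- which(apply(bits, 2, stats::var) > 0)
  x <- bits[, keep, drop = FALSE]
  m <- ncol(x)
  best <- -Inf
  best_S <- integer(0)
  for (mask in seq_len(2^m - 1L)) {
    S <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0)
    k <- length(S)
    rcf <- mean(abs(apply(x[, S, drop = FALSE], 2,
                          function(col) stats::cor(col, activity))))
    rff <- if (k > 1) {
      cc <- abs(stats::cor(x[, S, drop = FALSE]))
      mean(cc[upper.tri(cc)])
    } else 0
    mer <- k * rcf / sqrt(k + k * (k - 1) * rff)
    if (mer > best) { best <- mer; best_S <- S }
  }
  list(merit = best, subset = keep[best_S])
}

# brute-force minimum RMSD over rigid motions: centre both configurations,
# then grid + Nelder-Mead over Euler angles
oracle_fitted_rmsd <- function(A, B) {
  rot <- function(p) {
    ca <- cos(p); sa <- sin(p)
    Rz <- matrix(c(ca[1], -sa[1], 0, sa[1], ca[1], 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(ca[2], 0, sa[2], 0, 1, 0, -sa[2], 0, ca[2]), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, ca[3], -sa[3], 0, sa[3], ca[3]), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  obj <- function(p) sqrt(mean(rowSums((Ac %*% t(rot(p)) - Bc)^2)))
  best <- Inf
  grid <- seq(0, 2 * pi, length.out = 7)[-7]
  for (a in grid) for (b in grid) for (c_ in grid) {
    o <- stats::optim(c(a, b, c_), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
    if (o$value < best) best <- o$value
  }
  best
}

template_xyz <- function(tmpl) as.matrix(tmpl[, c("x", "y", "z")])
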