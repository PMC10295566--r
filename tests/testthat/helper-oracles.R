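# Independent oracles: deliberately naive implementations used only to check
# the package's optimised paths.

# full-matrix textbook Kalman predict+update for a scalar measurement
oracle_kf_step <- function(s, P, z, dt, alpha, beta) {
  A <- matrix(c(1, dt, dt^2 / 2,
                0, 1, dt,
                0, 0, 1), 3, 3, byrow = TRUE)
  H <- matrix(c(1, 0, 0), nrow = 1)
  Q <- alpha * diag(3)
  sp <- A %*% s
  Pp <- A %*% P %*% t(A) + Q
  S <- H %*% Pp %*% t(H) + beta
  K <- Pp %*% t(H) %*% solve(S)
  sn <- sp + K %*% (z - H %*% sp)
  Pn <- (diag(3) - K %*% H) %*% Pp
  list(s = drop(sn), P = Pn, prior_s = drop(sp), prior_P = Pp)
}

# all monotone warping-path sums between two series (exponential enumeration)
oracle_dtw_paths <- function(g, p) {
  cost <- abs(outer(g, p, "-"))
  rec <- function(i, j) {
    if (i == 1 && j == 1) return(cost[1, 1])
    sums <- numeric(0)
    if (i > 1) sums <- c(sums, rec(i - 1, j))
    if (i > 1 && j > 1) sums <- c(sums, rec(i - 1, j - 1))
    if (j > 1) sums <- c(sums, rec(i, j - 1))
    sums + cost[i, j]
  }
  rec(length(g), length(p))
}

# brute-force least-RMSE DFT subset search over all N-subsets of components
oracle_lrmse_rmse <- function(theta, N) {
  m <- length(theta)
  X <- stats::fft(theta)
  kmax <- floor(m / 2)
  ks <- 0:kmax
  reconstruct <- function(sel) {
    Y <- complex(length.out = m)
    Y[sel + 1] <- X[sel + 1]
    mirror <- sel[sel > 0 & sel != m - sel]
    Y[m - mirror + 1] <- X[m - mirror + 1]
    Re(stats::fft(Y, inverse = TRUE) / m)
  }
  subsets <- utils::combn(ks, N, simplify = FALSE)
  min(vapply(subsets, function(s) sqrt(mean((theta - reconstruct(s))^2)),
             numeric(1)))
}

# direct single-loop evaluation of the nested percentage-error sums
oracle_pe <- function(data) {
  samples <- unique(data$sample)
  acc_s <- 0
  for (s in samples) {
    joints <- unique(data$joint[data$sample == s])
    acc_j <- 0
    for (j in joints) {
      rows <- data[data$sample == s & data$joint == j, ]
      rmse <- sqrt(sum((rows$pred - rows$gold)^2) / nrow(rows))
      acc_j <- acc_j + rmse / (max(rows$gold) - min(rows$gold))
    }
    acc_s <- acc_s + acc_j / length(joints)
  }
  100 * acc_s / length(samples)
}

# squared Mahalanobis distance via explicit inverse covariance
oracle_mahalanobis2 <- function(Z, z) {
  drop(t(z) %*% solve(stats::cov(Z)) %*% z)
}
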