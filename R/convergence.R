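# Split-Rhat and bulk-ESS on rank-normalized split chains, following the
# standard published estimators (rank normalization; split halves; Geyer
# initial-monotone truncation of the autocorrelation sum).

rank_normalize <- function(x) {
  s <- length(x)
  z <- stats::qnorm((rank(x, ties.method = "average") - 3 / 8) / (s + 1 / 4))
  array(z, dim = dim(x))
}

split_chain_matrix <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  half <- floor(n / 2)
  m <- m[seq_len(2 * half), , drop = FALSE]
  cbind(m[seq_len(half), , drop = FALSE],
        m[half + seq_len(half), , drop = FALSE])
}

rhat_basic <- function(m) {
  n <- nrow(m)
  if (n < 2L) return(NA_real_)
  W <- mean(apply(m, 2, stats::var))
  B <- n * stats::var(colMeans(m))
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Split-\eqn{\widehat{R}} of a parameter
#'
#' Rank-normalizes the pooled draws, splits each chain in half, and computes
#' the potential scale reduction factor over the resulting chains. Values
#' close to 1 indicate between-chain agreement.
#'
#' @param m iterations x chains matrix of draws.
#' @return scalar \eqn{\widehat{R}} (NA for constant draws).
#' @export
split_rhat <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L && nrow(m) < 4L) return(NA_real_)
  rhat_basic(split_chain_matrix(rank_normalize(m)))
}

#' Bulk effective sample size of a parameter
#'
#' Rank-normalizes and splits the chains, then estimates the integrated
#' autocorrelation time from chain-averaged autocovariances with Geyer's
#' initial monotone positive-pair truncation.
#'
#' @param m iterations x chains matrix of draws.
#' @return scalar ESS estimate (NA for constant draws).
#' @export
bulk_ess <- function(m) {
  m <- split_chain_matrix(rank_normalize(as.matrix(m)))
  n <- nrow(m)
  nc <- ncol(m)
  if (n < 4L) return(NA_real_)
  S <- n * nc
  W <- mean(apply(m, 2, stats::var))
  B <- if (nc > 1L) n * stats::var(colMeans(m)) else 0
  var_plus <- (n - 1) / n * W + B / n
  if (!is.finite(var_plus) || var_plus == 0) return(NA_real_)
  lag_max <- min(n - 1L, 500L)
  acov <- sapply(seq_len(nc), function(c) {
    stats::acf(m[, c], lag.max = lag_max, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  })
  mean_acov <- rowMeans(acov)  # lag 0..lag_max
  rho <- 1 - (W - mean_acov[-1]) / var_plus
  # Geyer pairs: P_t = rho_{2t} + rho_{2t+1}; truncate at first negative,
  # then enforce monotone non-increasing
  rho_all <- c(1, rho)
  np <- floor(length(rho_all) / 2)
  P <- rho_all[2 * seq_len(np) - 1] + rho_all[2 * seq_len(np)]
  keep <- which(P <= 0)
  if (length(keep)) P <- P[seq_len(keep[1] - 1)]
  if (length(P) > 1L) P <- cummin(P)
  tau <- max(-1 + 2 * sum(P), 1 / S)
  min(S / tau, S * log10(S))
}
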