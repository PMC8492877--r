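# Internal numerical helpers.

# Truncated normal sampler by inverse-CDF; vectorised over n.
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  pl <- pnorm(lower, mean, sd)
  pu <- pnorm(upper, mean, sd)
  if (any(pu - pl <= 0))
    stop("infeasible truncation bounds", call. = FALSE)
  qnorm(runif(n, pl, pu), mean, sd)
}

.logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Random-effect covariance for a model: diagonal omega^2 with the single
# CL-Vc off-diagonal term.
.omegaMatrix <- function(omega, corr) {
  P <- length(omega)
  S <- diag(omega^2, P)
  dimnames(S) <- list(names(omega), names(omega))
  if (P >= 2) S[1, 2] <- S[2, 1] <- corr * omega[1] * omega[2]
  S
}

# Cholesky of a possibly singular covariance; inflates dead diagonal
# entries by `floor` so conditional densities stay proper.
.safeChol <- function(S, floor = 1e-10) {
  d <- diag(S)
  diag(S) <- pmax(d, floor)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("random-effect covariance is not positive semi-definite",
         call. = FALSE)
  if (min(ev) < floor) diag(S) <- diag(S) + floor
  chol(S)
}

# Small non-cryptographic content hash (FNV-1a over serialized bytes,
# 32-bit arithmetic done in doubles) for run manifests.
.contentHash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256                       # xor touches the low byte only
    h <- h - low + bitwXor(as.integer(low), b)
    lo16 <- h %% 65536; hi16 <- h %/% 65536
    h <- (lo16 * 16777619 + ((hi16 * 16777619) %% 65536) * 65536) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}
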