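# Independent oracles, deliberately naive, shared across test files.

# exhaustive double-loop band-pair search
naive_pair_search <- function(X, wl, y, kind) {
  best <- list(r = 0, l1 = NA, l2 = NA)
  for (i in seq_len(ncol(X))) {
    for (j in seq_len(ncol(X))) {
      if (i == j) next
      v <- two_band_index(X[, i], X[, j], kind)
      if (anyNA(v) || sd(v) == 0) next
      r <- cor(v, y)
      if (abs(r) > abs(best$r)) best <- list(r = r, l1 = wl[i], l2 = wl[j])
    }
  }
  best
}

# textbook Gram-Schmidt successive-projection forward selection
naive_spa <- function(X, k0, N, standardize = TRUE) {
  if (standardize) X <- scale(X)
  X <- unname(as.matrix(X))
  sel <- k0
  for (step in seq_len(N - 1)) {
    basis <- qr.Q(qr(X[, sel, drop = FALSE]))
    resid_norm <- rep(-Inf, ncol(X))
    for (j in setdiff(seq_len(ncol(X)), sel)) {
      v <- X[, j]
      v <- v - basis %*% crossprod(basis, v)
      resid_norm[j] <- sum(v^2)
    }
    sel <- c(sel, which.max(resid_norm))
  }
  sel
}
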