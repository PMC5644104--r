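# Shared fixtures and independent brute-force oracles used across tests.

# strip everything but dim for value-only matrix comparisons
bare <- function(m) {
  attributes(m) <- attributes(m)["dim"]
  m
}

# 2x2 identity-pattern toy used for hand-derived values
toy_A <- function() {
  matrix(c(1, 0, 0, 1), 2, 2,
         dimnames = list(c("d1", "d2"), c("m1", "m2")))
}

random_assoc <- function(n_d, n_m, p = 0.4) {
  A <- matrix(rbinom(n_d * n_m, 1, p) * 1, n_d, n_m,
              dimnames = list(sprintf("d%02d", seq_len(n_d)),
                              sprintf("m%02d", seq_len(n_m))))
  # guarantee at least one association so kernels are defined
  if (sum(A) == 0) A[1, 1] <- 1
  A
}

random_similarity <- function(n, ids) {
  S <- crossprod(matrix(runif(n * n), n))
  S <- S / max(S)
  diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  S
}

# Eqs. of the neighbor model as explicit double loops
cf_oracle <- function(A, DS, MS) {
  n_d <- nrow(A); n_m <- ncol(A)
  s_d <- matrix(0, n_d, n_m)
  s_m <- matrix(0, n_d, n_m)
  for (i in seq_len(n_d)) for (j in seq_len(n_m)) {
    s_d[i, j] <- sum(DS[i, ] * A[, j]) / n_d
    s_m[i, j] <- sum(MS[j, ] * A[i, ]) / n_m
  }
  list(s_disease = s_d, s_microbe = s_m, ns = (s_d + s_m) / 2)
}

# Two-step diffusion as explicit elementwise loops (0/0 := 0)
diffusion_oracle <- function(A, DS, MS, alpha, beta) {
  n_d <- nrow(A); n_m <- ncol(A)
  a_d <- DS %*% A
  a_m <- A %*% MS
  S1 <- matrix(0, n_d, n_d)
  for (i in seq_len(n_d)) {
    s <- numeric(n_d)
    for (j in seq_len(n_m)) {
      cm <- sum(a_m[, j]); cd <- sum(a_d[, j])
      if (cm > 0) s <- s + alpha * a_m[i, j] * A[, j] / cm
      if (cd > 0) s <- s + (1 - alpha) * a_d[i, j] * A[, j] / cd
    }
    S1[, i] <- s
  }
  GS <- matrix(0, n_d, n_m)
  for (j in seq_len(n_m)) {
    sp <- numeric(n_d)
    for (k in seq_len(n_d)) {
      rm_ <- sum(a_m[k, ]); rd <- sum(a_d[k, ])
      if (rm_ > 0) sp <- sp + beta * a_m[k, j] * S1[, k] / rm_
      if (rd > 0) sp <- sp + (1 - beta) * a_d[k, j] * S1[, k] / rd
    }
    GS[, j] <- sp
  }
  GS
}

# Mann-Whitney concordance by exhaustive pair counting, ties credited 1/2
concordance_oracle <- function(test, cand) {
  tot <- 0
  for (s in test) for (c in cand) {
    tot <- tot + (s > c) + 0.5 * (s == c)
  }
  tot / (length(test) * length(cand))
}

# Damped walk-count sum by explicit enumeration of all walks of length <= L
katz_walk_oracle <- function(H, beta, L) {
  n <- nrow(H)
  S <- matrix(0, n, n)
  recurse <- function(start, cur, len, wprod) {
    for (nxt in seq_len(n)) {
      w <- wprod * H[cur, nxt]
      S[start, nxt] <<- S[start, nxt] + beta^(len + 1) * w
      if (len + 1 < L) recurse(start, nxt, len + 1, w)
    }
  }
  for (v in seq_len(n)) recurse(v, v, 0, 1)
  S
}
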