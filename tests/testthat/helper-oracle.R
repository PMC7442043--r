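# Independent spatial-domain oracle for the convolutional sparse coding
# objective: an explicit circular-convolution matrix plus plain proximal
# gradient (ISTA).  Shares no code with the Fourier-domain ADMM solver.

# embed a 1D atom in length n with its centre wrapped to index 1, matching the
# solver's convention that coefficient peaks address atom centres
oracle_embed <- function(atom, n) {
  out <- numeric(n)
  ctr <- ceiling((length(atom) + 1) / 2)
  idx <- ((seq_along(atom) - ctr) %% n) + 1L
  out[idx] <- atom
  out
}

# dense operator A such that A %*% c(z_1, ..., z_M) = sum_m d_m (*) z_m
oracle_operator <- function(atoms, n) {
  cols <- lapply(atoms, function(a) {
    e <- oracle_embed(a, n)
    vapply(seq_len(n), function(s) e[((seq_len(n) - s) %% n) + 1L], numeric(n))
  })
  do.call(cbind, cols)
}

oracle_objective <- function(A, y, z, beta) {
  0.5 * sum((y - A %*% z)^2) + beta * sum(abs(z))
}

# ISTA with fixed step 1 / ||A||_2^2
oracle_ista <- function(atoms, y, beta, iters = 4000) {
  n <- length(y)
  A <- oracle_operator(atoms, n)
  L <- (svd(A, nu = 0, nv = 0)$d[1])^2
  z <- numeric(ncol(A))
  for (i in seq_len(iters)) {
    g <- crossprod(A, A %*% z - y)
    z <- soft_threshold(z - g / L, beta / L)
  }
  list(z = z, objective = oracle_objective(A, y, z, beta), A = A)
}

# exhaustive normalized cross-correlation over atoms and circular shifts
oracle_ncc_argmax <- function(atoms, y) {
  n <- length(y)
  best <- c(-Inf, NA, NA)
  for (m in seq_along(atoms)) {
    e <- oracle_embed(atoms[[m]], n)
    for (s in 0:(n - 1)) {
      v <- sum(y * e[((seq_len(n) - 1 - s) %% n) + 1L]) / sqrt(sum(e^2))
      if (v > best[1]) best <- c(v, m, s + 1)
    }
  }
  list(atom = best[2], position = best[3], value = best[1])
}

# small random 1D test atoms: unit-norm bumps of distinct widths
oracle_atoms <- function(M, width = 9) {
  lapply(seq_len(M), function(m) {
    x <- seq(-4, 4, length.out = width)
    a <- exp(-x^2 / (2 * (0.4 + 0.35 * m)^2)) * cos(x * m / 2)
    a / sqrt(sum(a^2))
  })
}
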