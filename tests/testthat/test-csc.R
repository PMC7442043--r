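# Convolutional sparse coding: proximal operator, ADMM solver against an
# independent spatial-domain oracle, selection, weights and fusion.

test_that("soft-thresholding matches the closed form on exhaustive grids", {
  xs <- seq(-3, 3, by = 0.125)
  for (lam in c(0, 0.25, 0.5, 1, 2)) {
    expect_equal(soft_threshold(xs, lam), sign(xs) * pmax(abs(xs) - lam, 0))
  }
  expect_equal(soft_threshold(1.2, 0.5), 0.7)
  expect_equal(soft_threshold(-1.2, 0.5), -0.7)
  expect_equal(soft_threshold(0.5, 1), 0)
  m <- matrix(c(-2, 0.1, 3, -0.4), 2)
  expect_equal(soft_threshold(m, 0), m)
  expect_error(soft_threshold(1, -0.1))
})

test_that("a beta above the null threshold yields all-zero maps", {
  atoms <- oracle_atoms(3)
  y <- oracle_embed(atoms[[2]], 48)
  y <- y[((seq_len(48) - 1 - 17) %% 48) + 1]  # shift by 17
  ncc <- max(vapply(atoms, function(a) {
    e <- oracle_embed(a, 48)
    max(abs(vapply(0:47, function(s) sum(y * e[((seq_len(48) - 1 - s) %% 48) + 1]),
                   numeric(1))))
  }, numeric(1)))
  fit <- csc_admm(matrix(y, 1), atoms, beta = ncc * 1.01, pad = 0, max_iter = 200)
  # the sparse solution is identically zero; the quadratic iterate approaches it
  expect_true(all(fit$T == 0))
  expect_lt(max(abs(fit$maps)), 0.05 * ncc)
})

test_that("Fourier-domain ADMM matches a spatial-domain proximal-gradient oracle", {
  set.seed(11)
  worst <- 0
  for (trial in 1:10) {
    M <- sample(2:3, 1)
    N <- sample(c(32, 48, 64), 1)
    atoms <- oracle_atoms(M)
    z_true <- numeric(M * N)
    z_true[sample(M * N, 3)] <- runif(3, 0.5, 2)
    A <- oracle_operator(atoms, N)
    y <- as.numeric(A %*% z_true) + rnorm(N, sd = 0.02)
    beta <- 0.1 * max(abs(crossprod(A, y)))
    fit <- csc_admm(matrix(y, 1), atoms, beta = beta, pad = 0,
                    max_iter = 500, tol = 1e-8)
    # evaluate the common functional at T (the sparse iterate)
    zT <- as.numeric(sapply(seq_len(M), function(m) fit$T[m, 1, ]))
    obj_admm <- oracle_objective(A, y, zT, beta)
    orc <- oracle_ista(atoms, y, beta, iters = 4000)
    gap <- abs(obj_admm - orc$objective) / max(orc$objective, 1e-12)
    worst <- max(worst, gap)
  }
  expect_lt(worst, 1e-4)
})

test_that("an exact shifted atom copy is identified at the right atom and shift", {
  atoms <- oracle_atoms(3)
  N <- 40
  for (q in 1:3) for (tau in c(5, 23)) {
    y <- oracle_embed(atoms[[q]], N)
    y <- y[((seq_len(N) - tau) %% N) + 1]  # centre now at index tau
    fit <- csc_admm(matrix(y, 1), atoms, beta = 1e-3, pad = 0, max_iter = 300)
    peak <- arrayInd(which.max(abs(fit$maps)), dim(fit$maps))
    ref <- oracle_ncc_argmax(atoms, y)
    expect_equal(peak[1], ref$atom)
    expect_equal(peak[3], ref$position)
    expect_equal(ref$position, tau)
  }
})

test_that("coefficient maps are equivariant to circular shifts of the input", {
  atoms <- oracle_atoms(2)
  z_sparse <- numeric(64)
  z_sparse[c(5, 40)] <- c(1, 0.8)
  y <- as.numeric(oracle_operator(atoms, 32) %*% z_sparse)
  fit0 <- csc_admm(matrix(y, 1), atoms, beta = 0.05, pad = 0, max_iter = 200)
  tau <- 7
  ys <- y[((seq_len(32) - 1 - tau) %% 32) + 1]
  fit1 <- csc_admm(matrix(ys, 1), atoms, beta = 0.05, pad = 0, max_iter = 200)
  for (m in 1:2) {
    shifted <- fit0$maps[m, 1, ][((seq_len(32) - 1 - tau) %% 32) + 1]
    expect_equal(fit1$maps[m, 1, ], shifted, tolerance = 1e-8)
  }
})

test_that("the solver never exceeds the trivial zero-coefficient objective", {
  dict <- test_dictionary()
  epi <- extract_epi(test_ball_lf(16), "horizontal")
  fit <- csc_admm(epi, dict, max_iter = 500)
  expect_lt(utils::tail(fit$objective, 1), 0.5 * sum(unclass(epi)^2))
  expect_true(all(is.finite(fit$objective)))
  expect_lt(utils::tail(fit$primal_residual, 1), 1e-3)
})

test_that("source selection ranks map energies and suppresses adjacent depths", {
  maps <- array(0, dim = c(4, 1, 20))
  maps[1, 1, 4] <- 3   # strongest
  maps[2, 1, 9] <- 2.5 # depth-adjacent to atom 1 -> suppressed
  maps[3, 1, 15] <- 2
  valid <- matrix(TRUE, 1, 20)
  fit <- structure(list(maps = maps, valid = valid, pad = c(0L, 0L)),
                   class = "lfm_csc")
  sel <- select_sources(fit, 2, depths = c(0, 4, 8, 12))
  expect_equal(sel$atom, c(1, 3))
  expect_equal(sel$peak_spatial, c(4, 15))
  expect_equal(sel$depth_um, c(0, 8))
  sel_nosup <- select_sources(fit, 2, depths = NULL)
  expect_equal(sel_nosup$atom, c(1, 2))
  expect_error(select_sources(fit, 4, depths = NULL), "fewer than")
  fit0 <- structure(list(maps = maps * 0, valid = valid, pad = c(0L, 0L)),
                    class = "lfm_csc")
  expect_error(select_sources(fit0, 1), "fewer than")
})

test_that("reliability weights follow the energy-ratio definition", {
  maps <- array(0, dim = c(3, 2, 2))
  maps[1, , ] <- 1
  expect_equal(compute_weight(maps, 1), 1)
  expect_equal(compute_weight(maps, c(2, 3)), 0)
  maps[2, , ] <- 1
  expect_equal(compute_weight(maps, 1), 0.5)
  expect_error(compute_weight(maps * 0, 1), "zero total")
  expect_error(compute_weight(maps, 9), "out of range")
})

test_that("fusion is a convex combination of the two estimates", {
  p_h <- c(1, 2, 8); p_v <- c(3, 0, 12)
  expect_equal(fuse_locations(p_h, p_v, 0.4, 0.4), (p_h + p_v) / 2)
  expect_equal(fuse_locations(p_h, p_v, 0.7, 0), p_h)
  expect_equal(fuse_locations(p_h, p_h, 0.9, 0.1), p_h)
  expect_error(fuse_locations(p_h, p_v, 0, 0), "zero")
})
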