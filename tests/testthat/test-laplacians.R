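test_that("restricted differentials keep nilpotency and match the full grid on a full mask", {
  gc <- build_grid_complex(c(3, 3, 3), 1)
  pv <- perturb_values(rep(-1, 27), 0, 1)
  m <- classify_support(gc, pv, NULL, 0, "normal")
  D <- restricted_differentials(gc, m)
  expect_equal(as.matrix(D[[1]]), as.matrix(incidence_matrix(gc, 0)))
  expect_equal(as.matrix(D[[3]]), as.matrix(incidence_matrix(gc, 2)))
  # random shapes and isovalues: exact nilpotency on both conditions
  fb <- sdf_primitive("four_ball_model", edge = 3, radius = 1)
  gcf <- centered_grid(15, 0.5)
  pvf <- sample_field(fb, gcf)
  dvf <- sample_field(fb, gcf, "dual_points")
  for (c0 in c(-0.2, 0.2, 0.6)) {
    for (bc in c("normal", "tangential")) {
      mk <- classify_support(gcf, perturb_values(pvf, c0, 0.5),
                             perturb_values(dvf, c0, 0.5), c0, bc)
      Dk <- restricted_differentials(gcf, mk)
      expect_identical(max(abs(Dk[[2]] %*% Dk[[1]]), 0), 0)
      expect_identical(max(abs(Dk[[3]] %*% Dk[[2]]), 0), 0)
    }
  }
})

test_that("restricted operators equal a brute-force re-derivation from kept cells", {
  ball <- ball_field(0.9)
  gc <- centered_grid(11, 0.25)
  pv <- perturb_values(sample_field(ball, gc), 0, 0.25)
  m <- classify_support(gc, pv, NULL, 0, "normal")
  D <- restricted_differentials(gc, m)
  for (k in 0:2) {
    full <- incidence_matrix(gc, k)
    oracle <- full[m$idx[[k + 2]], m$idx[[k + 1]], drop = FALSE]
    expect_equal(as.matrix(D[[k + 1]]), as.matrix(oracle))
  }
})

test_that("degree-0 BIG Laplacian on the full grid is the grid-graph Laplacian", {
  gc <- build_grid_complex(c(3, 3, 3), 1)
  pv <- perturb_values(rep(-1, 27), 0, 1)
  m <- classify_support(gc, pv, NULL, 0, "normal")
  D <- restricted_differentials(gc, m)
  L0 <- assemble_laplacian(D, 0, "big")
  # dense oracle: graph Laplacian deg - adj of the lattice graph
  A <- matrix(0, 27, 27)
  ev <- hodgecube:::.cell_vertices(gc, 1)
  for (i in seq_len(nrow(ev))) {
    A[ev[i, 1], ev[i, 2]] <- 1; A[ev[i, 2], ev[i, 1]] <- 1
  }
  oracle <- diag(rowSums(A)) - A
  expect_equal(as.matrix(L0), oracle)
  expect_equal(sum(abs(rowSums(as.matrix(L0)))), 0)
  # k = 3: Gram form, symmetric PSD
  L3 <- assemble_laplacian(D, 3, "big")
  expect_equal(as.matrix(L3), as.matrix(Matrix::tcrossprod(D[[3]])))
  ev3 <- eigen(as.matrix(L3), symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev3) > -1e-12)
})

test_that("hodge variant with identity stars equals the big variant exactly", {
  ball <- ball_field(0.9)
  gc <- centered_grid(9, 0.3)
  pv <- perturb_values(sample_field(ball, gc), 0, 0.3)
  m <- classify_support(gc, pv, NULL, 0, "normal")
  D <- restricted_differentials(gc, m)
  stars <- lapply(0:3, function(k) rep(1, m$n_kept[k + 1]))
  for (k in 0:3) {
    Lh <- assemble_laplacian(D, k, "hodge", stars)
    Lb <- assemble_laplacian(D, k, "big")
    expect_equal(as.matrix(Lh), as.matrix(Lb))
  }
  expect_error(assemble_laplacian(D, 1, "hodge"), "star")
})

test_that("symmetrization reproduces the generalized eigenproblem", {
  set.seed(13)
  n <- 40
  B <- matrix(rnorm(n * n), n)
  L <- crossprod(B)           # SPD stand-in for a Laplacian
  s <- runif(n, 0.5, 3)
  sym <- symmetrize_laplacian(L, s)
  ev1 <- sort(eigen(as.matrix(sym$L), symmetric = TRUE,
                    only.values = TRUE)$values)
  # dense generalized eigensolver oracle: L w = lambda S w
  ev2 <- sort(Re(eigen(diag(1 / s) %*% L, only.values = TRUE)$values))
  expect_equal(ev1, ev2, tolerance = 1e-10)
  expect_equal(as.matrix(symmetrize_laplacian(L, rep(1, n))$L), (L + t(L)) / 2)
  expect_error(symmetrize_laplacian(L, c(rep(1, n - 1), 0)), "nonpositive")
})

test_that("normalized differentials stay nilpotent and rebuild the symmetrized Laplacian", {
  ball <- ball_field(0.9)
  gc <- centered_grid(9, 0.3)
  b <- laplacian_bundle(gc, ball, isovalue = 0, bc = "normal",
                        variant = "hodge")
  Dn <- normalized_differentials(b$D, b$stars)
  expect_lt(max(abs(Dn[[2]] %*% Dn[[1]])), 1e-12)
  expect_lt(max(abs(Dn[[3]] %*% Dn[[2]])), 1e-12)
  for (k in 0:3) {
    L <- matrix(0, b$mask$n_kept[k + 1], b$mask$n_kept[k + 1])
    if (k < 3) L <- L + as.matrix(Matrix::crossprod(Dn[[k + 1]]))
    if (k > 0) L <- L + as.matrix(Matrix::tcrossprod(Dn[[k]]))
    expect_equal(as.matrix(b$L[[k + 1]]), L, tolerance = 1e-12)
  }
})

test_that("primal-normal and shifted-dual-tangential spectra coincide", {
  ball <- ball_field()
  gc <- centered_grid(17, 0.2)
  bn <- laplacian_bundle(gc, ball, isovalue = 0, bc = "normal",
                         variant = "big")
  gcd <- build_grid_complex(gc$counts - 1L, gc$spacing,
                            gc$origin + gc$spacing / 2)
  bt <- laplacian_bundle(gcd, ball, isovalue = 0, bc = "tangential",
                         variant = "big")
  for (k in c(0, 1)) {
    e1 <- sort(eigen(as.matrix(bn$L[[k + 1]]), symmetric = TRUE,
                     only.values = TRUE)$values)
    e2 <- sort(eigen(as.matrix(bt$L[[4 - k]]), symmetric = TRUE,
                     only.values = TRUE)$values)
    expect_equal(length(e1), length(e2))
    expect_lt(max(abs(e1 - e2)), 1e-8)
  }
})

test_that("big eigenvalues scaled by 1/spacing^2 approach hodge eigenvalues under refinement", {
  ball <- ball_field()
  err <- vapply(c(9, 13, 17), function(n) {
    gc <- centered_grid(n, 2.4 / (n - 1))
    bb <- laplacian_bundle(gc, ball, isovalue = 0, bc = "normal",
                           variant = "big")
    bh <- laplacian_bundle(gc, ball, isovalue = 0, bc = "normal",
                           variant = "hodge")
    sb <- smallest_spectrum(bb$L[[1]], m = 3)
    sh <- smallest_spectrum(bh$L[[1]], m = 3)
    abs(sb$lambda1 / gc$spacing^2 - sh$lambda1) / sh$lambda1
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("operators export as Matrix Market files", {
  gc <- build_grid_complex(c(3, 3, 3), 1)
  b <- laplacian_bundle(gc, isovalue = 0, bc = "normal", variant = "big",
                        primal_values = rep(-1, 27))
  path <- tempfile(fileext = ".mtx")
  write_operator_mtx(b$L[[1]], path)
  back <- Matrix::readMM(path)
  expect_equal(as.matrix(back), as.matrix(b$L[[1]]))
  unlink(path)
})
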