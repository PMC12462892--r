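ball_filtration <- function(n = 13, spacing = 0.26, isos = c(-0.2, -0.05, 0.1, 0.25)) {
  gc <- centered_grid(n, spacing)
  build_filtration(gc, ball_field(), isos, need_dual = TRUE)
}

test_that("filtrations are nested and reject bad isovalues", {
  filt <- ball_filtration()
  for (l in 2:length(filt$isovalues))
    for (k in 1:4)
      expect_false(any(filt$masks[[l - 1]]$keep[[k]] &
                         !filt$masks[[l]]$keep[[k]]))
  gc <- centered_grid(9, 0.3)
  expect_error(build_filtration(gc, ball_field(), c(0.1, 0.1)), "increasing")
  # four-ball across the merge: difference complex nonempty exactly when
  # cells enter
  fb <- sdf_primitive("four_ball_model", edge = 3, radius = 1)
  gcf <- centered_grid(17, 0.42)
  ff <- build_filtration(gcf, fb, c(0.25, 0.3, 0.55), need_dual = FALSE)
  n_new <- vapply(2:3, function(l)
    sum(ff$masks[[l]]$keep[[4]] & !ff$masks[[l - 1]]$keep[[4]]), numeric(1))
  expect_true(all(n_new > 0))
})

test_that("p = 0 persistent Laplacians equal the ordinary ones exactly", {
  filt <- ball_filtration()
  for (variant in c("big", "hodge")) {
    b <- laplacian_bundle(filt$complex, ball_field(), isovalue = -0.05,
                          bc = "normal", variant = variant)
    for (k in 0:3) {
      pl <- persistent_laplacian(filt, l = 2, p = 0, k = k, variant = variant)
      expect_equal(pl$L, as.matrix(b$L[[k + 1]]),
                   tolerance = if (variant == "big") 0 else 1e-12)
    }
  }
})

test_that("extension operators restrict back to the identity and fill harmonically", {
  filt <- ball_filtration()
  for (k in 0:3) {
    ext <- extension_operator(filt, l = 1, p = 2, k = k, variant = "big")
    R <- restriction_operator(ext)
    expect_lt(max(abs(R %*% ext$I - diag(ncol(ext$I)))), 1e-8)
    # identity rows on the level-l cells
    expect_equal(ext$I[cbind(ext$pos_old, seq_along(ext$pos_old))],
                 rep(1, length(ext$pos_old)))
  }
  # p = 0: plain identity
  ext0 <- extension_operator(filt, l = 2, p = 0, k = 1, variant = "big")
  expect_equal(ext0$I, diag(ncol(ext0$I)))
})

test_that("a bulk co-exact form extends by zero", {
  filt <- ball_filtration()
  idx_l <- filt$masks[[1]]$idx
  D2l <- filt$D_full[[3]][idx_l[[4]], idx_l[[3]], drop = FALSE]
  # potential on cubes far inside level 1 (all eight vertices well inside)
  centers <- dual_coordinates(filt$complex)[idx_l[[4]], , drop = FALSE]
  deep <- which(sqrt(rowSums(centers^2)) < 0.4)
  expect_gt(length(deep), 0)
  beta <- numeric(nrow(D2l)); beta[deep] <- seq_along(deep)
  omega <- as.numeric(Matrix::t(D2l) %*% beta)
  ext <- extension_operator(filt, l = 1, p = 2, k = 2, variant = "big")
  new_rows <- setdiff(seq_len(nrow(ext$I)), ext$pos_old)
  expect_lt(max(abs((ext$I %*% omega)[new_rows])), 1e-10)
})

test_that("persistent differentials compose to zero with the level differential", {
  filt <- ball_filtration()
  for (k in 2:3) {
    ext <- extension_operator(filt, l = 1, p = 2, k = k, variant = "big")
    idx_l <- filt$masks[[1]]$idx
    idx_p <- filt$masks[[3]]$idx
    Dp <- as.matrix(filt$D_full[[k]][idx_p[[k + 1]], idx_p[[k]], drop = FALSE])
    Dtil <- t(ext$I) %*% Dp
    if (k < 3) {
      Dl <- as.matrix(filt$D_full[[k + 1]][idx_l[[k + 2]], idx_l[[k + 1]],
                                           drop = FALSE])
      expect_lt(max(abs(Dl %*% Dtil)), 1e-10)
    } else {
      # at top degree there is no further differential; self-adjointness of
      # the assembled operator stands in
      pl <- persistent_laplacian(filt, 1, 2, 3, "big")
      expect_lt(max(abs(pl$L - t(pl$L))), 1e-10 * max(1, max(abs(pl$L))))
    }
  }
})

test_that("persistent operators are symmetric PSD in both variants", {
  filt <- ball_filtration()
  for (variant in c("big", "hodge")) {
    pl <- persistent_laplacian(filt, 1, 1, 2, variant)
    expect_lt(max(abs(pl$L - t(pl$L))), 1e-10 * max(1, max(abs(pl$L))))
    ev <- eigen(pl$L, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-9 * max(abs(ev)))
  }
})

test_that("ball filtrations have persistent component count 1 at every (l, p)", {
  filt <- ball_filtration()
  s <- length(filt$isovalues)
  for (l in 1:(s - 1))
    for (p in 0:(s - l)) {
      expect_equal(persistent_betti(filt, l, p, 3, "big"), 1L)
      expect_equal(persistent_component_count(filt, l, p), 1L)
    }
})

test_that("four-ball persistent beta0 across the merge matches union-find", {
  fb <- sdf_primitive("four_ball_model", edge = 3, radius = 1)
  gcf <- centered_grid(19, 0.38)
  filt <- build_filtration(gcf, fb, c(0.12, 0.2, 0.55), need_dual = FALSE)
  # before the merge: four components at p = 0
  expect_equal(persistent_betti(filt, 1, 0, 3, "big"), 4L)
  expect_equal(persistent_component_count(filt, 1, 0), 4L)
  # across the merge only the merged component persists
  expect_equal(persistent_betti(filt, 1, 2, 3, "big"), 1L)
  expect_equal(persistent_component_count(filt, 1, 2), 1L)
  # homotopy-equivalent pre-merge pair keeps all four
  expect_equal(persistent_betti(filt, 1, 1, 3, "big"), 4L)
  expect_equal(persistent_component_count(filt, 1, 1), 4L)
})

test_that("persistent kernel dimension is non-increasing in p", {
  filts <- list(
    ball_filtration(n = 11, spacing = 0.3, isos = c(-0.15, 0, 0.15, 0.3)),
    build_filtration(centered_grid(17, 0.42),
                     sdf_primitive("four_ball_model", edge = 3, radius = 1),
                     c(0.2, 0.35, 0.55, 0.75), need_dual = FALSE))
  for (filt in filts) {
    s <- length(filt$isovalues)
    for (k in c(2, 3))
      for (l in 1:(s - 1)) {
        dims <- vapply(0:(s - l), function(p)
          persistent_betti(filt, l, p, k, "big"), integer(1))
        expect_true(all(diff(dims) <= 0))
      }
  }
})
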