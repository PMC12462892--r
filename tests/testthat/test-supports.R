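test_that("perturbation clamps values away from the isovalue", {
  eps <- 1e-5
  v <- c(0, 3e-6, 0.5, -3e-6, -0.5, eps, -eps) + 2
  out <- perturb_values(v, isovalue = 2, spacing = 1)
  expect_equal(out - 2, c(-eps, eps, 0.5, -eps, -0.5, eps, -eps))
  expect_true(all(abs(out - 2) >= eps))
  # values already clear of the band are untouched
  expect_identical(perturb_values(c(1, 3), 2, 1), c(1, 3))
  # scale follows the spacing
  out2 <- perturb_values(2, isovalue = 2, spacing = 0.1)
  expect_equal(out2 - 2, -1e-6)
})

test_that("all-inside values keep every cell under both boundary conditions", {
  gc <- build_grid_complex(c(3, 3, 3), 1)
  pv <- rep(-1, gc$cell_counts[1])
  dv <- rep(-1, gc$cell_counts[4])
  for (bc in c("normal", "tangential")) {
    m <- classify_support(gc, pv, dv, isovalue = 0, bc = bc)
    expect_equal(m$n_kept, gc$cell_counts)
  }
  expect_error(classify_support(gc, pv, NULL, 0, "tangential"), "dual")
})

test_that("a single interior inside vertex keeps exactly its star", {
  gc <- build_grid_complex(c(4, 4, 4), 1)
  pv <- rep(1, gc$cell_counts[1])
  pv[hodgecube:::.lin_index(2, 2, 2, c(4, 4, 4))] <- -1
  m <- classify_support(gc, pv, NULL, isovalue = 0, bc = "normal")
  expect_equal(m$n_kept, c(1, 6, 12, 8))
})

test_that("normal and tangential supports differ near the boundary (1-cells)", {
  # a tilted half-space: edges near the boundary land in one support but
  # not the other, in both directions
  gc <- build_grid_complex(c(4, 4, 4), 1)
  f <- scalar_field(function(p) (p[, 1] + p[, 2]) / sqrt(2) - 0.8,
                    "halfspace")
  pv <- perturb_values(sample_field(f, gc), 0, 1)
  dv <- perturb_values(sample_field(f, gc, "dual_points"), 0, 1)
  mn <- classify_support(gc, pv, dv, 0, "normal")
  mt <- classify_support(gc, pv, dv, 0, "tangential")
  in_n <- mn$keep[[2]]; in_t <- mt$keep[[2]]
  expect_true(any(in_n & !in_t))   # neither support contains the other
  expect_true(any(in_t & !in_n))
  # both agree strictly inside and strictly outside
  expect_true(all(in_n[Matrix::rowSums(abs(incidence_matrix(gc, 0))) == 0]
                  == in_t[Matrix::rowSums(abs(incidence_matrix(gc, 0))) == 0]))
})

test_that("supports are monotone in the isovalue", {
  fb <- sdf_primitive("four_ball_model", edge = 3, radius = 1)
  gc <- centered_grid(19, 0.4)
  pv0 <- sample_field(fb, gc)
  dv0 <- sample_field(fb, gc, "dual_points")
  set.seed(21)
  for (i in 1:20) {
    cs <- sort(runif(2, -0.5, 1))
    for (bc in c("normal", "tangential")) {
      m1 <- classify_support(gc, perturb_values(pv0, cs[1], 0.4),
                             perturb_values(dv0, cs[1], 0.4), cs[1], bc)
      m2 <- classify_support(gc, perturb_values(pv0, cs[2], 0.4),
                             perturb_values(dv0, cs[2], 0.4), cs[2], bc)
      for (k in 1:4)
        expect_true(!any(m1$keep[[k]] & !m2$keep[[k]]))
    }
  }
})

test_that("projection matrices select kept rows and satisfy P t(P) = I", {
  gc <- build_grid_complex(c(3, 3, 3), 1)
  pv <- perturb_values(sample_field(ball_field(0.9), gc,), 0, 1)
  m <- classify_support(gc, pv, NULL, 0, "normal")
  for (k in 0:3) {
    P <- projection_matrix(m, k)
    expect_equal(dim(P), c(m$n_kept[k + 1], gc$cell_counts[k + 1]))
    if (nrow(P))
      expect_equal(as.matrix(P %*% Matrix::t(P)),
                   diag(nrow(P)), tolerance = 0)
  }
  # full mask gives the identity
  mfull <- classify_support(gc, rep(-1, 27), NULL, 0, "normal")
  expect_equal(as.matrix(projection_matrix(mfull, 1)),
               diag(gc$cell_counts[2]))
})

test_that("edge fractions follow the linear interpolant exactly", {
  gc <- build_grid_complex(c(3, 2, 2), 1)
  # values so that the first x-edge has endpoints -a, +a
  pv <- c(-0.3, 0.3, 1, rep(1, 9))
  expect_equal(fractional_measure(gc, 1, 1, pv, isovalue = 0), 0.5)
  pv2 <- c(-0.3, 0.9, 1, rep(1, 9))
  expect_equal(fractional_measure(gc, 1, 1, pv2, isovalue = 0), 0.25)
  # fully inside cell
  expect_equal(fractional_measure(gc, 3, 1, rep(-1, 12), isovalue = 0), 1)
})

test_that("face and cube fractions agree with a dense quadrature oracle", {
  gc <- build_grid_complex(c(2, 2, 2), 1)
  corner_vals <- function(vals) vals[hodgecube:::.cell_vertices(gc, 3)[1, ]]
  # face (-1,-1,-1,+1): oracle by dense bilinear sampling
  face_corners <- c(-1, -1, -1, 1)
  g <- seq(0.0005, 0.9995, length.out = 1000)
  G <- expand.grid(a = g, b = g)
  bil <- with(G, face_corners[1] * (1 - a) * (1 - b) +
                face_corners[2] * a * (1 - b) +
                face_corners[3] * (1 - a) * b + face_corners[4] * a * b)
  oracle <- mean(bil <= 0)
  got <- hodgecube:::.frac_from_corners(matrix(face_corners, 1), 2L, depth = 7)
  expect_lt(abs(got - oracle), 1e-3)
  # the default depth is coarser but converges to the same value
  got4 <- hodgecube:::.frac_from_corners(matrix(face_corners, 1), 2L, depth = 4)
  expect_lt(abs(got4 - oracle), 1e-2)
  # trilinear cube fraction against an independent midpoint oracle
  set.seed(9)
  for (i in 1:5) {
    cv <- runif(8, -1, 1)
    got3 <- hodgecube:::.frac_from_corners(matrix(cv, 1), 3L, depth = 6)
    gg <- seq(1 / 54, 1 - 1 / 54, length.out = 27)
    GG <- expand.grid(x = gg, y = gg, z = gg)
    tri <- with(GG, cv[1] * (1 - x) * (1 - y) * (1 - z) + cv[2] * x * (1 - y) * (1 - z) +
                  cv[3] * (1 - x) * y * (1 - z) + cv[4] * x * y * (1 - z) +
                  cv[5] * (1 - x) * (1 - y) * z + cv[6] * x * (1 - y) * z +
                  cv[7] * (1 - x) * y * z + cv[8] * x * y * z)
    expect_lt(abs(got3 - mean(tri <= 0)), 5e-3)
  }
})

test_that("hodge star entries implement the boundary-adjusted volume ratios", {
  gc <- build_grid_complex(c(3, 3, 3), 1)
  # fully inside: interior entries are spacing^(3-2k)
  pv <- perturb_values(rep(-1, 27), 0, 1)
  dv <- perturb_values(rep(-1, 8), 0, 1)
  m <- classify_support(gc, pv, dv, 0, "normal")
  for (k in 0:3) {
    s <- hodge_star(gc, k, m, pv, dv, 0)
    expect_true(all(abs(s - 1) < 1e-12))  # spacing 1
  }
  # an edge half inside under the normal condition gets entry 2
  gc2 <- build_grid_complex(c(3, 2, 2), 1)
  pv2 <- perturb_values(c(-0.3, 0.3, 1, rep(1, 9)), 0, 1)
  m2 <- classify_support(gc2, pv2, NULL, 0, "normal")
  s1 <- hodge_star(gc2, 1, m2, pv2, NULL, 0)
  e_pos <- match(1, m2$idx[[2]])  # first x-edge is grid edge 1
  expect_equal(as.numeric(s1[e_pos]), 2)
  # tangential stars on fully-inside interior dual cells equal the interior
  # value (grid-boundary cells have clipped dual volumes)
  mt <- classify_support(gc, pv, dv, 0, "tangential")
  st <- hodge_star(gc, 1, mt, pv, dv, 0, bc = "tangential")
  cc <- hodgecube:::.cell_cubes(gc, 1)[mt$idx[[2]], , drop = FALSE]
  interior <- rowSums(cc > 0) == 4
  expect_true(any(interior))
  expect_true(all(abs(st[interior] - 1) < 1e-12))
  # all stars positive and bounded by spacing^(3-2k)/floor
  fb <- sdf_primitive("four_ball_model", edge = 3, radius = 1)
  gcf <- centered_grid(15, 0.5)
  pvf <- perturb_values(sample_field(fb, gcf), 0.2, 0.5)
  dvf <- perturb_values(sample_field(fb, gcf, "dual_points"), 0.2, 0.5)
  mf <- classify_support(gcf, pvf, dvf, 0.2, "normal")
  for (k in 0:3) {
    s <- hodge_star(gcf, k, mf, pvf, dvf, 0.2)
    expect_true(all(s > 0))
    expect_true(all(s <= 0.5^(3 - 2 * k) / 1e-5 + 1e-9))
  }
})

test_that("sliver closing fills enclosed exterior points and nothing else", {
  gc <- centered_grid(9, 1)
  # an isolated outside vertex at the center of an inside block
  pv <- rep(-1, gc$cell_counts[1])
  centre <- hodgecube:::.lin_index(5, 5, 5, c(9, 9, 9))
  pv[centre] <- 0.5
  out <- close_slivers(pv, gc$counts, isovalue = 0, spacing = 1)
  expect_lt(out[centre], 0)
  # a resolvable cavity (3x3x3 outside block) is untouched
  pv2 <- rep(-1, gc$cell_counts[1])
  ijk <- hodgecube:::.lattice_grid(c(9, 9, 9))
  blk <- ijk[, 1] %in% 4:6 & ijk[, 2] %in% 4:6 & ijk[, 3] %in% 4:6
  pv2[blk] <- 0.5
  expect_identical(close_slivers(pv2, gc$counts, 0, 1), pv2)
})
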