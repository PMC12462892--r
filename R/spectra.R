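# Eigenvalue extraction, Betti numbers from Laplacian kernels, and the
# T/C/N singular-spectrum split.

# exact rank of a sparse +/-1 incidence matrix over GF(p); p = 46337 is the
# largest prime below 2^15.5 so modular products stay well inside 64 bits.
# Cubical complexes embedded in R^3 are torsion-free, so the finite-field
# rank equals the real rank.
rank_incidence <- function(M, p = 46337L) {
  M <- methods::as(methods::as(M, "CsparseMatrix"), "generalMatrix")
  if (nrow(M) == 0L || ncol(M) == 0L) return(0L)
  # eliminate on the smaller dimension
  if (nrow(M) < ncol(M)) M <- Matrix::t(M)
  .rank_ff_cpp(dim(M), M@i, M@p, M@x, as.integer(p))
}

# power-iteration estimate of the largest eigenvalue (deterministic start)
.lambda_max_estimate <- function(L, iters = 30) {
  n <- nrow(L)
  if (n == 0L) return(0)
  x <- sin(seq_len(n)); x <- x / sqrt(sum(x^2))
  lam <- 0
  for (i in seq_len(iters)) {
    y <- as.numeric(L %*% x)
    ny <- sqrt(sum(y^2))
    if (ny == 0) return(0)
    lam <- ny; x <- y / ny
  }
  lam
}

.zero_threshold <- function(lmax, tol_abs = 1e-8, tol_rel = 1e-6) {
  tol_abs + tol_rel * lmax
}

#' Smallest eigenvalues of a symmetric PSD operator
#'
#' Dense solve below `dense_cutoff` unknowns, ARPACK shift-invert above
#' (Cholesky factorization of `L + sigma I`, deterministic start vector).
#' Eigenvalues are counted as zero below the threshold
#' `1e-8 + 1e-6 * lambda_max_estimate`.
#'
#' @param L symmetric positive semidefinite sparse matrix.
#' @param m number of smallest eigenvalues requested.
#' @param tol_abs,tol_rel zero-counting threshold parameters.
#' @param dense_cutoff dense-solver size threshold.
#' @return a `spectral_summary`: list with `values` (ascending, length <=
#'   m), `n_zero`, `lambda1` (first nonzero, NA when none), `threshold`,
#'   `n` (operator size) and `ambiguous` (TRUE when an eigenvalue falls
#'   within a decade of the threshold).
#' @export
smallest_spectrum <- function(L, m = 6, tol_abs = 1e-8, tol_rel = 1e-6,
                              dense_cutoff = 2000) {
  n <- nrow(L)
  if (n == 0L)
    return(structure(list(values = numeric(0), n_zero = 0L, lambda1 = NA_real_,
                          threshold = NA_real_, n = 0L, ambiguous = FALSE),
                     class = "spectral_summary"))
  m <- min(m, n)
  if (n <= dense_cutoff) {
    ev <- eigen(as.matrix(L), symmetric = TRUE, only.values = TRUE)$values
    lmax <- max(abs(ev))
    vals <- sort(ev)[seq_len(m)]
  } else {
    lmax <- .lambda_max_estimate(L)
    vals <- .arpack_smallest(L, m, lmax)
  }
  thr <- .zero_threshold(lmax, tol_abs, tol_rel)
  n_zero <- sum(vals < thr)
  nz <- vals[vals >= thr]
  ambiguous <- any(vals > 0.1 * thr & vals < 10 * thr)
  structure(list(values = vals, n_zero = n_zero,
                 lambda1 = if (length(nz)) nz[1] else NA_real_,
                 threshold = thr, n = n, ambiguous = ambiguous),
            class = "spectral_summary")
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat("spectral summary: n =", x$n, " zero multiplicity =", x$n_zero,
      " lambda1 =", format(x$lambda1), "\n")
  if (length(x$values))
    cat("  smallest:", paste(format(x$values, digits = 4), collapse = " "),
        "\n")
  invisible(x)
}

# m smallest eigenvalues via ARPACK shift-invert on (L + sigma I)^{-1}
.arpack_smallest <- function(L, m, lmax, maxiter = 10000) {
  n <- nrow(L)
  sigma <- max(1e-12, 1e-8 * lmax)
  A <- methods::as(L + sigma * Matrix::Diagonal(n), "CsparseMatrix")
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE, perm = TRUE)
  fn <- function(x, extra) as.numeric(Matrix::solve(ch, x))
  ncv <- min(n, max(4 * m + 5, 20))
  start <- sin(seq_len(n))
  res <- igraph::arpack(fn, options = list(n = n, nev = m, ncv = ncv,
                                           which = "LM", maxiter = maxiter,
                                           start = start),
                        sym = TRUE)
  mu <- res$values
  sort(1 / mu - sigma)[seq_len(m)]
}

# ---- Betti numbers -----------------------------------------------------------

# rank of a restricted degree-0 differential (edges x vertices with possible
# single-endpoint rows) via graph components: kernel vectors are constant on
# components of the both-endpoints-kept subgraph and vanish on components
# anchored by a half-edge.
.rank_d0_graph <- function(D) {
  nv <- ncol(D)
  if (nv == 0L) return(list(rank = 0L, n_components = 0L, n_free = 0L))
  M <- methods::as(methods::as(D, "CsparseMatrix"), "generalMatrix")
  tm <- Matrix::t(M)  # vertices x edges; column j = endpoints of edge j
  ptr <- tm@p; rows <- tm@i + 1L
  deg <- diff(ptr)
  both <- which(deg == 2L)
  anchored_v <- rows[ptr[which(deg == 1L)] + 1L]
  el <- cbind(rows[ptr[both] + 1L], rows[ptr[both] + 2L])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nv - igraph::vcount(g)))
  comp <- igraph::components(g)
  anchored_comp <- unique(comp$membership[anchored_v])
  n_free <- comp$no - length(anchored_comp)
  list(rank = nv - n_free, n_components = comp$no, n_free = n_free)
}

#' Betti numbers of a sublevel-set manifold from Laplacian kernels
#'
#' Under the normal boundary condition the kernel dimension of the degree-k
#' Laplacian equals the Betti number `beta_{3-k}` of the manifold:
#' `beta0 = dim ker L_{3,n}` (connected components),
#' `beta1 = dim ker L_{2,n}` (tunnels),
#' `beta2 = dim ker L_{1,n}` (enclosed cavities).
#'
#' Kernel dimensions are computed exactly by default (`method = "rank"`)
#' using `dim ker L_k = N_k - rank D_k - rank D_{k-1}` with sparse ranks over
#' GF(p); the spectra of BIG and Hodge variants share these kernels.
#' `method = "eigen"` instead counts numerically zero eigenvalues of the BIG
#' Laplacians (threshold policy of [smallest_spectrum()]) and is the
#' cross-checked slower path.
#'
#' @param bundle a [laplacian_bundle()] with `bc = "normal"`.
#' @param method `"rank"` (exact) or `"eigen"`.
#' @return named integer vector `c(beta0, beta1, beta2)`.
#' @export
betti_numbers <- function(bundle, method = c("rank", "eigen")) {
  method <- match.arg(method)
  stopifnot(inherits(bundle, "laplacian_bundle"))
  if (bundle$bc != "normal")
    stop("Betti numbers beta_{3-k} require the normal boundary condition")
  if (method == "rank") {
    D <- bundle$D
    n_kept <- bundle$mask$n_kept
    r0 <- .rank_d0_graph(D[[1]])$rank
    # rank(D2) via the dual-graph analog: t(D2) has cube columns
    r2 <- .rank_d0_graph(Matrix::t(D[[3]]))$rank
    r1 <- rank_incidence(D[[2]])
    beta0 <- n_kept[4] - r2
    beta1 <- n_kept[3] - r2 - r1
    beta2 <- n_kept[2] - r1 - r0
  } else {
    count0 <- function(L, guess) {
      if (nrow(L) == 0L) return(0L)
      s <- smallest_spectrum(L, m = min(nrow(L), guess + 5L))
      if (s$n_zero > guess)  # request more until the zero cluster is resolved
        s <- smallest_spectrum(L, m = min(nrow(L), s$n_zero + 5L))
      s$n_zero
    }
    beta0 <- count0(bundle$L[[4]], 8L)
    beta1 <- count0(bundle$L[[3]], 8L)
    beta2 <- count0(bundle$L[[2]], 8L)
  }
  c(beta0 = as.integer(beta0), beta1 = as.integer(beta1),
    beta2 = as.integer(beta2))
}

#' Connected components of kept 3-cells (union-find oracle)
#'
#' Counts components of the dual adjacency graph over kept 3-cells, two cubes
#' being adjacent when their shared face is kept.  Used as an independent
#' combinatorial check on `beta0`.
#'
#' @param bundle a normal-bc [laplacian_bundle()].
#' @return list with `no` (component count) and `membership` over kept cubes.
#' @export
component_count <- function(bundle) {
  D2 <- methods::as(methods::as(bundle$D[[3]], "CsparseMatrix"),
                    "generalMatrix")
  nc <- nrow(D2)
  ptr <- D2@p; rows <- D2@i + 1L   # column = face, rows = incident cubes
  deg <- diff(ptr)
  both <- which(deg == 2L)
  el <- cbind(rows[ptr[both] + 1L], rows[ptr[both] + 2L])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nc - igraph::vcount(g)))
  comp <- igraph::components(g)
  list(no = comp$no, membership = comp$membership)
}

# ---- T/C/N split -------------------------------------------------------------

#' T/C/N singular-spectrum split of the normal-bc differentials
#'
#' The full spectra of all four normal-condition Laplacians decompose into
#' the squared nonzero singular values of the three normalized differentials:
#' `N` from `Dbar_0` (gradients of normal scalar fields), `C` from `Dbar_1`
#' (curls of tangential curl fields) and `T` from `Dbar_2` (gradients of
#' tangential scalar fields; tangential 0-forms live on the dual grid, whose
#' gradient corresponds to the primal degree-2 differential under the
#' primal-normal/dual-tangential duality).
#'
#' Dense SVD; intended for moderate problem sizes.  Use
#' [spectral_curves()] for the sparse first-eigenvalue path.
#'
#' @param D list of three (normalized) restricted differentials under the
#'   normal condition.
#' @param tol singular values below `tol * max(sv)` count as zero.
#' @return a `tnc_split`: list of ascending squared singular values `T`,
#'   `C`, `N` and the leading entries `lambda1T`, `lambda1C`, `lambda1N`
#'   (NA when the family is empty).
#' @export
tnc_split <- function(D, tol = 1e-10) {
  sq <- function(M) {
    if (nrow(M) == 0L || ncol(M) == 0L) return(numeric(0))
    sv <- svd(as.matrix(M), nu = 0, nv = 0)$d
    sv <- sv[sv > tol * max(sv, 1)]
    sort(sv^2)
  }
  Nv <- sq(D[[1]]); Cv <- sq(D[[2]]); Tv <- sq(D[[3]])
  first <- function(v) if (length(v)) v[1] else NA_real_
  structure(list(T = Tv, C = Cv, N = Nv,
                 lambda1T = first(Tv), lambda1C = first(Cv),
                 lambda1N = first(Nv)),
            class = "tnc_split")
}

#' @export
print.tnc_split <- function(x, ...) {
  cat("T/C/N split: |T| =", length(x$T), " |C| =", length(x$C),
      " |N| =", length(x$N), "\n")
  cat("  lambda1: T =", format(x$lambda1T), " C =", format(x$lambda1C),
      " N =", format(x$lambda1N), "\n")
  invisible(x)
}

# first nonzero eigenvalues lambda1T / lambda1C / lambda1N from the sparse
# normal-bc bundle, using kernel dimensions known exactly from ranks:
#   lambda1N: smallest nonzero eigenvalue of L0 (all nonzeros are N),
#   lambda1T: smallest nonzero eigenvalue of L3 (all nonzeros are T),
#   lambda1C: from L2 = t(D2) D2 + D1 t(D1); nonzero eigenvectors split into
#     the C family (image of D1, where D2 v = 0) and the T family (image of
#     t(D2), where t(D1) v = 0); classify by comparing residual norms.
.lambda1_tnc <- function(bundle, betti = NULL, nev_c = 12, dense_cutoff = 2000,
                         which = c("T", "C", "N")) {
  D <- bundle$D
  first_nonzero <- function(L, kernel_dim) {
    if (nrow(L) == 0L) return(NA_real_)
    m <- min(nrow(L), kernel_dim + 3L)
    s <- smallest_spectrum(L, m = m, dense_cutoff = dense_cutoff)
    nz <- s$values[s$values >= s$threshold]
    if (length(nz)) nz[1] else NA_real_
  }
  lamN <- lamT <- lamC <- NA_real_
  if ("N" %in% which) {
    g0 <- .rank_d0_graph(D[[1]])
    lamN <- first_nonzero(bundle$L[[1]], g0$n_free)
  }
  g3 <- .rank_d0_graph(Matrix::t(D[[3]]))
  if ("T" %in% which)
    lamT <- first_nonzero(bundle$L[[4]], g3$n_free)
  # lambda1C from L2
  L2 <- bundle$L[[3]]
  if ("C" %in% which && nrow(L2) > 0L) {
    beta1 <- if (!is.null(betti)) betti["beta1"] else {
      r1 <- rank_incidence(D[[2]])
      as.integer(nrow(L2) - g3$rank - r1)
    }
    m <- min(nrow(L2), beta1 + nev_c)
    repeat {
      if (nrow(L2) <= dense_cutoff) {
        es <- eigen(as.matrix(L2), symmetric = TRUE)
        ord <- order(es$values)[seq_len(m)]
        vals <- es$values[ord]; vecs <- es$vectors[, ord, drop = FALSE]
        lmax <- max(abs(es$values))
      } else {
        lmax <- .lambda_max_estimate(L2)
        sigma <- max(1e-12, 1e-8 * lmax)
        A <- methods::as(L2 + sigma * Matrix::Diagonal(nrow(L2)),
                         "CsparseMatrix")
        ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE,
                               perm = TRUE)
        fn <- function(x, extra) as.numeric(Matrix::solve(ch, x))
        res <- igraph::arpack(fn, options = list(
          n = nrow(L2), nev = m, ncv = min(nrow(L2), max(4 * m + 5, 20)),
          which = "LM", maxiter = 10000, start = sin(seq_len(nrow(L2)))),
          sym = TRUE)
        ord <- order(1 / res$values)
        vals <- (1 / res$values - sigma)[ord]
        vecs <- res$vectors[, ord, drop = FALSE]
      }
      thr <- .zero_threshold(lmax)
      nz <- which(vals >= thr)
      if (length(nz)) {
        nC <- vapply(nz, function(j) {
          v <- vecs[, j]
          sum(as.numeric(Matrix::t(D[[2]]) %*% v)^2) >
            sum(as.numeric(D[[3]] %*% v)^2)
        }, logical(1))
        if (any(nC)) { lamC <- vals[nz[nC][1]]; break }
      }
      if (m >= nrow(L2)) break
      m <- min(nrow(L2), 2L * m)   # widen the window until a C value appears
    }
  }
  c(lambda1T = as.numeric(lamT), lambda1C = as.numeric(lamC),
    lambda1N = as.numeric(lamN))
}

#' Betti and first-eigenvalue curves along a level-set filtration
#'
#' For each isovalue (treated independently: the 0-persistent case) the
#' normal-support BIG (or Hodge) Laplacians are assembled and the row
#' `(beta0, beta1, beta2, lambda1T, lambda1C, lambda1N)` is recorded.
#' Discontinuities in the curves mark topological transitions of the
#' sublevel sets; the monotone trends between them are geometric.
#'
#' @param field a [scalar_field()].
#' @param complex grid complex.
#' @param isovalues strictly increasing isovalues.
#' @param variant `"big"` or `"hodge"`.
#' @param eigenvalues which first-eigenvalue families to compute: `TRUE`
#'   (all of T, C, N), `FALSE` (none; Betti numbers only, much faster) or a
#'   character subset such as `c("T", "C")`.  The C family is the most
#'   expensive (it works on the degree-2 operator).
#' @param check_clearance warn when the sublevel set touches the grid
#'   boundary.
#' @return a data.frame of class `spectral_curves` with one row per isovalue.
#' @export
spectral_curves <- function(field, complex, isovalues,
                            variant = c("big", "hodge"),
                            eigenvalues = TRUE, check_clearance = TRUE) {
  variant <- match.arg(variant)
  which_lam <- if (isTRUE(eigenvalues)) c("T", "C", "N")
               else if (is.character(eigenvalues)) eigenvalues
               else character(0)
  if (any(diff(isovalues) <= 0)) stop("isovalues must be strictly increasing")
  pv <- sample_field(field, complex, "primal_vertices")
  dv <- if (variant == "hodge") sample_field(field, complex, "dual_points")
        else NULL
  rows <- lapply(isovalues, function(c0) {
    if (check_clearance)
      check_grid_clearance(complex, perturb_values(pv, c0, complex$spacing), c0)
    bundle <- laplacian_bundle(complex, isovalue = c0, bc = "normal",
                               variant = variant, primal_values = pv,
                               dual_values = dv)
    if (bundle$mask$n_kept[1] == 0) {
      warning("empty support at isovalue ", format(c0))
      return(data.frame(isovalue = c0, beta0 = 0L, beta1 = 0L, beta2 = 0L,
                        lambda1T = NA_real_, lambda1C = NA_real_,
                        lambda1N = NA_real_))
    }
    b <- betti_numbers(bundle)
    lam <- if (length(which_lam)) .lambda1_tnc(bundle, betti = b,
                                               which = which_lam)
           else c(lambda1T = NA_real_, lambda1C = NA_real_,
                  lambda1N = NA_real_)
    data.frame(isovalue = c0, beta0 = b["beta0"], beta1 = b["beta1"],
               beta2 = b["beta2"], lambda1T = lam["lambda1T"],
               lambda1C = lam["lambda1C"], lambda1N = lam["lambda1N"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("spectral_curves", "data.frame")
  out
}

#' Plot spectral curves
#'
#' Two-panel base-graphics plot: Betti numbers (step curves) and the first
#' nonzero eigenvalues on a log scale, against the isovalue.
#'
#' @param x a [spectral_curves()] result.
#' @param ... unused.
#' @export
plot.spectral_curves <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(x$isovalue, cbind(x$beta0, x$beta1, x$beta2),
                    type = "s", lty = 1, lwd = 2, col = c(1, 2, 4),
                    xlab = "isovalue", ylab = "Betti number")
  graphics::legend("topright", c(expression(beta[0]), expression(beta[1]),
                                 expression(beta[2])),
                   col = c(1, 2, 4), lty = 1, lwd = 2, bty = "n")
  lam <- cbind(x$lambda1T, x$lambda1C, x$lambda1N)
  if (any(is.finite(lam))) {
    graphics::matplot(x$isovalue, lam, type = "l", lty = 1, lwd = 2,
                      col = c(1, 2, 4), log = "y", xlab = "isovalue",
                      ylab = expression(lambda[1]))
    graphics::legend("topright",
                     c(expression(lambda[1]^T), expression(lambda[1]^C),
                       expression(lambda[1]^N)),
                     col = c(1, 2, 4), lty = 1, lwd = 2, bty = "n")
  }
  invisible(x)
}
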