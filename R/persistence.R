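# Filtration of normal-support sub-complexes, discrete harmonic extension,
# and persistent Hodge / BIG Laplacians.

#' Build a nested filtration of normal-support sub-complexes
#'
#' Samples the field once, then classifies the normal support at every
#' isovalue.  Sublevel sets are nested, so the supports are nested at every
#' degree (verified); each level carries the kept-cell index maps used by the
#' persistent operators.
#'
#' @param complex grid complex.
#' @param field a [scalar_field()].
#' @param isovalues strictly increasing isovalues `c_1 < ... < c_s`.
#' @param need_dual also sample dual points (required for Hodge-variant
#'   persistent operators).
#' @param regularize apply [close_slivers()] per level (default TRUE); the
#'   flip rule is monotone in the isovalue so nesting is preserved.
#' @return a `filtration` object.
#' @export
build_filtration <- function(complex, field, isovalues, need_dual = TRUE,
                             regularize = TRUE) {
  if (any(diff(isovalues) <= 0)) stop("isovalues must be strictly increasing")
  pv <- sample_field(field, complex, "primal_vertices")
  dv <- if (need_dual) sample_field(field, complex, "dual_points") else NULL
  masks <- lapply(isovalues, function(c0) {
    pvp <- perturb_values(pv, c0, complex$spacing)
    if (regularize)
      pvp <- close_slivers(pvp, complex$counts, c0, complex$spacing)
    dvp <- if (!is.null(dv)) perturb_values(dv, c0, complex$spacing) else NULL
    classify_support(complex, pvp, dvp, c0, "normal")
  })
  # nesting check
  for (l in seq_along(masks)[-1])
    for (k in 1:4)
      if (any(masks[[l - 1]]$keep[[k]] & !masks[[l]]$keep[[k]]))
        stop("supports are not nested; the field evaluator is inconsistent")
  D_full <- lapply(0:2, function(k) incidence_matrix(complex, k))
  structure(list(complex = complex, isovalues = isovalues,
                 primal_values = pv, dual_values = dv,
                 masks = masks, D_full = D_full),
            class = "filtration")
}

#' @export
print.filtration <- function(x, ...) {
  cat("filtration:", length(x$isovalues), "levels, isovalues in [",
      format(min(x$isovalues)), ",", format(max(x$isovalues)), "]\n")
  kept <- t(vapply(x$masks, function(m) m$n_kept, numeric(4)))
  colnames(kept) <- paste0("k", 0:3)
  print(utils::head(cbind(isovalue = x$isovalues, kept), 10))
  invisible(x)
}

# per-level stars (normal bc) over kept cells; identity for the big variant
.level_stars <- function(filt, l, variant) {
  gc <- filt$complex
  mask <- filt$masks[[l]]
  if (variant == "big") {
    lapply(0:3, function(k) rep(1, mask$n_kept[k + 1]))
  } else {
    c0 <- filt$isovalues[l]
    pv <- close_slivers(perturb_values(filt$primal_values, c0, gc$spacing),
                        gc$counts, c0, gc$spacing)
    dv <- if (!is.null(filt$dual_values))
      perturb_values(filt$dual_values, c0, gc$spacing) else NULL
    lapply(0:3, function(k)
      as.numeric(hodge_star(gc, k, mask, pv, dv, c0)))
  }
}

# minimum-norm least-squares solve via SVD with relative tolerance
.pinv_mult <- function(A, B, rtol = 1e-10) {
  if (nrow(A) == 0L) return(matrix(0, 0, ncol(B)))
  s <- svd(A)
  keep <- s$d > rtol * max(s$d, .Machine$double.eps)
  if (!any(keep)) return(matrix(0, ncol(A), ncol(B)))
  s$v[, keep, drop = FALSE] %*%
    ((t(s$u[, keep, drop = FALSE]) %*% B) / s$d[keep])
}

#' Discrete harmonic extension operator between filtration levels
#'
#' Builds the linear map `I_{l,p}` sending a discrete k-form on the level-l
#' sub-complex to one on level l+p.  Rows for cells already in the level-l
#' complex act as the identity (rescaled by the star ratio of shared cells
#' for the Hodge variant); rows for newly added k-cells carry `d zeta` where
#' the potential `zeta` on new (k-1)-cells solves the harmonic system driven
#' by the boundary codifferential of the input form (minimum-norm
#' least-squares when the difference region carries topology).  At k = 0 the
#' extension fills new vertex values by the degree-0 Laplace solve with
#' Dirichlet data from the level-l vertices.
#'
#' @param filt a [build_filtration()] object.
#' @param l source level (1-based).
#' @param p persistence (levels forward; `l + p` must be a valid level).
#' @param k form degree 0..3.
#' @param variant `"big"` or `"hodge"`.
#' @param rtol relative singular-value tolerance of the interior solve.
#' @return list with the dense operator `I` (`N_k(l+p) x N_k(l)`), the index
#'   maps and diagnostics (`n_new`, `n_unknown`).
#' @export
extension_operator <- function(filt, l, p, k, variant = c("big", "hodge"),
                               rtol = 1e-10) {
  variant <- match.arg(variant)
  stopifnot(inherits(filt, "filtration"), k %in% 0:3,
            l >= 1, p >= 0, l + p <= length(filt$isovalues))
  idx_l <- filt$masks[[l]]$idx
  idx_p <- filt$masks[[l + p]]$idx
  nl <- length(idx_l[[k + 1]]); np <- length(idx_p[[k + 1]])
  pos_old <- match(idx_l[[k + 1]], idx_p[[k + 1]])
  I <- matrix(0, np, nl)
  diag_scale <- rep(1, nl)
  if (variant == "hodge") {
    Sl <- .level_stars(filt, l, variant)[[k + 1]]
    Sp <- .level_stars(filt, l + p, variant)[[k + 1]]
    diag_scale <- Sl / Sp[pos_old]   # identity up to boundary star rescaling
  }
  I[cbind(pos_old, seq_len(nl))] <- diag_scale
  if (p == 0L || nl == 0L)
    return(list(I = I, pos_old = pos_old, n_new = np - nl, n_unknown = 0L,
                k = k, l = l, p = p, variant = variant))
  new_k <- setdiff(idx_p[[k + 1]], idx_l[[k + 1]])      # grid ids of new k-cells
  if (!length(new_k))
    return(list(I = I, pos_old = pos_old, n_new = 0L, n_unknown = 0L,
                k = k, l = l, p = p, variant = variant))
  stars_p <- .level_stars(filt, l + p, variant)
  if (k == 0L) {
    # Dirichlet problem on new vertices over all level-(l+p) edges touching them
    U <- new_k
    E <- filt$D_full[[1]]
    rows_touch <- which(Matrix::rowSums(abs(E[, U, drop = FALSE])) > 0)
    rows_use <- intersect(rows_touch, idx_p[[2]])
    S1 <- stars_p[[2]][match(rows_use, idx_p[[2]])]
    DU <- E[rows_use, U, drop = FALSE]
    DB <- E[rows_use, idx_l[[1]], drop = FALSE]
    Lt <- as.matrix(Matrix::t(DU) %*% (S1 * DU))
    rhs <- -as.matrix(Matrix::t(DU) %*% (S1 * (DB %*% diag(diag_scale, nl, nl))))
    Z <- .pinv_mult(Lt, rhs, rtol)
    I[match(U, idx_p[[1]]), ] <- Z
    return(list(I = I, pos_old = pos_old, n_new = length(U),
                n_unknown = length(U), k = k, l = l, p = p,
                variant = variant))
  }
  # k >= 1: potential zeta on new (k-1)-cells
  U <- setdiff(idx_p[[k]], idx_l[[k]])                  # new (k-1)-cells
  Dk1 <- filt$D_full[[k]]                               # k-cells x (k-1)-cells
  A <- new_k                                            # new k-cells
  if (!length(U)) {
    # nothing to solve: new k-cells (if any) get zero, matching d(zeta)=0
    return(list(I = I, pos_old = pos_old, n_new = length(A), n_unknown = 0L,
                k = k, l = l, p = p, variant = variant))
  }
  D_AU <- Dk1[A, U, drop = FALSE]
  # boundary k-cells of K_l: level-l cells incident to an unknown (k-1)-cell
  D_BU <- Dk1[idx_l[[k + 1]], U, drop = FALSE]
  Sk_A <- stars_p[[k + 1]][match(A, idx_p[[k + 1]])]
  Sk_B <- stars_p[[k + 1]][match(idx_l[[k + 1]], idx_p[[k + 1]])]
  Lt <- as.matrix(Matrix::t(D_AU) %*% (Sk_A * D_AU))
  if (k >= 2L) {
    # lower-order term of the difference-complex Laplacian (gauge fixing)
    V <- setdiff(idx_p[[k - 1]], idx_l[[k - 1]])
    if (length(V)) {
      D_UV <- filt$D_full[[k - 1]][U, V, drop = FALSE]
      Sk1_U <- stars_p[[k]][match(U, idx_p[[k]])]
      Sk2_V <- stars_p[[k - 1]][match(V, idx_p[[k - 1]])]
      M <- (Sk1_U * D_UV) %*% Matrix::Diagonal(x = 1 / Sk2_V)
      Lt <- Lt + as.matrix(M %*% Matrix::t(Sk1_U * D_UV))
    }
  }
  # right-hand side: - t(D_BU) S_k omega on boundary cells of K_l
  rhs <- -as.matrix(Matrix::t(D_BU) %*% (Sk_B * diag(diag_scale, nl, nl)))
  Z <- .pinv_mult(Lt, rhs, rtol)                        # zeta per unit input
  I[match(A, idx_p[[k + 1]]), ] <- as.matrix(D_AU %*% Z)
  list(I = I, pos_old = pos_old, n_new = length(A), n_unknown = length(U),
       k = k, l = l, p = p, variant = variant)
}

#' Restriction onto level-l forms
#'
#' The left inverse of the harmonic extension: the level-(l+p) inner-product
#' projection onto the space of harmonic extensions followed by restriction
#' to the level-l sub-complex, realized as `(t(I) S I)^{-1} t(I) S`.
#' Satisfies `R %*% I = Id` on level-l k-forms.
#'
#' @param ext an [extension_operator()] result.
#' @param stars optional level-(l+p) star diagonal for degree k (identity
#'   when omitted: the BIG inner product).
#' @return dense `N_k(l) x N_k(l+p)` matrix.
#' @export
restriction_operator <- function(ext, stars = NULL) {
  I <- ext$I
  S <- if (is.null(stars)) rep(1, nrow(I)) else as.numeric(stars)
  G <- t(I) %*% (S * I)
  solve(G, t(I * S))
}

#' Persistent Hodge / BIG Laplacian
#'
#' Assembles the p-persistent degree-k Laplacian on level-l k-forms: the
#' down-up term passes through the harmonic extension to level l+p
#' (persistent codifferential `delta_{l+p} o I_{l,p}` and its adjoint), the
#' up-down term is the ordinary level-l term.  For `p = 0` the operator
#' equals the ordinary level-l Laplacian.  The returned operator is
#' symmetrized with respect to the level-l inner product.
#'
#' @param filt a [build_filtration()] object.
#' @param l level; @param p persistence; @param k degree 0..3.
#' @param variant `"big"` or `"hodge"`.
#' @return list with `L` (dense symmetric PSD matrix on level-l k-forms),
#'   `extension` (the [extension_operator()] result), `transform`
#'   (`S^{-1/2}` diagonal used for symmetrization) and metadata.
#' @export
persistent_laplacian <- function(filt, l, p, k,
                                 variant = c("big", "hodge")) {
  variant <- match.arg(variant)
  stopifnot(k %in% 0:3)
  idx_l <- filt$masks[[l]]$idx
  idx_p <- filt$masks[[l + p]]$idx
  nl <- length(idx_l[[k + 1]])
  ext <- extension_operator(filt, l, p, k, variant)
  Dl <- lapply(0:2, function(j)
    filt$D_full[[j + 1]][idx_l[[j + 2]], idx_l[[j + 1]], drop = FALSE])
  L <- matrix(0, nl, nl)
  transform <- rep(1, nl)
  if (variant == "big") {
    if (k >= 1L) {
      Dp <- filt$D_full[[k]][idx_p[[k + 1]], idx_p[[k]], drop = FALSE]
      Dt <- t(ext$I) %*% as.matrix(Dp)        # persistent differential
      L <- L + Dt %*% t(Dt)
    }
    if (k <= 2L) {
      Dk <- as.matrix(Dl[[k + 1]])
      L <- L + t(Dk) %*% Dk
    }
    L <- (L + t(L)) / 2
  } else {
    Sl <- .level_stars(filt, l, variant)
    Sp <- .level_stars(filt, l + p, variant)
    Skl <- Sl[[k + 1]]
    if (k >= 1L) {
      Dp <- as.matrix(filt$D_full[[k]][idx_p[[k + 1]], idx_p[[k]],
                                       drop = FALSE])
      Skp <- Sp[[k + 1]]; Sk1p <- Sp[[k]]
      # d-tilde = S_k(l)^{-1} t(I) S_k(l+p) D_{l+p};
      # delta-tilde = S_{k-1}(l+p)^{-1} t(D_{l+p}) S_k(l+p) I
      A <- (1 / Skl) * (t(ext$I) %*% (Skp * Dp))
      B <- (1 / Sk1p) * (t(Dp) %*% (Skp * ext$I))
      L <- L + A %*% B
    }
    if (k <= 2L) {
      Dk <- as.matrix(Dl[[k + 1]])
      Sk1l <- Sl[[k + 2]]
      L <- L + (1 / Skl) * (t(Dk) %*% (Sk1l * Dk))
    }
    transform <- 1 / sqrt(Skl)
    L <- sqrt(Skl) * L %*% diag(transform, nl, nl)
    L <- (L + t(L)) / 2
  }
  list(L = L, extension = ext, transform = transform,
       l = l, p = p, k = k, variant = variant)
}

#' Kernel dimension (persistent Betti number) of a persistent Laplacian
#'
#' Counts numerically zero eigenvalues with the package's threshold policy.
#' At degree k = 3 under the normal condition this is the number of
#' connected components persisting from level l to level l+p.
#'
#' @param filt filtration; @param l,p,k as in [persistent_laplacian()].
#' @param variant `"big"` or `"hodge"`.
#' @return integer kernel dimension.
#' @export
persistent_betti <- function(filt, l, p, k, variant = c("big", "hodge")) {
  pl <- persistent_laplacian(filt, l, p, k, match.arg(variant))
  if (nrow(pl$L) == 0L) return(0L)
  ev <- eigen(pl$L, symmetric = TRUE, only.values = TRUE)$values
  thr <- .zero_threshold(max(abs(ev)))
  as.integer(sum(ev < thr))
}

#' Persistent component count by union-find (oracle)
#'
#' Number of connected components of the level-(l+p) kept-cube adjacency
#' graph that contain at least one level-l kept cube: the combinatorial
#' persistent `beta0` from level l to level l+p.
#'
#' @param filt filtration; @param l level; @param p persistence.
#' @return integer count.
#' @export
persistent_component_count <- function(filt, l, p) {
  idx_p <- filt$masks[[l + p]]$idx
  D2 <- filt$D_full[[3]][idx_p[[4]], idx_p[[3]], drop = FALSE]
  D2 <- methods::as(methods::as(D2, "CsparseMatrix"), "generalMatrix")
  nc <- nrow(D2)
  ptr <- D2@p; rows <- D2@i + 1L
  deg <- diff(ptr)
  both <- which(deg == 2L)
  el <- cbind(rows[ptr[both] + 1L], rows[ptr[both] + 2L])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nc - igraph::vcount(g)))
  comp <- igraph::components(g)
  old_pos <- match(filt$masks[[l]]$idx[[4]], idx_p[[4]])
  length(unique(comp$membership[old_pos]))
}
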