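#' Restricted discrete differentials on a support
#'
#' Restricts the full-grid incidence operators to the kept cells of a support
#' mask: `D_k_bc = P_{k+1} D_k t(P_k)`.  Nilpotency
#' `D_{k+1,bc} %*% D_{k,bc} == 0` is preserved exactly (integer arithmetic).
#'
#' @param complex grid complex.
#' @param mask support mask.
#' @return list of three sparse matrices (degrees 0, 1, 2), each
#'   `kept_{k+1} x kept_k`.
#' @export
restricted_differentials <- function(complex, mask) {
  stopifnot(inherits(complex, "grid_complex"), inherits(mask, "support_mask"))
  lapply(0:2, function(k) {
    D <- incidence_matrix(complex, k)
    D[mask$idx[[k + 2]], mask$idx[[k + 1]], drop = FALSE]
  })
}

#' Assemble a degree-k Hodge or BIG Laplacian
#'
#' The Hodge variant is
#' `L_k = t(D_k) S_{k+1} D_k + S_k D_{k-1} S_{k-1}^{-1} t(D_{k-1}) S_k`,
#' with terms dropped at k = 0 and k = 3 (operators are null outside
#' 0..3).  The BIG (boundary-induced graph) variant replaces every Hodge star
#' by the identity:
#' `L_k = t(D_k) D_k + D_{k-1} t(D_{k-1})`.
#' The raw Hodge operator is nonsymmetric; use [symmetrize_laplacian()] (or
#' `laplacian_bundle()`, which stores the symmetrized form) for eigenanalysis.
#'
#' @param D list of restricted differentials from
#'   [restricted_differentials()].
#' @param k degree 0..3.
#' @param variant `"big"` or `"hodge"`.
#' @param stars for the Hodge variant, a list of four star diagonals
#'   (degrees 0..3) over kept cells.
#' @return sparse symmetric (big) or general (hodge) matrix of size
#'   `kept_k x kept_k`.
#' @export
assemble_laplacian <- function(D, k, variant = c("big", "hodge"),
                               stars = NULL) {
  variant <- match.arg(variant)
  stopifnot(k %in% 0:3)
  nk <- if (k < 3) ncol(D[[k + 1]]) else nrow(D[[3]])
  L <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(nk, nk))
  if (variant == "big") {
    if (k < 3) L <- L + Matrix::crossprod(D[[k + 1]])
    if (k > 0) L <- L + Matrix::tcrossprod(D[[k]])
  } else {
    if (is.null(stars)) stop("hodge variant requires star diagonals")
    Sd <- function(j) Matrix::Diagonal(x = as.numeric(stars[[j + 1]]))
    if (k < 3)
      L <- L + Matrix::t(D[[k + 1]]) %*% Sd(k + 1) %*% D[[k + 1]]
    if (k > 0)
      L <- L + Sd(k) %*% D[[k]] %*%
        Matrix::Diagonal(x = 1 / as.numeric(stars[[k]])) %*%
        Matrix::t(D[[k]]) %*% Sd(k)
  }
  L
}

#' Symmetrize a Laplacian with respect to its Hodge star
#'
#' Returns `Lbar = S^{-1/2} L S^{-1/2}`, whose (ordinary) eigenvalues equal
#' the generalized eigenvalues of `(L, S)`, together with the diagonal
#' transform `S^{-1/2}` mapping symmetrized eigenvectors back
#' (`W = S^{-1/2} Wbar`).
#'
#' @param L square operator.
#' @param S_k star diagonal for degree k (strictly positive).
#' @return list with `L` (symmetrized sparse matrix) and `transform`
#'   (numeric diagonal of `S^{-1/2}`).
#' @export
symmetrize_laplacian <- function(L, S_k) {
  s <- as.numeric(S_k)
  if (any(s <= 0)) stop("nonpositive star diagonal")
  t <- 1 / sqrt(s)
  Td <- Matrix::Diagonal(x = t)
  Ls <- Td %*% L %*% Td
  list(L = Matrix::forceSymmetric((Ls + Matrix::t(Ls)) / 2),
       transform = t)
}

#' Normalized restricted differentials
#'
#' `Dbar_k = S_{k+1}^{1/2} D_k S_k^{-1/2}`; nilpotency of consecutive
#' normalized differentials is preserved and the symmetrized Laplacian
#' satisfies `Lbar_k = t(Dbar_k) Dbar_k + Dbar_{k-1} t(Dbar_{k-1})`.
#'
#' @param D restricted differentials.
#' @param stars list of four star diagonals (degrees 0..3) over kept cells.
#' @return list of three normalized sparse differentials.
#' @export
normalized_differentials <- function(D, stars) {
  lapply(0:2, function(k) {
    Matrix::Diagonal(x = sqrt(as.numeric(stars[[k + 2]]))) %*% D[[k + 1]] %*%
      Matrix::Diagonal(x = 1 / sqrt(as.numeric(stars[[k + 1]])))
  })
}

#' Build the full bundle of Laplacians for one support
#'
#' Convenience constructor: classifies the support at an isovalue, restricts
#' the differentials, computes stars (Hodge variant) and assembles the four
#' degree-wise operators, stored in symmetrized form.
#'
#' @param complex grid complex.
#' @param field a [scalar_field()]; or pass precomputed samples via
#'   `primal_values` / `dual_values`.
#' @param isovalue the isovalue c.
#' @param bc `"normal"` or `"tangential"`.
#' @param variant `"big"` or `"hodge"`.
#' @param primal_values,dual_values optional raw samples (unperturbed).
#' @param depth subdivision depth for fractional volumes (hodge).
#' @param regularize apply [close_slivers()] to the classification samples
#'   (default TRUE); see that help page for what it guards against.
#' @return a `laplacian_bundle`: list with `mask`, `D` (restricted
#'   differentials), `stars` (identity-free for big), `L` (list of four
#'   symmetric operators), `transform` (per-degree back-transforms), plus
#'   grid metadata.
#' @export
laplacian_bundle <- function(complex, field = NULL, isovalue,
                             bc = c("normal", "tangential"),
                             variant = c("big", "hodge"),
                             primal_values = NULL, dual_values = NULL,
                             depth = 4, regularize = TRUE) {
  bc <- match.arg(bc); variant <- match.arg(variant)
  if (is.null(primal_values)) {
    if (is.null(field)) stop("either a field or primal samples are required")
    primal_values <- sample_field(field, complex, "primal_vertices")
  }
  if (is.null(dual_values) && (bc == "tangential" || variant == "hodge")) {
    if (is.null(field)) stop("dual samples required")
    dual_values <- sample_field(field, complex, "dual_points")
  }
  pv <- perturb_values(primal_values, isovalue, complex$spacing)
  dv <- if (!is.null(dual_values))
    perturb_values(dual_values, isovalue, complex$spacing) else NULL
  if (regularize) {
    pv <- close_slivers(pv, complex$counts, isovalue, complex$spacing)
    if (!is.null(dv))
      dv <- close_slivers(dv, complex$counts - 1L, isovalue, complex$spacing)
  }
  mask <- classify_support(complex, pv, dv, isovalue, bc)
  D <- restricted_differentials(complex, mask)
  if (variant == "hodge") {
    stars <- lapply(0:3, function(k)
      hodge_star(complex, k, mask, pv, dv, isovalue, bc = bc, depth = depth))
  } else {
    stars <- lapply(0:3, function(k)
      structure(rep(1, mask$n_kept[k + 1]), k = k, bc = bc,
                spacing = complex$spacing, class = "star_diagonal"))
  }
  L <- vector("list", 4); transform <- vector("list", 4)
  for (k in 0:3) {
    Lk <- assemble_laplacian(D, k, variant, stars)
    if (variant == "hodge") {
      sym <- symmetrize_laplacian(Lk, stars[[k + 1]])
      L[[k + 1]] <- sym$L; transform[[k + 1]] <- sym$transform
    } else {
      L[[k + 1]] <- Matrix::forceSymmetric(Lk)
      transform[[k + 1]] <- rep(1, nrow(Lk))
    }
  }
  structure(list(bc = bc, variant = variant, isovalue = isovalue,
                 spacing = complex$spacing, mask = mask, D = D,
                 stars = stars, L = L, transform = transform),
            class = "laplacian_bundle")
}

#' @export
print.laplacian_bundle <- function(x, ...) {
  cat("laplacian bundle:", x$variant, "variant,", x$bc,
      "bc, isovalue", format(x$isovalue), "\n")
  cat("  unknowns per degree:",
      paste(vapply(x$L, nrow, numeric(1)), collapse = ", "), "\n")
  invisible(x)
}

#' Export an operator as a Matrix Market file
#'
#' @param L sparse matrix (e.g. an entry of a bundle's `L`).
#' @param path output `.mtx` path.
#' @return `path`, invisibly.
#' @export
write_operator_mtx <- function(L, path) {
  Matrix::writeMM(methods::as(methods::as(L, "generalMatrix"), "CsparseMatrix"),
                  path)
  invisible(path)
}
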