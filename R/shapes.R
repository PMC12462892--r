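#' Scalar fields: analytic level-set functions
#'
#' A `scalar_field` wraps a deterministic evaluator mapping an n x 3 matrix of
#' points to n values.  Sublevel sets \{x : f(x) <= c\} of the field are the
#' manifolds analysed throughout the package; raising the isovalue c sweeps
#' the offset filtration.
#'
#' @param evaluator function taking an n x 3 matrix, returning n values.
#' @param kind short label describing the field.
#' @param params named list of shape parameters (metadata only).
#' @return a `scalar_field` object.
#' @export
scalar_field <- function(evaluator, kind = "custom", params = list()) {
  stopifnot(is.function(evaluator))
  structure(list(evaluator = evaluator, kind = kind, params = params),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat("scalar field:", x$kind, "\n")
  if (length(x$params))
    cat("  params:", paste(names(x$params),
                           vapply(x$params, function(p)
                             paste(format(p), collapse = ","), ""),
                           sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Evaluate a scalar field at points
#' @param field a [scalar_field()].
#' @param points n x 3 matrix (or length-3 vector).
#' @return numeric vector of field values.
#' @export
eval_field <- function(field, points) {
  stopifnot(inherits(field, "scalar_field"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  as.numeric(field$evaluator(points))
}

.dist_to <- function(p, center) {
  sqrt((p[, 1] - center[1])^2 + (p[, 2] - center[2])^2 + (p[, 3] - center[3])^2)
}

#' Analytic implicit solids
#'
#' Signed-distance / implicit level-set functions for the demonstration
#' shapes.  `ball` is an exact signed distance.  `union` combines member
#' fields by pointwise minimum (a valid level-set function with the correct
#' sign structure, not an exact distance).  `solid_torus` is the exact torus
#' signed distance.  `genus3_solid` is a rounded box pierced by three parallel
#' cylindrical tunnels (boolean difference via max), a genus-3 handlebody with
#' first Betti number 3.  `four_ball_model` places four balls at the vertices
#' of a regular tetrahedron; its offset filtration merges the components,
#' opens three tunnels and finally traps and fills one cavity.
#'
#' @param kind one of `"ball"`, `"union"`, `"solid_torus"`, `"genus3_solid"`,
#'   `"four_ball_model"`.
#' @param ... shape parameters: `ball`: `center`, `radius`; `union`: `fields`
#'   (list of scalar fields); `solid_torus`: `center`, `major`, `minor`
#'   (torus in the x-y plane); `genus3_solid`: `half_extents`, `tunnel_radius`,
#'   `tunnel_spacing` (tunnels along z at x = -s, 0, s); `four_ball_model`:
#'   `edge`, `radius` (tetrahedron centroid at the origin).
#' @return a [scalar_field()].
#' @examples
#' f <- sdf_primitive("ball", center = c(0, 0, 0), radius = 1)
#' eval_field(f, c(2, 0, 0))  # 1
#' @export
sdf_primitive <- function(kind, ...) {
  args <- list(...)
  switch(kind,
    ball = {
      center <- as.numeric(args$center %||% c(0, 0, 0))
      radius <- args$radius %||% 1
      if (radius <= 0) stop("degenerate parameters: radius must be > 0")
      scalar_field(function(p) .dist_to(p, center) - radius,
                   "ball", list(center = center, radius = radius))
    },
    union = {
      fields <- args$fields
      if (!length(fields)) stop("degenerate parameters: empty union")
      evs <- lapply(fields, function(f) f$evaluator)
      scalar_field(function(p) {
        v <- evs[[1]](p)
        for (e in evs[-1]) v <- pmin(v, e(p))
        v
      }, "union", list(n = length(fields)))
    },
    solid_torus = {
      center <- as.numeric(args$center %||% c(0, 0, 0))
      major <- args$major %||% 2
      minor <- args$minor %||% 0.6
      if (minor <= 0 || major <= minor)
        stop("degenerate parameters: need 0 < minor < major")
      scalar_field(function(p) {
        q <- sweep(p, 2, center)
        sqrt((sqrt(q[, 1]^2 + q[, 2]^2) - major)^2 + q[, 3]^2) - minor
      }, "solid_torus", list(center = center, major = major, minor = minor))
    },
    genus3_solid = {
      he <- as.numeric(args$half_extents %||% c(1.6, 1.0, 0.8))
      tr <- args$tunnel_radius %||% 0.35
      ts <- args$tunnel_spacing %||% 1.0
      if (any(he <= 0) || tr <= 0 || ts <= tr)
        stop("degenerate parameters for genus3_solid")
      # box SDF minus union of three z-axis cylinders through it
      scalar_field(function(p) {
        q <- cbind(abs(p[, 1]) - he[1], abs(p[, 2]) - he[2],
                   abs(p[, 3]) - he[3])
        qp <- pmax(q, 0)
        box <- sqrt(qp[, 1]^2 + qp[, 2]^2 + qp[, 3]^2) +
          pmin(pmax(q[, 1], pmax(q[, 2], q[, 3])), 0)
        cyl <- pmin(sqrt((p[, 1] + ts)^2 + p[, 2]^2),
                    pmin(sqrt(p[, 1]^2 + p[, 2]^2),
                         sqrt((p[, 1] - ts)^2 + p[, 2]^2))) - tr
        pmax(box, -cyl)
      }, "genus3_solid",
      list(half_extents = he, tunnel_radius = tr, tunnel_spacing = ts))
    },
    four_ball_model = {
      edge <- args$edge %||% 3
      radius <- args$radius %||% 1
      if (edge <= 0 || radius <= 0)
        stop("degenerate parameters for four_ball_model")
      centers <- tetrahedron_vertices(edge)
      scalar_field(function(p) {
        v <- .dist_to(p, centers[1, ]) - radius
        for (i in 2:4) v <- pmin(v, .dist_to(p, centers[i, ]) - radius)
        v
      }, "four_ball_model",
      list(edge = edge, radius = radius, centers = centers))
    },
    stop("unknown shape kind: ", kind)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Vertices of a regular tetrahedron
#'
#' Centroid at the origin, given edge length.  Circumradius is
#' `edge * sqrt(3/8)`.
#' @param edge edge length (> 0).
#' @return a 4 x 3 matrix of vertex coordinates.
#' @export
tetrahedron_vertices <- function(edge) {
  stopifnot(edge > 0)
  v <- rbind(c( 1,  1,  1), c( 1, -1, -1), c(-1,  1, -1), c(-1, -1,  1))
  v * (edge / (2 * sqrt(2)))
}

# ---- FRI molecular density ---------------------------------------------------

#' Atom records
#'
#' Minimal atom representation: element symbol, coordinates (Angstrom) and
#' van der Waals radius.
#' @param element character vector of element symbols.
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param radius van der Waals radii; defaults to the built-in Bondi table
#'   looked up by element.
#' @return a data.frame of class `atom_set`.
#' @export
atom_set <- function(element, xyz, radius = NULL) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  element <- as.character(element)
  stopifnot(nrow(xyz) == length(element))
  if (is.null(radius)) radius <- vdw_radius(element)
  if (any(!is.finite(radius)) || any(radius <= 0))
    stop("atom radii must be positive")
  out <- data.frame(element = element, x = xyz[, 1], y = xyz[, 2],
                    z = xyz[, 3], radius = radius,
                    stringsAsFactors = FALSE)
  class(out) <- c("atom_set", "data.frame")
  out
}

#' Bondi van der Waals radii (Angstrom)
#'
#' Radii for the ten supported elements; overridable by passing explicit radii
#' to [atom_set()].
#' @param element character vector of symbols.
#' @return numeric radii.
#' @export
vdw_radius <- function(element) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
           P = 1.80, F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98)
  r <- tab[element]
  if (any(is.na(r)))
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  as.numeric(r)
}

#' Flexibility-rigidity-index (FRI) density field
#'
#' The molecular level-set function: the negative sum of atom-centered
#' Gaussians
#' \deqn{\rho(x, \tau) = -\sum_i \exp(-(\|x - x_i\| / (\tau r_i))^2),}
#' where \eqn{r_i} is the van der Waals radius of atom i and \eqn{\tau} a
#' dimensionless scale.  The field is strictly negative everywhere and tends
#' to 0 at infinity; sublevel sets at isovalues c < 0 are compact molecular
#' manifolds.
#'
#' @param atoms an [atom_set()] (at least one atom).
#' @param tau positive scale factor multiplying the van der Waals radii.
#' @return a [scalar_field()].
#' @examples
#' a <- atom_set("C", c(0, 0, 0))
#' eval_field(fri_density(a, 1), c(0, 0, 0))  # -1
#' @export
fri_density <- function(atoms, tau = 1) {
  if (!inherits(atoms, "atom_set")) stop("'atoms' must be an atom_set")
  if (nrow(atoms) == 0L) stop("empty atom selection")
  if (!is.numeric(tau) || tau <= 0) stop("tau must be > 0")
  ax <- atoms$x; ay <- atoms$y; az <- atoms$z
  w <- (tau * atoms$radius)^2
  scalar_field(function(p) {
    v <- numeric(nrow(p))
    for (i in seq_along(ax)) {
      d2 <- (p[, 1] - ax[i])^2 + (p[, 2] - ay[i])^2 + (p[, 3] - az[i])^2
      v <- v - exp(-d2 / w[i])
    }
    v
  }, "fri_density", list(n_atoms = nrow(atoms), tau = tau))
}

#' Sample a scalar field on a grid complex
#'
#' Evaluates the field at all primal vertices (`site = "primal_vertices"`) or
#' at all 3-cell centers, the dual grid points (`site = "dual_points"`), in
#' cell enumeration order.
#'
#' @param field a [scalar_field()].
#' @param complex a grid complex.
#' @param site `"primal_vertices"` or `"dual_points"`.
#' @return numeric vector (length N_0 or N_3).
#' @export
sample_field <- function(field, complex,
                         site = c("primal_vertices", "dual_points")) {
  site <- match.arg(site)
  pts <- if (site == "primal_vertices") vertex_coordinates(complex)
         else dual_coordinates(complex)
  eval_field(field, pts)
}
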