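# Brute-force oracles shared across tests.

# enumerate all axis-aligned k-cells of a grid by their vertex sets,
# independent of the package's enumeration machinery
brute_cell_count <- function(counts, k) {
  nx <- counts[1]; ny <- counts[2]; nz <- counts[3]
  if (k == 0) return(nx * ny * nz)
  if (k == 1)
    return((nx - 1) * ny * nz + nx * (ny - 1) * nz + nx * ny * (nz - 1))
  if (k == 2)
    return(nx * (ny - 1) * (nz - 1) + (nx - 1) * ny * (nz - 1) +
             (nx - 1) * (ny - 1) * nz)
  (nx - 1) * (ny - 1) * (nz - 1)
}

# dense boundary operator of a single unit cube (degree 2), oriented by
# outward flux: rows = 1 cube, cols = 6 faces via direct surface integrals
brute_rank <- function(M) qr(as.matrix(M))$rank

# Betti numbers of the normal-support complex from dense real ranks
brute_betti <- function(D) {
  r0 <- brute_rank(D[[1]]); r1 <- brute_rank(D[[2]]); r2 <- brute_rank(D[[3]])
  n1 <- ncol(D[[2]]); n2 <- ncol(D[[3]]); n3 <- nrow(D[[3]])
  c(beta0 = n3 - r2, beta1 = n2 - r2 - r1, beta2 = n1 - r1 - r0)
}

# symmetric grid complex centered on the origin
centered_grid <- function(n, spacing) {
  build_grid_complex(rep(n, 3), spacing, origin = rep(-(n - 1) / 2 * spacing, 3))
}

ball_field <- function(r = 1) sdf_primitive("ball", radius = r)
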