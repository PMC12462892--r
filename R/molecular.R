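# Protein-ligand featurization: element-specific FRI densities and
# persistent spectra of the degree-3 normal-support BIG Laplacian.

.protein_elements <- c("C", "N", "O", "S")
.ligand_elements <- c("H", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I")

# normalize element symbols: "CL"/"cl" -> "Cl"
.normalize_element <- function(e) {
  e <- trimws(e)
  ifelse(nchar(e) > 0,
         paste0(toupper(substr(e, 1, 1)), tolower(substr(e, 2, nchar(e)))),
         e)
}

# fallback heuristic: derive element from a PDB atom name
.element_from_name <- function(name) {
  nm <- gsub("[^A-Za-z]", "", name)
  two <- .normalize_element(substr(nm, 1, 2))
  one <- toupper(substr(nm, 1, 1))
  ifelse(two %in% c("Cl", "Br"), two, one)
}

#' Read a protein-ligand complex from structure files
#'
#' Parses the protein from PDB and the ligand from MOL2 or SDF.  Protein
#' atoms are filtered to \{C, N, O, S\} (hydrogens are ignored in proteins);
#' ligand atoms are filtered to the ten supported elements.  Atoms with
#' unrecognized element symbols are skipped with a warning.  Van der Waals
#' radii are attached from the built-in Bondi table.
#'
#' @param protein_path PDB file.
#' @param ligand_path MOL2 (`.mol2`) or SDF (`.sdf`) file.
#' @return list with `protein` and `ligand` [atom_set()]s; each carries the
#'   attribute `n_skipped` (atoms dropped by the element filter).
#' @export
read_structures <- function(protein_path, ligand_path) {
  pdb <- bio3d::read.pdb(protein_path)
  at <- pdb$atom
  elem <- .normalize_element(at$elesy)
  need <- is.na(elem) | elem == ""
  if (any(need)) {
    elem[need] <- .element_from_name(at$elety[need])
    message("element inferred from atom name for ", sum(need),
            " protein atom(s)")
  }
  keep <- elem %in% .protein_elements
  protein <- atom_set(elem[keep], cbind(at$x, at$y, at$z)[keep, , drop = FALSE])
  attr(protein, "n_skipped") <- sum(!keep)
  ext <- tolower(tools::file_ext(ligand_path))
  if (ext == "mol2") {
    m <- bio3d::read.mol2(ligand_path)
    la <- m$atom
    # SYBYL atom types carry the element before the dot (e.g. "C.3", "Cl")
    lelem <- .normalize_element(sub("\\..*$", "", la$elety))
    lxyz <- cbind(la$x, la$y, la$z)
  } else if (ext %in% c("sdf", "sd", "mol")) {
    if (!requireNamespace("ChemmineR", quietly = TRUE))
      stop("reading SDF ligands requires the ChemmineR package")
    sdf <- ChemmineR::read.SDFset(ligand_path)[[1]]
    ab <- ChemmineR::atomblock(sdf)
    lelem <- .normalize_element(gsub("_.*$", "", rownames(ab)))
    lxyz <- ab[, 1:3, drop = FALSE]
  } else stop("unsupported ligand format: ", ligand_path)
  lkeep <- lelem %in% .ligand_elements
  if (any(!lkeep))
    warning(sum(!lkeep), " ligand atom(s) with unsupported element skipped")
  ligand <- atom_set(lelem[lkeep], lxyz[lkeep, , drop = FALSE])
  attr(ligand, "n_skipped") <- sum(!lkeep)
  list(protein = protein, ligand = ligand)
}

#' The 40 element-specific atom pairs
#'
#' All pairs of a protein element in \{C, N, O, S\} with a ligand element in
#' \{H, C, N, O, S, P, F, Cl, Br, I\}, in a fixed documented order
#' (protein-major, ligand order as listed).
#'
#' @return a 40 x 2 character matrix with columns `protein`, `ligand`.
#' @export
element_pairs <- function() {
  out <- cbind(protein = rep(.protein_elements,
                             each = length(.ligand_elements)),
               ligand = rep(.ligand_elements, length(.protein_elements)))
  out
}

#' Select the atoms of one element pair near the binding site
#'
#' Returns the protein atoms of element `pair[1]` lying within `cutoff` of
#' any ligand atom, together with all ligand atoms of element `pair[2]`.
#'
#' @param protein,ligand [atom_set()]s.
#' @param pair length-2 character vector (protein element, ligand element).
#' @param cutoff distance cutoff in Angstrom (default 12).
#' @return an [atom_set()] (possibly empty).
#' @export
pair_atom_selection <- function(protein, ligand, pair, cutoff = 12) {
  stopifnot(cutoff > 0, length(pair) == 2)
  pe <- protein[protein$element == pair[1], , drop = FALSE]
  le <- ligand[ligand$element == pair[2], , drop = FALSE]
  if (nrow(pe) > 0 && nrow(ligand) > 0) {
    px <- as.matrix(pe[, c("x", "y", "z")])
    lx <- as.matrix(ligand[, c("x", "y", "z")])
    d2min <- apply(px, 1, function(q)
      min((lx[, 1] - q[1])^2 + (lx[, 2] - q[2])^2 + (lx[, 3] - q[3])^2))
    pe <- pe[d2min <= cutoff^2, , drop = FALSE]
  }
  out <- rbind(pe, le)
  class(out) <- c("atom_set", "data.frame")
  out
}

#' Combine atom sets
#'
#' Row-binds any number of [atom_set()]s into one.
#' @param ... atom sets.
#' @return an [atom_set()].
#' @export
rbind_atom_sets <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("atom_set", "data.frame")
  out
}

#' Default featurization configuration
#'
#' @param spacing grid spacing in Angstrom.
#' @param isovalues isovalues of the FRI density filtration (default: 9
#'   evenly spaced values in [-0.5, -0.001]).
#' @param k number of leading nonzero eigenvalues per manifold.
#' @param tau FRI scale factor.
#' @param cutoff pair-selection cutoff (Angstrom).
#' @param variant Laplacian variant.
#' @param min_cells_per_component resolution rule: smallest admissible
#'   component size, in 3-cells.
#' @return a named list.
#' @export
featurize_config <- function(spacing = 0.549,
                             isovalues = seq(-0.5, -0.001, length.out = 9),
                             k = 5, tau = 1, cutoff = 12, variant = "big",
                             min_cells_per_component = 8) {
  list(spacing = spacing, isovalues = isovalues, k = k, tau = tau,
       cutoff = cutoff, variant = variant,
       min_cells_per_component = min_cells_per_component)
}

# grid sized to cover the selection: bounding box padded so that the density
# stays above every isovalue at the boundary, plus one cell of clearance
.selection_grid <- function(sel, config) {
  tau <- config$tau
  cmin <- min(config$isovalues)
  rmax <- max(sel$radius) * tau
  # a single atom reaches |rho| = |c| at distance r*sqrt(log(1/|c|)); the
  # n-atom bound replaces 1/|c| by n/(0.001) to clear the shallowest isovalue
  pad <- rmax * sqrt(log(nrow(sel) / 0.001)) + 2 * config$spacing
  lo <- c(min(sel$x), min(sel$y), min(sel$z)) - pad
  hi <- c(max(sel$x), max(sel$y), max(sel$z)) + pad
  counts <- pmax(4L, as.integer(ceiling((hi - lo) / config$spacing)) + 1L)
  build_grid_complex(counts, config$spacing, lo)
}

#' Topological feature vector of a protein-ligand complex
#'
#' For every element pair and isovalue, builds the FRI density of the pair
#' selection, samples it on a Cartesian grid covering the selection, computes
#' the degree-3 normal-support BIG Laplacian of the sublevel manifold and
#' records `beta0` (its kernel dimension) followed by the first `k` nonzero
#' eigenvalues (zero-padded when fewer exist).  Empty pair selections give
#' all-zero blocks.  The vector length is `(k + 1) * n_isovalues * 40`:
#' 2,160 features at k = 5, 3,960 at k = 10.
#'
#' Layout is pair-major (order of [element_pairs()]), then isovalue
#' (ascending), then `[beta0, lambda_1, ..., lambda_k]`.
#'
#' Components smaller than `min_cells_per_component` 3-cells trigger one
#' automatic halving of the grid spacing for that pair/isovalue, then a
#' warning if still violated.
#'
#' @param protein,ligand [atom_set()]s.
#' @param config a [featurize_config()].
#' @return numeric feature vector with attributes `config` and `warnings`.
#' @export
featurize_complex <- function(protein, ligand, config = featurize_config()) {
  pairs <- element_pairs()
  niso <- length(config$isovalues)
  block_len <- (config$k + 1L) * niso
  out <- numeric(block_len * nrow(pairs))
  warns <- character(0)
  for (ip in seq_len(nrow(pairs))) {
    sel <- pair_atom_selection(protein, ligand, pairs[ip, ], config$cutoff)
    if (nrow(sel) == 0L) next  # all-zero block
    base <- (ip - 1L) * block_len
    field <- fri_density(sel, config$tau)
    gc0 <- .selection_grid(sel, config)
    for (ic in seq_len(niso)) {
      c0 <- config$isovalues[ic]
      gc <- gc0
      feats <- NULL
      for (attempt in 1:2) {
        bundle <- laplacian_bundle(gc, field, isovalue = c0, bc = "normal",
                                   variant = config$variant)
        if (bundle$mask$n_kept[4] == 0) { feats <- numeric(config$k + 1); break }
        comp <- component_count(bundle)
        sizes <- tabulate(comp$membership)
        if (min(sizes) >= config$min_cells_per_component || attempt == 2) {
          if (min(sizes) < config$min_cells_per_component)
            warns <- c(warns, sprintf(
              "pair %s-%s isovalue %.4g: component below %d cells after refinement",
              pairs[ip, 1], pairs[ip, 2], c0, config$min_cells_per_component))
          b0 <- comp$no
          s <- smallest_spectrum(bundle$L[[4]],
                                 m = min(nrow(bundle$L[[4]]), b0 + config$k + 2L))
          nz <- s$values[s$values >= s$threshold]
          lam <- c(nz, numeric(config$k))[seq_len(config$k)]
          feats <- c(b0, lam)
          break
        }
        gc <- build_grid_complex(2L * (gc$counts - 1L) + 1L, gc$spacing / 2,
                                 gc$origin)  # one spacing halving, same box
      }
      out[base + (ic - 1L) * (config$k + 1L) + seq_len(config$k + 1L)] <- feats
    }
  }
  names(out) <- paste(rep(paste(pairs[, 1], pairs[, 2], sep = "-"),
                          each = block_len),
                      rep(rep(seq_len(niso), each = config$k + 1L),
                          nrow(pairs)),
                      rep(c("beta0", paste0("lambda", seq_len(config$k))),
                          niso * nrow(pairs)),
                      sep = ".")
  attr(out, "config") <- config
  attr(out, "warnings") <- warns
  if (length(warns)) warning(paste(warns, collapse = "; "))
  out
}
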