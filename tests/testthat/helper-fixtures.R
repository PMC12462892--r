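# Tiny structure-file fixtures written on the fly.

write_toy_pdb <- function(path, atoms) {
  # atoms: data.frame with name, element, x, y, z
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    sprintf("ATOM  %5d %-4s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, atoms$name[i], i, atoms$x[i], atoms$y[i], atoms$z[i],
            atoms$element[i])
  }, "")
  writeLines(c(lines, "END"), path)
  path
}

write_toy_mol2 <- function(path, atoms) {
  # atoms: data.frame with name, type (SYBYL), x, y, z
  n <- nrow(atoms)
  lines <- c("@<TRIPOS>MOLECULE", "toy",
             sprintf(" %d %d 0 0 0", n, max(0, n - 1)),
             "SMALL", "NO_CHARGES", "", "@<TRIPOS>ATOM",
             vapply(seq_len(n), function(i)
               sprintf("%7d %-4s %9.4f %9.4f %9.4f %-5s %3d LIG %9.4f",
                       i, atoms$name[i], atoms$x[i], atoms$y[i], atoms$z[i],
                       atoms$type[i], 1, 0), ""))
  if (n > 1) {
    lines <- c(lines, "@<TRIPOS>BOND",
               vapply(seq_len(n - 1), function(i)
                 sprintf("%6d %4d %4d %s", i, i, i + 1, "1"), ""))
  }
  writeLines(lines, path)
  path
}
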