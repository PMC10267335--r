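# Shared fixtures: a minimal multi-model PDB writer (text only, built at
# test time) and an independent brute-force contact-occupancy oracle.

# Write a multi-model PDB with one N (residue 551) and one P atom (residue
# 900) per model; `coords` is a list of 2x3 matrices (rows: atom a, atom b).
write_multimodel_pdb <- function(coords, path = tempfile(fileext = ".pdb")) {
  atom_line <- function(serial, name, resname, resno, xyz, element) {
    sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      serial, name, resname, resno, xyz[1], xyz[2], xyz[3], element
    )
  }
  lines <- character(0)
  for (i in seq_along(coords)) {
    lines <- c(
      lines,
      sprintf("MODEL     %4d", i),
      atom_line(1L, "N", "GLY", 551L, coords[[i]][1L, ], "N"),
      atom_line(2L, "PG", "ATP", 900L, coords[[i]][2L, ], "P"),
      "ENDMDL"
    )
  }
  writeLines(c(lines, "END"), path)
  path
}

test_metric <- function(threshold = 5) {
  contact_metric("lambda",
    atom_a = list(resno = 551, elety = "N"),
    atom_b = list(resno = 900, elety = "PG"),
    threshold = threshold
  )
}

# Brute-force oracle: loop over frames and count, no vectorised shortcut.
brute_force_fraction <- function(distances, threshold) {
  n_below <- 0L
  for (d in distances) {
    if (d < threshold) n_below <- n_below + 1L
  }
  n_below / length(distances)
}
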