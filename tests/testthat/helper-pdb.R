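# Hand-rolled PDB text fixtures (written at test time, never stored).

pdb_atom_line <- function(serial, name, resid, chain, resno, xyz,
                          occ = 1.00, alt = "") {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name), alt,
          resid, chain, resno, xyz[1], xyz[2], xyz[3], occ, 0)
}

# write a toy PDB from coordinate matrices; drop_atoms is a data.frame
# (resno, elety) of atoms to omit
write_toy_pdb <- function(path, xyz, resid = "ALA", chain = "A",
                          drop_atoms = NULL, extra_lines = NULL) {
  n <- nrow(xyz$N)
  lines <- character(); serial <- 0L
  for (i in seq_len(n)) {
    for (ele in c("N", "CA", "C", "O")) {
      if (!is.null(drop_atoms) &&
          any(drop_atoms$resno == i & drop_atoms$elety == ele)) next
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line(serial, ele, resid, chain, i,
                                      xyz[[ele]][i, ]))
    }
  }
  writeLines(c(lines, extra_lines, "END"), path)
  path
}

helix_xyz <- function(n) fatsurf:::build_backbone_coords(n, -57, -47)
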