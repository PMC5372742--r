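# Hand-built PDB fixtures for parser tests. Coordinates are taken from
# the package's own generator at fixed torsions, re-rendered with
# controlled quirks (altlocs, models, malformed fields).

pdb_atom_line <- function(serial, name, resname, chain, resno, xyz,
                          occ = 1, alt = " ", record = "ATOM  ") {
  sprintf("%s%5d  %-3s%s%s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, alt, resname, chain, resno,
          xyz[1], xyz[2], xyz[3], occ, 0, substr(name, 1, 1))
}

# two complete cysteines bridged at the given torsions
two_cys_lines <- function(chi = c(-60, -80, -85, -80, -60),
                          ss = 2.04) {
  co <- build_disulfide_coords(
    disulfide_spec(chi[1], chi[2], chi[3], chi[4], chi[5],
                   ss_bond_length = ss))
  lab <- list(c("N", 55), c("CA", 55), c("CB", 55), c("SG", 55),
              c("SG", 99), c("CB", 99), c("CA", 99), c("N", 99))
  vapply(seq_len(8), function(k)
    pdb_atom_line(k, lab[[k]][1], "CYS", "A", as.integer(lab[[k]][2]),
                  co$xyz[k, ]),
    character(1))
}

write_fixture_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# absolute angular difference on the circle, degrees
wrap_diff <- function(a, b) {
  abs(((a - b + 180) %% 360) - 180)
}

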