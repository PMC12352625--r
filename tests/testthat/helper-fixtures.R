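# Shared fixtures: tiny hand-written coordinate files and random rigid
# motions. Everything is built in code at test time.

pdb_atom_line <- function(serial, name, resname, chain, resseq, x, y, z,
                          altloc = " ", occ = 1, b = 0, element = NULL,
                          record = "ATOM") {
  if (is.null(element)) element <- substr(gsub("[0-9]", "", name), 1, 1)
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, if (nchar(name) < 4) paste0(" ", name) else name,
          altloc, resname, chain, resseq, x, y, z, occ, b, element)
}

write_tiny_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# A 3-atom water used by several parser tests
tiny_water_pdb <- function() {
  write_tiny_pdb(c(
    pdb_atom_line(1, "O", "HOH", "A", 1, 0, 0, 0, element = "O",
                  record = "HETATM"),
    pdb_atom_line(2, "H1", "HOH", "A", 1, 0.96, 0, 0, element = "H",
                  record = "HETATM"),
    pdb_atom_line(3, "H2", "HOH", "A", 1, -0.24, 0.93, 0, element = "H",
                  record = "HETATM")))
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

apply_rigid <- function(s, R, t) {
  models <- lapply(s$models, function(m) {
    xyz <- as.matrix(m[, c("x", "y", "z")]) %*% t(R)
    m$x <- xyz[, 1] + t[1]; m$y <- xyz[, 2] + t[2]; m$z <- xyz[, 3] + t[3]
    m
  })
  Structure(models, s$source_format, s$id)
}
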