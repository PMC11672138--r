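# Programmatic construction of minimal PDB fixtures.

# atoms: data frame with columns name, resid, chain, resno, x, y, z,
# element; writes standard fixed-column ATOM records.
write_test_pdb <- function(atoms, path = tempfile(fileext = ".pdb")) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, a$name, a$resid, a$chain, a$resno, a$x, a$y, a$z, 1.00, 0.00,
            a$element)
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

# nitrile probe (C at origin, N on +z) with donor oxygens at given d/theta
# in the xz plane
probe_with_donors <- function(d, theta, cn_len = 1.16) {
  ang <- theta * pi / 180
  n_pos <- c(0, 0, cn_len)
  donors <- data.frame(
    name = "O", resid = "HOH", chain = "A",
    resno = seq_along(d) + 100L,
    # N->C is -z; rotate away from -z by (180 - theta)
    x = d * sin(pi - ang), y = 0, z = cn_len + d * cos(pi - ang),
    element = "O")
  probe <- data.frame(
    name = c("CZ", "NZ"), resid = "OCN", chain = "A", resno = 1L,
    x = 0, y = 0, z = c(0, cn_len), element = c("C", "N"))
  rbind(probe, donors)
}
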