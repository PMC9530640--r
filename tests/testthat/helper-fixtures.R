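# Shared builders for toy structures and alignments.

# CA-only helical trace: n residues on an ideal alpha-helix (non-collinear).
toy_trace <- function(n = 10, chain = "A", resno = seq_len(n), id = "toy") {
  th <- (seq_len(n) - 1) * 100 * pi / 180
  zip_structure(data.frame(
    chain = chain, resno = resno, resid = "ALA", elety = "CA", elesy = "C",
    x = 2.3 * cos(th), y = 2.3 * sin(th), z = 1.5 * (seq_len(n) - 1),
    o = 1, het = FALSE), id = id)
}

# deterministic proper rotation from three angles (radians)
rotation_matrix <- function(a, b, c) {
  rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  rz <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
  rx %*% ry %*% rz
}

shift_structure <- function(s, dxyz, residues = NULL) {
  at <- s$atom
  sel <- if (is.null(residues)) rep(TRUE, nrow(at)) else at$resno %in% residues
  at$x[sel] <- at$x[sel] + dxyz[1]
  at$y[sel] <- at$y[sel] + dxyz[2]
  at$z[sel] <- at$z[sel] + dxyz[3]
  zip_structure(at, id = s$id)
}

rotate_structure <- function(s, rot, dxyz = c(0, 0, 0)) {
  transformed <- apply_transform(as.matrix(s$atom[, c("x", "y", "z")]),
                                 list(rotation = rot, translation = dxyz))
  at <- s$atom
  at$x <- transformed[, 1]; at$y <- transformed[, 2]; at$z <- transformed[, 3]
  zip_structure(at, id = s$id)
}

# Handcrafted three-residue PDB text, fixed-width.
toy_pdb_text <- function() {
  paste(c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.300   2.000   3.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       3.800   2.500   4.500  1.00  0.00           C",
    "ATOM      4  CA  SER A   3       5.100   3.100   6.000  1.00  0.00           C",
    "END"), collapse = "\n")
}
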