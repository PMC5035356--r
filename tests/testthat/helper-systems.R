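# Shared builders for toy systems and plain-text fixtures.

# Compact 30-node cluster at protein-like ~4 A packing: jittered grid so the
# 8 A elastic network is well connected (every node has >= 5 contacts) and
# the harmonic linearisation underlying the analytic oracle holds.
grid_reference <- function(n = 30L, spacing = 4, jitter_sd = 0.3,
                           seed = 101L) {
  set.seed(seed)
  g <- as.matrix(expand.grid(x = 0:2, y = 0:2, z = 0:3))[seq_len(n), ]
  g * spacing + matrix(rnorm(3L * n, sd = jitter_sd), n, 3L)
}

scatter_reference <- function(n, side = 30, seed = 11L) {
  set.seed(seed)
  matrix(runif(3L * n, 0, side), n, 3L)
}

random_rotation <- function() {
  q <- svd(matrix(rnorm(9), 3, 3))
  R <- q$u %*% t(q$v)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Fixed-column PDB fixture with a VAL (CG1 + CG2) and a LEU (CG), written
# independently of the package's own writer.
write_fixture_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   VAL A   1       0.000   0.000   0.000  1.00  7.00           N",
    "ATOM      2  CA  VAL A   1       1.458   0.000   0.000  1.00  8.50           C",
    "ATOM      3  CB  VAL A   1       2.000   1.420   0.000  1.00 10.00           C",
    "ATOM      4  CG1 VAL A   1       3.512   1.430   0.120  1.00 12.25           C",
    "ATOM      5  CG2 VAL A   1       1.450   2.210   1.200  1.00 11.75           C",
    "ATOM      6  C   VAL A   1       2.000  -0.800  -1.200  1.00  9.00           C",
    "ATOM      7  O   VAL A   1       1.400  -1.850  -1.400  1.00 10.50           O",
    "ATOM      8  N   LEU A   2       3.200  -0.400  -1.700  1.00  9.25           N",
    "ATOM      9  CA  LEU A   2       3.900  -1.100  -2.780  1.00 10.75           C",
    "ATOM     10  CB  LEU A   2       5.350  -0.650  -2.900  1.00 12.00           C",
    "ATOM     11  CG  LEU A   2       6.100  -1.250  -4.100  1.00 14.50           C",
    "ATOM     12  C   LEU A   2       3.850  -2.620  -2.560  1.00 11.00           C",
    "ATOM     13  O   LEU A   2       4.100  -3.380  -3.500  1.00 12.30           O",
    "HETATM   14  O   HOH A 101       8.000   8.000   8.000  1.00 30.00           O",
    "END")
  writeLines(lines, path)
  path
}

# Minimal AMBER prmtop with a 7-atom MASS block in 5E16.8 format.
write_fixture_prmtop <- function(path,
                                 masses = c(1.008, 12.011, 14.007, 15.999,
                                            32.06, 1.008, 12.011)) {
  mass_lines <- vapply(split(sprintf("%16.8E", masses),
                             (seq_along(masses) - 1L) %/% 5L),
                       paste0, character(1L), collapse = "")
  lines <- c(
    "%VERSION  VERSION_STAMP = V0001.000  DATE = 01/01/01  00:00:00",
    "%FLAG TITLE",
    "%FORMAT(20a4)",
    "toy system",
    "%FLAG POINTERS",
    "%FORMAT(10I8)",
    sprintf("%8d%8d%8d", 7L, 2L, 0L),
    "%FLAG ATOM_NAME",
    "%FORMAT(20a4)",
    "H1  C1  N1  O1  S1  H2  C2  ",
    "%FLAG MASS",
    "%FORMAT(5E16.8)",
    mass_lines,
    "%FLAG CHARGE",
    "%FORMAT(5E16.8)",
    paste0(sprintf("%16.8E", c(0.1, -0.1, 0.0, 0.0, 0.0)), collapse = ""),
    paste0(sprintf("%16.8E", c(0.05, -0.05)), collapse = ""))
  writeLines(lines, path)
  path
}
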