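# Small fixtures built in code.

pdb_fixture_lines <- function() {
  c(
    "ATOM      1  N   ALA A  10      11.104   6.134  -6.504  1.00 10.00           N",
    "ATOM      2  CA  ALA A  10      11.639   6.071  -5.147  1.00 10.00           C",
    "ATOM      3  C   ALA A  10      12.760   7.092  -4.973  1.00 10.00           C",
    "ATOM      4  O   ALA A  10      13.420   7.450  -5.947  1.00 10.00           O",
    "ATOM      5  N   GLY A  11      12.990   7.533  -3.737  1.00 11.00           N",
    "ATOM      6  CA  GLY A  11      14.040   8.510  -3.463  1.00 11.00           C",
    "HETATM    7  C1  LIG B 301       1.000   2.000   3.000  1.00 20.00           C",
    "HETATM    8  O   HOH A 201       5.000   5.000   5.000  1.00 20.00           O",
    "END"
  )
}

write_pdb_fixture <- function(path = tempfile(fileext = ".pdb"),
                              lines = pdb_fixture_lines()) {
  writeLines(lines, path)
  path
}

small_pentamer <- function(noise_sigma = 0, seed = 1, n = 8) {
  make_ideal_pentamer(residues_per_domain = n, noise_sigma = noise_sigma,
                      seed = seed)
}

# A tiny five-residue single-chain model with distinct CA positions.
five_res_chain <- function() {
  structure_model(tibble::tibble(
    atom_name = rep(c("N", "CA"), 5)[1:10],
    residue_name = "ALA",
    chain = "A",
    residue_number = rep(1:5, each = 2),
    x = seq(0, 9), y = (seq(0, 9))^1.3 * 0.1, z = rep(c(0, 0.5), 5),
    element = rep(c("N", "C"), 5)
  ), identifier = "five_res")
}
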