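test_that("PDB read-back matches the fixture and survives a round trip", {
  path <- write_pdb_fixture()
  m <- read_structure(path)
  # waters dropped, ligand HETATM kept
  expect_equal(nrow(m), 7)
  expect_false("HOH" %in% m$residue_name)
  expect_true("LIG" %in% m$residue_name)
  expect_equal(m$x[1], 11.104, tolerance = 1e-9)
  expect_equal(unname(coords(m)[2, ]), c(11.639, 6.071, -5.147))

  out <- tempfile(fileext = ".pdb")
  write_structure(m, out)
  m2 <- read_structure(out)
  expect_equal(nrow(m2), nrow(m))
  expect_equal(coords(m2), coords(m), tolerance = 1e-3)
  expect_identical(m2$chain, m$chain)
  expect_identical(m2$residue_number, m$residue_number)
  expect_identical(m2$atom_name, m$atom_name)
})

test_that("written PDB parses under an independent fixed-column reader", {
  m <- five_res_chain()
  out <- tempfile(fileext = ".pdb")
  write_structure(m, out)
  lines <- grep("^(ATOM|HETATM)", readLines(out), value = TRUE)
  expect_equal(length(lines), nrow(m))
  # fixed-column extraction, independent of any parser package
  x <- as.numeric(substr(lines, 31, 38))
  y <- as.numeric(substr(lines, 39, 46))
  z <- as.numeric(substr(lines, 47, 54))
  expect_equal(x, m$x, tolerance = 1e-3)
  expect_equal(y, m$y, tolerance = 1e-3)
  expect_equal(z, m$z, tolerance = 1e-3)
  expect_equal(trimws(substr(lines, 22, 22)), m$chain)
  expect_equal(as.integer(substr(lines, 23, 26)), m$residue_number)
})

test_that("alt-loc policy keeps the highest-occupancy conformer, first on ties", {
  lines <- c(
    "ATOM      1  CA AALA A  10      11.639   6.071  -5.147  0.60 10.00           C",
    "ATOM      2  CA BALA A  10      11.700   6.100  -5.200  0.40 10.00           C",
    "ATOM      3  CA AALA A  11       1.000   1.000   1.000  0.50 10.00           C",
    "ATOM      4  CA BALA A  11       2.000   2.000   2.000  0.50 10.00           C",
    "END"
  )
  m <- read_structure(write_pdb_fixture(lines = lines))
  expect_equal(nrow(m), 2)
  expect_equal(m$x[m$residue_number == 10], 11.639)  # higher occupancy wins
  expect_equal(m$x[m$residue_number == 11], 1.0)     # tie -> first encountered
})

test_that("read_structure rejects missing and atom-free files", {
  expect_error(read_structure(tempfile()), "not found")
  empty <- tempfile(fileext = ".pdb")
  writeLines(c("HEADER    NOTHING", "END"), empty)
  expect_error(read_structure(empty), "unreadable|no atoms")
})

test_that("select_atoms matches a brute-force filter", {
  gen <- small_pentamer()
  m <- gen$model
  sel <- select_atoms(m, chains = c("A", "C"), residues = list(c(10, 217)),
                      atom_names = "CA")
  brute <- m[m$chain %in% c("A", "C") & m$residue_number >= 10 &
               m$residue_number <= 217 & m$atom_name == "CA", ]
  expect_equal(nrow(sel), nrow(brute))
  expect_identical(paste(sel$chain, sel$residue_number, sel$atom_name),
                   paste(brute$chain, brute$residue_number, brute$atom_name))

  chain5 <- five_res_chain()
  expect_equal(nrow(select_atoms(chain5, atom_names = "CA")), 5)
  expect_equal(nrow(select_atoms(chain5)), nrow(chain5))  # empty criteria = all
  expect_equal(nrow(select_atoms(chain5, chains = "Z")), 0)
})

test_that("center_of_mass is correct, weighted, and rigid-equivariant", {
  two <- structure_model(tibble::tibble(
    atom_name = "CA", residue_name = "ALA", chain = "A",
    residue_number = 1:2, x = c(0, 2), y = 0, z = 0, element = "C"
  ))
  expect_equal(unname(center_of_mass(two)), c(1, 0, 0))
  one <- select_atoms(two, residues = 1)
  expect_equal(unname(center_of_mass(one)), c(0, 0, 0))

  # mass weighting vs hand-computed weighted mean on random atoms
  set.seed(42)
  els <- c("C", "N", "O", "S", "H")
  atoms <- structure_model(tibble::tibble(
    atom_name = paste0("X", 1:10), residue_name = "UNK", chain = "A",
    residue_number = 1:10,
    x = rnorm(10), y = rnorm(10), z = rnorm(10),
    element = sample(els, 10, replace = TRUE)
  ))
  w <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, H = 1.008)[atoms$element]
  hand <- colSums(coords(atoms) * w) / sum(w)
  expect_equal(unname(center_of_mass(atoms, "mass")), unname(hand),
               tolerance = 1e-9)

  R <- random_rotation(7)
  t_ <- c(3, -2, 5)
  moved <- transform_model(atoms, R, t_)
  expect_equal(unname(center_of_mass(moved, "mass")),
               unname(as.numeric(R %*% hand) + t_), tolerance = 1e-9)
  expect_error(center_of_mass(select_atoms(atoms, chains = "Z")), "empty")
})

test_that("min_distance agrees with an exhaustive double loop and is symmetric", {
  p <- structure_model(tibble::tibble(
    atom_name = "C1", residue_name = "X", chain = "A", residue_number = 1,
    x = 0, y = 0, z = 0, element = "C"
  ))
  q <- structure_model(tibble::tibble(
    atom_name = "C1", residue_name = "X", chain = "B", residue_number = 1,
    x = 3, y = 4, z = 0, element = "C"
  ))
  expect_equal(min_distance(p, q), 5.0)
  expect_equal(min_distance(p, p), 0)

  set.seed(11)
  mk <- function(ch) structure_model(tibble::tibble(
    atom_name = paste0("C", 1:20), residue_name = "X", chain = ch,
    residue_number = 1:20, x = rnorm(20, sd = 5), y = rnorm(20, sd = 5),
    z = rnorm(20, sd = 5), element = "C"
  ))
  a <- mk("A"); b <- mk("B")
  expect_equal(min_distance(a, b), brute_min_distance(coords(a), coords(b)),
               tolerance = 1e-12)
  expect_equal(min_distance(a, b), min_distance(b, a))
  expect_error(min_distance(a, select_atoms(b, chains = "Z")), "empty")
})

test_that("duplicate atom keys are rejected", {
  expect_error(structure_model(tibble::tibble(
    atom_name = "CA", residue_name = "ALA", chain = "A",
    residue_number = c(1, 1), x = 0:1, y = 0, z = 0, element = "C"
  )), "duplicated")
})
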