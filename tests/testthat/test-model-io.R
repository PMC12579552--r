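test_that("PDB write/read round trip preserves the model at format precision", {
  m <- noisy_toy(3, sd = 0.2, seed = 42)
  a <- tibble::as_tibble(m)
  a$occ[4] <- 0.25
  a$b <- round(a$b + runif(nrow(a), 0, 5), 2)
  m <- struct_model(a, cell = c(25.5, 26.25, 27, 90, 90, 90))
  p <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, p)
  m2 <- read_structure(p)
  expect_equal(round(m$x, 3), m2$x)
  expect_equal(round(m$y, 3), m2$y)
  expect_equal(round(m$z, 3), m2$z)
  expect_equal(round(m$occ, 2), m2$occ)
  expect_equal(round(m$b, 2), m2$b)
  expect_equal(m$atom, m2$atom)
  expect_equal(m$altloc, m2$altloc)
  expect_equal(model_cell(m), model_cell(m2))
  expect_equal(m2$occ[4], 0.25)
  # read-write-read is stable
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m2, p2)
  expect_equal(tibble::as_tibble(read_structure(p2)), tibble::as_tibble(m2))
})

test_that("PDB output uses fixed-column conventions", {
  m <- tiny_model(list(atom_row(atom = "CA", x = 1, y = 2, z = 3, occ = 1),
                       atom_row(resno = 2, atom = "CA", x = 5, y = 5, z = 5,
                                occ = 0.25)))
  p <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, p)
  lines <- grep("^ATOM", readLines(p), value = TRUE)
  expect_equal(substr(lines[1], 55, 60), "  1.00")  # occupancy 1.0 -> "1.00"
  expect_equal(substr(lines[2], 55, 60), "  0.25")
  expect_equal(substr(lines[1], 17, 17), " ")       # blank altloc stays blank
})

test_that("malformed and inconsistent PDB input is rejected with context", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134   1.000  1.00 20.00           N",
    "ATOM      2  CA  ALA A   1      12.560   badxx   1.100  1.00 21.00           C"
  ), p)
  expect_error(read_structure(p), "line 2")

  # duplicate altloc copies of one atom violate the model invariant
  p2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1      11.104   6.134   1.000  0.50 20.00           C",
    "ATOM      2  CA AALA A   1      12.560   6.351   1.100  0.50 21.00           C"
  ), p2)
  expect_error(read_structure(p2), "duplicate")
  expect_error(read_structure(tempfile()), "no such file")
})

test_that("atom-name mapping renames only targeted atoms", {
  m <- make_toy_structure(4)
  noop <- map_atom_names(m, tibble::tibble(
    resname = character(0), from = character(0), to = character(0)))
  expect_equal(attr(noop, "n_renamed"), 0L)
  attr(noop, "n_renamed") <- NULL
  expect_equal(as.data.frame(noop), as.data.frame(m))
  a <- tibble::as_tibble(m)
  a$atom[a$resno == 4 & a$atom == "O"] <- "OXT"
  m2 <- struct_model(a, cell = model_cell(m))
  expect_message(
    out <- map_atom_names(m2, tibble::tibble(resname = "*", from = "OXT",
                                             to = "O")),
    "renamed 1")
  expect_equal(attr(out, "n_renamed"), 1L)
  expect_equal(sort(unique(out$atom)), c("C", "CA", "CB", "N", "O"))
  # mapping that collides two atoms into one name errors
  expect_error(map_atom_names(m, tibble::tibble(resname = "*", from = "CB",
                                                to = "CA")),
               "collides")
})

test_that("merging installs the two-state occupancy and B-factor policy", {
  ref <- make_toy_structure(10)
  sel <- residue_selection("A", 5:6)
  frag <- displaced <- {
    a <- tibble::as_tibble(ref)
    moved <- a$resno %in% 5:6
    a$x[moved] <- a$x[moved] + 1
    struct_model(a, cell = model_cell(ref))
  }
  merged <- merge_alt_conformers(ref, frag, sel, q_init = 0.25)
  a <- tibble::as_tibble(merged)
  expect_equal(unique(a$occ[a$altloc == "B"]), 0.25)
  expect_equal(unique(a$occ[a$altloc == "A"]), 0.75)
  # occupancy complement per merged atom pair
  paired <- a |>
    dplyr::filter(.data$altloc != "") |>
    dplyr::group_by(chain, resno, ins, atom) |>
    dplyr::summarise(total = sum(occ), .groups = "drop")
  expect_true(all(abs(paired$total - 1) < 1e-6))
  # B-factor transfer is exact
  bb <- a |>
    dplyr::filter(.data$altloc != "") |>
    tidyr::pivot_wider(id_cols = c(chain, resno, ins, atom),
                       names_from = altloc, values_from = b)
  expect_equal(max(abs(bb$A - bb$B)), 0)
  # atom conservation: + one fragment copy for each selected residue
  expect_equal(nrow(merged), nrow(ref) + 2 * 5)
  # unselected residues byte-identical on rewrite
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  other <- residue_selection("A", setdiff(1:10, 5:6))
  write_structure(subset_residues(ref, other), p1)
  write_structure(subset_residues(merged, other), p2)
  skip_lines <- function(p) grep("^ATOM", readLines(p), value = TRUE)
  expect_identical(skip_lines(p1), skip_lines(p2))
})

test_that("merge rejects invalid occupancy and unmatched fragment atoms", {
  ref <- make_toy_structure(5)
  sel <- residue_selection("A", 3)
  expect_error(merge_alt_conformers(ref, ref, sel, q_init = 0), "q_init")
  expect_error(merge_alt_conformers(ref, ref, sel, q_init = 1), "q_init")
  # fragment atom with no same-named reference atom
  a <- tibble::as_tibble(ref)
  a$atom[a$resno == 3 & a$atom == "CB"] <- "CG"
  frag <- struct_model(a, cell = model_cell(ref))
  expect_error(merge_alt_conformers(ref, frag, sel), "CG")
  # identical fragment gives zero conformer separation
  merged <- merge_alt_conformers(ref, ref, sel)
  expect_equal(conformer_rmsd(merged, sel), 0)
})

test_that("merge drops fragment hydrogens unless asked to keep them", {
  ref <- make_toy_structure(4)
  a <- tibble::as_tibble(ref)
  h <- a[a$atom == "CA" & a$resno == 2, ]
  h$atom <- "HA"; h$element <- "H"; h$x <- h$x + 1
  withH_ref <- struct_model(dplyr::bind_rows(a, h), cell = model_cell(ref))
  sel <- residue_selection("A", 2)
  merged <- merge_alt_conformers(withH_ref, withH_ref, sel)
  expect_false(any(merged$element == "H" & merged$altloc == "B"))
  merged_h <- merge_alt_conformers(withH_ref, withH_ref, sel,
                                   keep_hydrogens = TRUE)
  expect_true(any(merged_h$element == "H" & merged_h$altloc == "B"))
})
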