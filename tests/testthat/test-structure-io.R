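test_that("hand-written PDB parses to the expected structure graph", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(tiny_pdb_lines(), f)
  s <- read_structure(f)
  expect_s3_class(s, "rna_structure")
  expect_equal(nrow(s$atoms), 3)
  ri <- residue_table(s)
  expect_equal(nrow(ri), 1)
  expect_equal(ri$chain, "A")
  expect_equal(ri$parent, "G")
  expect_equal(s$atoms$x, c(1.0, 2.5, 3.4))
  expect_equal(s$atoms$b, c(20, 30, 40))
})

test_that("the same content as mmCIF gives an identical structure graph", {
  fp <- withr::local_tempfile(fileext = ".pdb")
  fc <- withr::local_tempfile(fileext = ".cif")
  writeLines(tiny_pdb_lines(), fp)
  writeLines(tiny_cif_lines(), fc)
  sp <- read_structure(fp)
  sc <- read_structure(fc)
  expect_equal(sc$source_format, "mmCIF")
  expect_equal(sc$atoms$key, sp$atoms$key)
  expect_equal(sc$atoms$name, sp$atoms$name)
  expect_equal(sc$atoms$x, sp$atoms$x, tolerance = 1e-9)
  expect_equal(sc$atoms$y, sp$atoms$y, tolerance = 1e-9)
  expect_equal(sc$atoms$z, sp$atoms$z, tolerance = 1e-9)
})

test_that("multi-MODEL files keep only the first model, with a warning", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    tiny_pdb_lines()[1:3],
    "ENDMDL",
    "MODEL        2",
    sub("^ATOM      1", "ATOM      9", tiny_pdb_lines()[1]),
    "ENDMDL",
    "END"), f)
  expect_warning(s <- read_structure(f), "MODEL 1")
  expect_equal(nrow(s$atoms), 3)
})

test_that("alt-locs resolve to highest occupancy, ties to first in file", {
  f <- withr::local_tempfile(fileext = ".pdb")
  altloc_line <- function(serial, name, alt, x, occ, el) {
    sprintf("ATOM  %5d %-4s%1s  G A   1    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, alt, x, 0, 0, occ, 20, el)
  }
  writeLines(c(
    altloc_line(1, " P", "A", 1.0, 0.40, "P"),
    altloc_line(2, " P", "B", 9.0, 0.60, "P"),
    altloc_line(3, "C1'", "A", 2.0, 0.50, "C"),
    altloc_line(4, "C1'", "B", 8.0, 0.50, "C"),
    "END"), f)
  s <- read_structure(f)
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$atoms$x[s$atoms$name == "P"], 9.0)    # higher occupancy
  expect_equal(s$atoms$x[s$atoms$name == "C1'"], 2.0)  # tie -> first
})

test_that("waters are dropped and empty files error", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A 101       0.000   0.000   0.000  1.00  0.00           O",
    "END"), f)
  expect_error(read_structure(f), "empty structure")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(tiny_pdb_lines()[1:3],
    "HETATM    4  O   HOH A 101       0.000   0.000   0.000  1.00  0.00           O",
    "END"), f2)
  expect_equal(nrow(read_structure(f2)$atoms), 3)
})

test_that("hetero ligands are kept but flagged non-polymer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(tiny_pdb_lines()[1:3],
    "HETATM    4  C1  SAM A 201       5.000   5.000   5.000  1.00 10.00           C",
    "END"), f)
  s <- read_structure(f)
  expect_equal(sum(s$atoms$het), 1)
  ri <- residue_table(s)
  expect_false(ri$is_nt[ri$resname == "SAM"])
})

test_that("PDB round-trip preserves residue keys and coordinates to 1e-3", {
  fx <- build_duplex("GACU", seed = 3)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(fx$structure, f)
  s2 <- read_structure(f)
  expect_equal(s2$atoms$key, fx$structure$atoms$key)
  expect_equal(s2$atoms$name, fx$structure$atoms$name)
  expect_lt(max(abs(s2$atoms$x - fx$structure$atoms$x)), 1e-3)
  expect_lt(max(abs(s2$atoms$y - fx$structure$atoms$y)), 1e-3)
  expect_lt(max(abs(s2$atoms$z - fx$structure$atoms$z)), 1e-3)
})

test_that("unreadable numeric fields raise a parse error naming the line", {
  f <- withr::local_tempfile(fileext = ".pdb")
  bad <- tiny_pdb_lines()
  bad[2] <- "ATOM      2  C1'   G A   1       xx.xxx   2.000   3.000  1.00 30.00           C"
  writeLines(bad, f)
  expect_error(read_structure(f), "line")
})
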