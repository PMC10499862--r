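test_that("read_structure round-trips a toy fixture written by the test", {
  path <- write_pdb_lines(c(
    pdb_atom_line(1, "ALA", "A", 1, 1.25, -2.5, 3.125, 10.5),
    pdb_atom_line(2, "GLY", "A", 2, 4.0, 5.0, 6.0, 20.25),
    pdb_atom_line(3, "MSE", "A", 3, 7.0, 8.0, 9.0, 30.0)))
  rec <- read_structure(path, protein_id = "toy3")
  expect_s3_class(rec, "protein_record")
  expect_equal(n_residues(rec), 3L)
  expect_equal(rec$sites$aa_code, c("ALA", "GLY", "MSE"))
  expect_equal(rec$sites$x, c(1.25, 4, 7))
  expect_equal(rec$sites$b_factor, c(10.5, 20.25, 30))
  expect_equal(rec$sites$ss_label, rep("unassigned", 3))
})

test_that("chains are kept in file order with their labels", {
  path <- write_pdb_lines(c(
    pdb_atom_line(1, "ALA", "A", 1, 0, 0, 0, 10),
    pdb_atom_line(2, "GLY", "A", 2, 3.8, 0, 0, 12),
    "TER",
    pdb_atom_line(3, "LEU", "B", 1, 10, 0, 0, 14),
    pdb_atom_line(4, "VAL", "B", 2, 13.8, 0, 0, 16)))
  rec <- read_structure(path)
  expect_equal(rec$sites$chain_id, c("A", "A", "B", "B"))
  expect_equal(rec$sites$aa_code, c("ALA", "GLY", "LEU", "VAL"))
})

test_that("altlocs resolve to one site, HETATM and later models are ignored", {
  path <- write_pdb_lines(c(
    "MODEL        1",
    pdb_atom_line(1, "ALA", "A", 1, 0, 0, 0, 10),
    pdb_atom_line(2, "GLY", "A", 2, 3.8, 1, 0, 20, altloc = "A"),
    pdb_atom_line(3, "GLY", "A", 2, 3.9, 1, 0, 22, altloc = "B"),
    pdb_atom_line(4, "SER", "A", 3, 7.6, 0, 1, 30),
    "HETATM    5  CA  CA  A 101      20.000  20.000  20.000  1.00 50.00          CA",
    "ENDMDL",
    "MODEL        2",
    pdb_atom_line(1, "ALA", "A", 1, 9, 0, 0, 11),
    pdb_atom_line(2, "GLY", "A", 2, 9, 1, 0, 21, altloc = "A"),
    pdb_atom_line(4, "SER", "A", 3, 9, 0, 1, 31),
    "ENDMDL"))
  rec <- read_structure(path)
  expect_equal(n_residues(rec), 3L)          # one site per residue
  expect_equal(rec$sites$b_factor[2], 20)    # first-listed altloc
  expect_equal(rec$sites$x[1], 0)            # model 1, not model 2
})

test_that("reading a written record is the identity at format precision", {
  rec <- random_record(n = 25, seed = 7)
  path <- tempfile(fileext = ".pdb")
  write_structure(rec, path)
  back <- read_structure(path, protein_id = rec$protein_id)
  expect_equal(back$sites$aa_code, rec$sites$aa_code)
  expect_equal(back$sites$chain_id, rec$sites$chain_id)
  expect_equal(back$sites$x, round(rec$sites$x, 3))
  expect_equal(back$sites$y, round(rec$sites$y, 3))
  expect_equal(back$sites$z, round(rec$sites$z, 3))
  expect_equal(back$sites$b_factor, round(rec$sites$b_factor, 2))
})

test_that("reading fails cleanly on missing files and CA-free files", {
  expect_error(read_structure(tempfile()), "cannot read")
  path <- write_pdb_lines(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N")
  expect_error(read_structure(path), "no C-alpha")
})

test_that("curation filters fire on their printed boundaries", {
  line <- cbind(seq_len(100) * 3.8, sin(seq_len(100)), cos(seq_len(100)))
  ok_b <- 20 + 10 * sin(seq_len(100))
  hi <- toy_record("hi", line, b = c(ok_b[-100], 85))
  expect_false(curate_protein(hi)$accepted)
  expect_equal(curate_protein(hi)$reasons, "b_above_max")

  line5 <- cbind(seq_len(501) * 3.8, sin(seq_len(501)), cos(seq_len(501)))
  long <- toy_record("long", line5, b = 20 + 10 * sin(seq_len(501)))
  expect_equal(curate_protein(long)$reasons, "too_long")

  const <- toy_record("const", line[1:50, ], b = 20)
  expect_equal(curate_protein(const)$reasons, "b_constant")

  clean <- toy_record("clean", line[1:50, ], b = ok_b[1:50])
  expect_true(curate_protein(clean)$accepted)
  expect_length(curate_protein(clean)$reasons, 0)
})

test_that("every violated rule is reported, not just the first", {
  line <- cbind(seq_len(501) * 3.8, sin(seq_len(501)), cos(seq_len(501)))
  bad <- toy_record("bad", line, b = c(-1, 90, rep(20, 499)))
  d <- curate_protein(bad)
  expect_false(d$accepted)
  expect_setequal(d$reasons, c("b_above_max", "b_nonpositive", "too_long"))
})

test_that("raising max_b never converts accepted into rejected", {
  for (seed in 1:5) {
    rec <- random_record(n = 20, seed = seed)
    rec$sites$b_factor <- runif(20, 1, 120)
    verdicts <- vapply(c(40, 80, 120, 200), function(mb)
      curate_protein(rec, max_b = mb)$accepted, logical(1))
    expect_true(all(diff(verdicts) >= 0))
  }
})

test_that("split_dataset sizes, determinism, and partition invariant hold", {
  ids <- sprintf("p%03d", 1:100)
  sp <- split_dataset(ids, c(0.92, 0.04, 0.04), seed = 7)
  expect_equal(lengths(sp[c("train", "validation", "test")]),
               c(train = 92L, validation = 4L, test = 4L))
  sp2 <- split_dataset(ids, c(0.92, 0.04, 0.04), seed = 7)
  expect_identical(sp, sp2)
  expect_setequal(c(sp$train, sp$validation, sp$test), ids)
  expect_length(intersect(sp$train, sp$test), 0)

  all_train <- split_dataset(ids[1:10], c(1, 0, 0), seed = 1)
  expect_setequal(all_train$train, ids[1:10])
  expect_length(all_train$test, 0)

  expect_error(split_dataset("only", c(0.5, 0.25, 0.25)), "fewer ids")
  expect_error(split_dataset(ids, c(0.5, 0.5, 0.5)), "summing to 1")
})

test_that("ideal helix and strand geometries get their labels; short chains coil", {
  hel <- assign_secondary_structure(ideal_helix(12))
  expect_equal(unique(hel$sites$ss_label), "helix")

  str <- assign_secondary_structure(ideal_strand(10))
  expect_equal(unique(str$sites$ss_label), "sheet")

  short <- toy_record("short", cbind(c(0, 3.8, 7.6), c(0, 1, 0), 0), b = 1:3)
  expect_equal(assign_secondary_structure(short)$sites$ss_label, rep("coil", 3))
})

test_that("secondary-structure labels are rigid-motion invariant", {
  rec <- random_record(n = 40, seed = 11)
  base <- assign_secondary_structure(rec)$sites$ss_label
  expect_true(all(base %in% c("helix", "sheet", "coil")))
  th <- 0.83
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  xyz <- as.matrix(rec$sites[, c("x", "y", "z")]) %*% t(rot)
  moved <- rec
  moved$sites$x <- xyz[, 1] + 100
  moved$sites$y <- xyz[, 2] - 50
  moved$sites$z <- xyz[, 3] + 3
  expect_equal(assign_secondary_structure(moved)$sites$ss_label, base)
})

test_that("curation audit table lists one row per record", {
  fixtures <- make_curation_fixtures()
  path <- tempfile(fileext = ".tsv")
  audit <- write_curation_report(lapply(fixtures, `[[`, "record"), path)
  expect_true(file.exists(path))
  expect_equal(nrow(audit), 5L)
  expect_equal(sum(audit$accepted), 1L)
})
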