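pdb3 <- c(
  "CRYST1  100.000  100.000  100.000  90.00  90.00  90.00 P 1           1",
  "ATOM      1  N   ALA A 130      11.104   6.134  -6.504  1.00  0.00           N",
  "ATOM      2  CA  ALA A 130      12.560   6.351  -6.510  1.00  0.00           C",
  "ATOM      3  C   ALA A 130      13.240   5.122  -7.120  1.00  0.00           C",
  "END")

test_that("PDB structures round-trip with names, box and coordinates intact", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb3, f)
  s <- read_structure(f)
  expect_equal(n_atoms(s), 3)
  expect_equal(s$atoms$name, c("N", "CA", "C"))
  expect_equal(s$atoms$resid, rep(130L, 3))
  expect_equal(s$box, c(100, 100, 100))
  expect_equal(coords(s)[2, ], c(12.560, 6.351, -6.510))

  # read -> write -> read is idempotent on names, resids, coords (3 dp)
  set.seed(7)
  xyz <- matrix(round(stats::runif(60, -50, 50), 3), 20, 3)
  s0 <- toy_structure(xyz, name = sample(c("CA", "CB", "P1"), 20, TRUE),
                      resname = sample(c("ALA", "POPC", "PIP2"), 20, TRUE),
                      resid = sort(sample(1:500, 20)), chain = "B",
                      box = c(80, 90, 100))
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s0, f2)
  s1 <- read_structure(f2)
  write_structure(s1, f2)
  s2 <- read_structure(f2)
  expect_identical(s1$atoms, s2$atoms)
  expect_equal(s1$atoms$name, s0$atoms$name)
  expect_equal(s1$atoms$resid, s0$atoms$resid)
  expect_equal(s1$atoms$resname, s0$atoms$resname)
  expect_equal(coords(s1), xyz, tolerance = 1e-9)
})

test_that("malformed records fail loudly, naming the offending line", {
  bad <- pdb3
  bad[3] <- "ATOM      2  CA  ALA A 130      12.5a0   6.351  -6.510  1.00  0.00           C"
  f <- withr::local_tempfile(); writeLines(bad, f)
  expect_error(read_structure(f), "line 3")

  # an overflowing coordinate shifts later fields: error, not truncation
  trunc <- pdb3
  trunc[4] <- substr(trunc[4], 1, 44)
  f2 <- withr::local_tempfile(); writeLines(trunc, f2)
  expect_error(read_structure(f2), "line 4")

  f3 <- withr::local_tempfile(); writeLines(c("REMARK nothing", "END"), f3)
  expect_error(read_structure(f3), "empty")

  ins <- pdb3
  ins[2] <- paste0(substr(ins[2], 1, 26), "A", substr(ins[2], 28, nchar(ins[2])))
  f4 <- withr::local_tempfile(); writeLines(ins, f4)
  expect_error(read_structure(f4), "insertion")
})

test_that("first alternate location is kept", {
  alt <- c(
    "ATOM      1  CA AALA A   1      10.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA BALA A   1      20.000   0.000   0.000  1.00  0.00           C",
    "END")
  f <- withr::local_tempfile(); writeLines(alt, f)
  s <- read_structure(f)
  expect_equal(n_atoms(s), 1)
  expect_equal(s$atoms$x, 10)
})

atom_line <- function(serial, resid, x, y, z) {
  sprintf("ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, resid, x, y, z)
}

test_that("multi-model PDB trajectories read frame-per-model", {
  lines <- character(0)
  for (m in 1:5) {
    lines <- c(lines, sprintf("MODEL %8d", m),
               vapply(1:10, function(i) atom_line(i, i, i + m, 0, 0),
                      character(1)),
               "ENDMDL")
  }
  f <- withr::local_tempfile(); writeLines(c(lines, "END"), f)
  topo <- read_structure(f)
  expect_equal(n_atoms(topo), 10)
  traj <- read_trajectory(f, topo, stride = 2)
  expect_equal(n_frames(traj), 5)
  expect_equal(traj$times, c(0, 2, 4, 6, 8)) # stride applied, no embedded time
  expect_equal(traj$frames[[3]][, 1], 1:10 + 3)

  # single-model file is a usable 1-frame trajectory
  f1 <- withr::local_tempfile()
  writeLines(c(vapply(1:10, function(i) atom_line(i, i, i, 0, 0),
                      character(1)), "END"), f1)
  tr1 <- read_trajectory(f1, topo)
  expect_equal(n_frames(tr1), 1)

  # a model with a missing atom names the model in the error
  broken <- character(0)
  for (m in 1:4) {
    natom <- if (m == 3) 9 else 10
    broken <- c(broken, sprintf("MODEL %8d", m),
                vapply(seq_len(natom), function(i) atom_line(i, i, i, 0, 0),
                       character(1)),
                "ENDMDL")
  }
  f2 <- withr::local_tempfile(); writeLines(broken, f2)
  expect_error(read_trajectory(f2, topo), "model 3")
})

test_that("trajectory writer embeds times and round-trips", {
  s <- toy_structure(matrix(stats::runif(30, 0, 50), 10, 3))
  frames <- lapply(1:4, function(i) matrix(round(stats::runif(30, 0, 50), 3), 10, 3))
  tr <- toy_trajectory(s, frames, times = c(0, 0.5, 1.25, 4))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(tr, f)
  tr2 <- read_trajectory(f, s)
  expect_equal(tr2$times, tr$times)
  expect_equal(tr2$frames, tr$frames, tolerance = 1e-9)

  ff <- withr::local_tempfile(fileext = ".txt")
  write_frames(tr, ff)
  tr3 <- read_trajectory(ff, s)
  expect_equal(tr3$times, tr$times)
  expect_equal(tr3$frames, tr$frames, tolerance = 1e-9)
  s3 <- read_structure(ff)
  expect_equal(n_atoms(s3), 10)
})

test_that("selection grammar resolves names, ranges, chains and booleans", {
  resid <- rep(120:150, each = 2)
  n <- length(resid)
  s <- toy_structure(matrix(seq_len(3 * n), n, 3),
                     name = rep(c("CA", "CB"), length.out = n),
                     resname = "ALA", resid = resid, chain = "A")
  helix <- parse_selection("name CA and resid 130-146", s)
  expect_length(helix$indices, 17) # the 17-residue helix window
  expect_equal(sort(unique(s$atoms$resid[helix$indices])), 130:146)

  lipids <- membrane_fixture()
  lsel <- parse_selection("resname POPC POPS PIP2", lipids)
  expect_equal(lsel$indices, 1:4)

  # 'not' equals the complement on a 20-atom fixture
  s20 <- toy_structure(matrix(1:60, 20, 3),
                       resname = rep(c("TIP3", "ALA"), 10))
  water <- parse_selection("resname TIP3", s20)
  notw <- parse_selection("not resname TIP3", s20)
  expect_equal(notw$indices, setdiff(1:20, water$indices))

  both <- parse_selection("(name CA and resid 120-125) or resid 150", s)
  expect_equal(sort(unique(s$atoms$resid[both$indices])), c(120:125, 150))

  # purity: identical calls give identical index sets
  expect_identical(parse_selection("name CA and resid 130-146", s)$indices,
                   helix$indices)

  empty <- parse_selection("resid 9999", s)
  expect_length(empty$indices, 0)
  expect_match(empty$label, "\\[empty\\]")
})

test_that("selection syntax errors point at the offending position", {
  s <- toy_structure(matrix(1:30, 10, 3))
  err <- tryCatch(parse_selection("name CA and bogus X", s),
                  error = function(e) conditionMessage(e))
  expect_match(err, "\\^")
  expect_match(err, "bogus")
  expect_error(parse_selection("resid", s), "needs at least one value")
  expect_error(parse_selection("(name CA", s), "expected '\\)'")
})

test_that("TSV tables write headers, 6 significant digits, and round-trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  rows <- data.frame(id = c("a", "b"), value = c(1.23456789, 3.14159265),
                     n = c(1L, 2L))
  write_table(rows, f)
  expect_length(readLines(f), 3)
  back <- read_table_tsv(f)
  expect_equal(back$value, signif(rows$value, 6), tolerance = 1e-12)
  expect_identical(back$id, rows$id)

  write_table(rows[0, ], f)
  expect_length(readLines(f), 1) # header only
})
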