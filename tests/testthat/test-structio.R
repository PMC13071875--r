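test_that("a single well-formed ATOM line parses into one atom with its coordinates", {
  s <- read_structure(paste(atom_line(x = 1, y = 2, z = 3), "END", sep = "\n"))
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(unname(coords(s)[1, ]), c(1, 2, 3))
  expect_equal(s$atoms$charge, 0)
  expect_equal(s$atoms$radius, vdw_radius("C"))
})

test_that("only the first model of a multi-model file is read", {
  lines <- c("MODEL     1",
             sapply(1:5, function(i) atom_line(i, resno = i, x = i)),
             "ENDMDL",
             "MODEL     2",
             sapply(1:5, function(i) atom_line(i, resno = i, x = i + 50)),
             "ENDMDL", "END")
  s <- read_structure(paste(lines, collapse = "\n"))
  expect_equal(nrow(s$atoms), 5L)
  expect_equal(s$atoms$x, as.numeric(1:5))
})

test_that("malformed and empty PDB input raise informative errors", {
  expect_error(read_structure("ATOM      1  CA  ALA A   1     bad\nEND"),
               "line 1")
  expect_error(read_structure("HEADER junk\nEND"), "empty input")
})

test_that("write/read round-trips preserve coordinates to PDB precision", {
  toy <- toy_fixture_fast(seed = 3)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(toy$receptor, f)
  s2 <- read_structure(f)
  expect_equal(coords(s2), round(coords(toy$receptor), 3),
               ignore_attr = TRUE)
  # idempotence: a second round trip changes nothing
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s2, f2)
  expect_equal(coords(read_structure(f2)), coords(s2), ignore_attr = TRUE)
})

test_that("select_within uses a closed boundary and matches a brute-force scan", {
  atoms <- data.frame(x = c(5, 19.9, 20.1), y = 0, z = 0, element = "C")
  s <- make_structure(atoms)
  expect_equal(nrow(select_within(s, c(0, 0, 0), 20)$atoms), 2L)
  # cutoff 0 with no atom at the center
  expect_equal(nrow(select_within(s, c(1, 1, 1), 0)$atoms), 0L)
  # random fixture against an independent distance scan
  set.seed(11)
  xyz <- matrix(runif(300, -12, 12), 100, 3)
  s2 <- make_structure(data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                  element = "C"))
  got <- nrow(select_within(s2, c(0, 0, 0), 8)$atoms)
  want <- sum(sqrt(rowSums(xyz^2)) <= 8)
  expect_equal(got, want)
})

test_that("select_within is monotone in the cutoff and respects chain filters", {
  set.seed(4)
  xyz <- matrix(runif(150, -10, 10), 50, 3)
  s <- make_structure(data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                 element = "C",
                                 chain_id = rep(c("A", "B"), 25)))
  for (r in c(2, 5, 8, 12)) {
    inner <- select_within(s, c(0, 0, 0), r)$atoms$serial
    outer <- select_within(s, c(0, 0, 0), r + 3)$atoms$serial
    expect_true(all(inner %in% outer))
  }
  only_a <- select_within(s, c(0, 0, 0), 50, chains = "A")$atoms
  expect_true(all(only_a$chain_id == "A"))
  expect_equal(nrow(only_a), 25L)
})

test_that("box_from_atom centers the box on the unique matching atom", {
  lines <- paste(atom_line(1, name = "CZ", resid = "ARG", chain = "A",
                           resno = 266, x = 10, y = 10, z = 10), "END",
                 sep = "\n")
  s <- read_structure(lines)
  b <- box_from_atom(s, "A", 266, "CZ", edge = 15)
  expect_equal(b$center, c(10, 10, 10))
  expect_equal(unname(box_bounds(b)[, 1]), c(2.5, 17.5))
  expect_error(box_from_atom(s, "A", 266, "CA"), "no atom matches")
})

test_that("duplicate matches for the box atom are an ambiguity error, never a silent pick", {
  dup <- make_structure(data.frame(
    x = c(0, 1), y = 0, z = 0, element = "C", name = "CZ",
    chain_id = "A", residue_number = 266, residue_name = "ARG"))
  expect_error(box_from_atom(dup, "A", 266, "CZ"), "ambiguous")
})

test_that("a bounding sphere of radius edge*sqrt(3)/2 contains every atom inside the box", {
  set.seed(21)
  xyz <- matrix(runif(300, -8, 8), 100, 3)
  s <- make_structure(data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                 element = "C"))
  b <- search_box(c(1, -1, 0.5), edge = 7)
  bb <- box_bounds(b)
  inside <- apply(xyz, 1, function(p) all(p >= bb[1, ]) && all(p <= bb[2, ]))
  sphere <- select_within(s, b$center, b$edge * sqrt(3) / 2)$atoms$serial
  expect_true(all(s$atoms$serial[inside] %in% sphere))
})

test_that("sidecar charges are applied by serial and bad serials are rejected", {
  s <- make_structure(data.frame(x = 1:3, y = 0, z = 0, element = "C"))
  f <- withr::local_tempfile(lines = c("# serial charge", "1 0.25", "3 -0.5"))
  s2 <- apply_charges(s, read_charges(f))
  expect_equal(s2$atoms$charge, c(0.25, 0, -0.5))
  f2 <- withr::local_tempfile(lines = "9 1.0")
  expect_error(apply_charges(s, read_charges(f2)), "unknown atom serial")
})

test_that("search boxes survive a JSON round trip", {
  b <- search_box(c(1.5, -2.25, 3), edge = 12.5)
  b2 <- box_from_json(box_to_json(b))
  expect_equal(b2$center, b$center)
  expect_equal(b2$edge, b$edge)
})
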