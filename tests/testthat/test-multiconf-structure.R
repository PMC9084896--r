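# Multiconformer PDB data model and input/output.

minimal_pdb <- function() {
  c("REMARK   2 RESOLUTION.    1.60 ANGSTROMS.",
    "CRYST1   50.000   60.000   70.000  90.00  90.00  90.00 P 1",
    "ATOM      1  N   SER A   1      -0.720  -1.250   0.000  1.00 12.00           N",
    "ATOM      2  CA  SER A   1       0.000   0.000   0.000  1.00 12.00           C",
    "ATOM      3  CB ASER A   1       0.000   0.604   1.406  0.60 14.00           C",
    "ATOM      4  OG ASER A   1       0.500   1.800   2.000  0.60 14.00           O",
    "ATOM      5  CB BSER A   1       0.000   0.604   1.406  0.40 15.00           C",
    "ATOM      6  OG BSER A   1      -0.700   1.700   1.900  0.40 15.00           O",
    "END")
}

test_that("altloc groups assemble into conformers with shared blank atoms", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(minimal_pdb(), f)
  m <- read_pdb(f)
  expect_length(m$residues, 1)
  res <- m$residues[[1]]
  expect_length(res$conformers, 2)
  expect_equal(vapply(res$conformers, `[[`, "", "altloc"), c("A", "B"))
  expect_equal(vapply(res$conformers, `[[`, 0, "occupancy"), c(0.6, 0.4))
  # blank-altloc backbone replicated into both conformers
  for (cf in res$conformers) expect_true(all(c("N", "CA") %in% cf$atoms$name))
  expect_equal(m$resolution, 1.6)
  expect_equal(m$space_group, "P 1")
  expect_equal(m$cell, c(50, 60, 70, 90, 90, 90))
})

test_that("files without altlocs give one conformer per residue", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(minimal_pdb()[c(1:4)], f)  # header + N, CA only
  m <- read_pdb(f)
  expect_length(m$residues[[1]]$conformers, 1)
  expect_equal(m$residues[[1]]$conformers[[1]]$occupancy, 1.0)
})

test_that("malformed coordinate records report the line number", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(minimal_pdb()[1:3], "ATOM      9  CA  SER A   2     bad"), f)
  expect_error(read_pdb(f), "line 4")
})

test_that("write/read round-trip preserves the model", {
  pr <- small_pair()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(pr$holo, f)
  m2 <- read_pdb(f, id = pr$holo$id)
  expect_equal(length(m2$residues), length(pr$holo$residues))
  expect_equal(length(m2$ligands), length(pr$holo$ligands))
  expect_equal(m2$resolution, pr$holo$resolution, tolerance = 1e-6)
  expect_equal(m2$cell, pr$holo$cell, tolerance = 1e-3)
  for (i in seq_along(m2$residues)) {
    a <- pr$holo$residues[[i]]; b <- m2$residues[[i]]
    expect_identical(b$aa, a$aa)
    expect_identical(b$seqnum, a$seqnum)
    expect_length(b$conformers, length(a$conformers))
    for (k in seq_along(a$conformers)) {
      ca <- a$conformers[[k]]; cb <- b$conformers[[k]]
      expect_lt(abs(cb$occupancy - ca$occupancy), 0.0051)
      expect_equal(sort(cb$atoms$name), sort(ca$atoms$name))
      ord_a <- order(ca$atoms$name); ord_b <- order(cb$atoms$name)
      expect_lt(max(abs(as.matrix(cb$atoms[ord_b, c("x", "y", "z")]) -
                          as.matrix(ca$atoms[ord_a, c("x", "y", "z")]))),
                5.1e-4)
      expect_lt(max(abs(cb$atoms$b[ord_b] - ca$atoms$b[ord_a])), 0.0051)
    }
  }
})

test_that("occupancy and altloc columns are written at fixed positions", {
  res <- two_centroid_residue(q = c(0.6, 0.4))
  m <- structure_model("t", list(res), cell = c(50, 50, 50, 90, 90, 90))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, f)
  lines <- grep("^ATOM", readLines(f), value = TRUE)
  cb_a <- lines[grepl("CB A", lines)]
  expect_length(cb_a, 1)
  expect_identical(substr(cb_a, 55, 60), "  0.60")
  expect_identical(substr(cb_a, 17, 17), "A")
  expect_error(write_pdb(structure_model("bad", list(multiconf_residue(
    "A", 1, "SER", list(conformer("", 1, atom_table(
      "TOOLONG", "C", 0, 0, 0)))))), withr::local_tempfile()),
    "longer than 4")
})

test_that("residue occupancy invariants are enforced", {
  expect_error(multiconf_residue("A", 1, "SER", list(
    conformer("A", 0.7, atom_table("CB", "C", 0, 0, 0, altloc = "A")),
    conformer("B", 0.5, atom_table("CB", "C", 1, 0, 0, altloc = "B")))),
    "sum")
  expect_error(conformer("A", 0, atom_table("CB", "C", 0, 0, 0)), "occupancy")
  expect_error(atom_table("CB", "", 0, 0, 0), "element")
})

test_that("split_by_altloc covers every atom once per output with fallback", {
  # residue 1 has altlocs {A,B,C}; residue 2 has {A,B} with B the major
  # conformer; the C model must use residue 2's highest-occupancy conformer
  mk_res <- function(seqnum, labs, occs) {
    cfs <- lapply(seq_along(labs), function(i) conformer(
      labs[i], occs[i], atom_table(c("CA", "CB"), "C",
                                   x = c(0, i) + 10 * seqnum, y = 0, z = 0,
                                   occupancy = c(1, occs[i]),
                                   altloc = c("", labs[i]))))
    multiconf_residue("A", seqnum, "SER", cfs)
  }
  m <- structure_model("s", list(mk_res(1, c("A", "B", "C"), c(0.5, 0.3, 0.2)),
                                 mk_res(2, c("A", "B"), c(0.4, 0.6))))
  sp <- split_by_altloc(m)
  expect_named(sp, c("A", "B", "C"))
  for (s in sp) for (r in s$residues) expect_length(r$conformers, 1)
  expect_equal(sp$C$residues[[2]]$conformers[[1]]$altloc, "B")  # fallback
  # brute-force coverage: every labelled atom appears in exactly one output,
  # blank atoms in every output, no duplicates within one output
  for (s in sp) {
    at <- do.call(rbind, lapply(s$residues, confhet:::residue_atoms_unique))
    expect_false(any(duplicated(paste(at$x, at$y, at$z, at$name))))
  }
  labelled_x <- unlist(lapply(m$residues, function(r) lapply(r$conformers,
    function(cf) cf$atoms$x[cf$atoms$altloc != ""])))
  seen <- unlist(lapply(sp, function(s) lapply(s$residues, function(r)
    r$conformers[[1]]$atoms$x[r$conformers[[1]]$atoms$altloc != ""])))
  expect_true(all(labelled_x %in% seen))
})

test_that("a model without altlocs splits into one identical copy", {
  m <- structure_model("s", list(multiconf_residue("A", 1, "SER", list(
    conformer("", 1, atom_table("CA", "C", 0, 0, 0))))))
  sp <- split_by_altloc(m)
  expect_length(sp, 1)
  expect_equal(sp[[1]]$residues, m$residues)
})
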