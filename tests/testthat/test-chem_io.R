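test_that("read_sdf parses V2000 records, charges and vdW parameters", {
  path <- withr::local_tempfile(fileext = ".sdf")
  write_methane_sdf(path, charges = c(-0.4, 0.1, 0.1, 0.1, 0.1))
  mols <- read_sdf(path)
  expect_length(mols, 1L)
  m <- mols[[1]]
  expect_equal(m$id, "methane")
  expect_equal(nrow(m$atoms), 5L)
  expect_equal(m$atoms$element, c("C", "H", "H", "H", "H"))
  expect_equal(m$atoms$charge, c(-0.4, 0.1, 0.1, 0.1, 0.1))
  # vdW parameters come from the packaged table
  tab <- default_vdw_table()
  expect_equal(m$atoms$rmin[1], tab$rmin[tab$element == "C"])
  expect_equal(m$atoms$epsilon[2], tab$epsilon[tab$element == "H"])
})

test_that("read_sdf falls back to Gasteiger-type charges", {
  path <- withr::local_tempfile(fileext = ".sdf")
  write_methane_sdf(path)  # no charge property
  m <- read_sdf(path)[[1]]
  expect_true(all(is.finite(m$atoms$charge)))
  # PEOE conserves total charge (neutral molecule) and pulls electron
  # density toward carbon relative to hydrogen
  expect_equal(sum(m$atoms$charge), 0, tolerance = 1e-10)
  expect_lt(m$atoms$charge[1], m$atoms$charge[2])
  # determinism
  expect_identical(m$atoms$charge, read_sdf(path)[[1]]$atoms$charge)
})

test_that("read_sdf error and edge contracts", {
  empty <- withr::local_tempfile(fileext = ".sdf")
  writeLines("", empty)
  expect_warning(mols <- read_sdf(empty), "empty")
  expect_length(mols, 0L)

  bad <- withr::local_tempfile(fileext = ".sdf")
  write_methane_sdf(bad, carbon = "Xx")
  expect_error(read_sdf(bad), "no vdW parameters for Xx")

  trunc <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c("broken", "", "", "  9  0", "$$$$"), trunc)
  expect_error(read_sdf(trunc), "record 1")
})

test_that("SDF round trip preserves structure to 1e-4 A", {
  set.seed(7)
  mols <- make_series(4, seed = 11)$molecules
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(mols, path)
  back <- read_sdf(path)
  expect_length(back, 4L)
  for (i in seq_along(mols)) {
    expect_equal(back[[i]]$id, mols[[i]]$id)
    expect_equal(back[[i]]$atoms$element, mols[[i]]$atoms$element)
    expect_lt(max(abs(coords(back[[i]]) - coords(mols[[i]]))), 1e-4)
    expect_equal(back[[i]]$atoms$charge, mols[[i]]$atoms$charge,
                 tolerance = 1e-5)
  }
})

test_that("to_pic50 converts units and is strictly decreasing", {
  expect_equal(to_pic50(1e-6, "M"), 6)
  expect_equal(to_pic50(1, "M"), 0)
  expect_equal(to_pic50(50, "nM"), 7.30103, tolerance = 1e-6)
  expect_equal(to_pic50(1, "uM"), to_pic50(1000, "nM"))
  expect_error(to_pic50(0, "M"), "positive")
  expect_error(to_pic50(-1, "nM"), "positive")
  vals <- sort(10^runif(25, -3, 3))
  expect_true(all(diff(to_pic50(vals, "uM")) < 0))
})

test_that("read_activities handles both CSV layouts", {
  p1 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,pIC50", "a,6.5", "b,7.1"), p1)
  expect_equal(read_activities(p1)$pIC50, c(6.5, 7.1))
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,value,unit", "a,50,nM", "b,1,uM"), p2)
  acts <- read_activities(p2)
  expect_equal(acts$pIC50, c(to_pic50(50, "nM"), 6))
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,act", "a,1"), p3)
  expect_error(read_activities(p3), "columns")
})

test_that("alignment removes rigid motion and recovers known rotations", {
  ref <- make_series(2, seed = 3)$molecules[[1]]
  tmap <- template_map(seq_len(nrow(ref$atoms)))

  aligned <- align_to_template(ref, ref, tmap)
  expect_equal(attr(aligned, "alignment_rmsd"), 0, tolerance = 1e-10)

  shifted <- ref
  shifted$atoms$x <- shifted$atoms$x + 5
  al <- align_to_template(shifted, ref, tmap)
  expect_equal(attr(al, "alignment_rmsd"), 0, tolerance = 1e-9)
  expect_equal(coords(al), coords(ref), tolerance = 1e-9)

  # rotate 90 degrees about z: recovered rotation must invert it
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  rot <- ref
  xyz <- coords(ref) %*% t(Rz)
  rot$atoms$x <- xyz[, 1]; rot$atoms$y <- xyz[, 2]; rot$atoms$z <- xyz[, 3]
  al2 <- align_to_template(rot, ref, tmap)
  expect_lt(max(abs(attr(al2, "rotation") %*% Rz - diag(3))), 1e-8)
  expect_equal(coords(al2), coords(ref), tolerance = 1e-8)
})

test_that("alignment never changes intramolecular distances", {
  mols <- make_series(5, seed = 21)$molecules
  tmap <- template_map(1:10)
  ref <- mols[[1]]
  for (m in mols[-1]) {
    shifted <- m
    shifted$atoms$x <- shifted$atoms$x + 3.3
    shifted$atoms$z <- shifted$atoms$z - 1.1
    al <- align_to_template(shifted, ref, tmap)
    expect_lt(max(abs(dist(coords(al)) - dist(coords(m)))), 1e-9)
  }
})

test_that("degenerate template maps are rejected", {
  ref <- one_atom_mol()
  lin <- molecule("lin", data.frame(element = c("C", "C", "C"),
                                    x = 0:2, y = 0, z = 0))
  expect_error(template_map(1:2), "at least 3")
  expect_error(template_map(c(1, 1, 2)), "injective")
  expect_error(align_to_template(lin, lin, template_map(1:3)), "collinear")
})
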