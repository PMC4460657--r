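test_that("build_grid spans the bounding box inclusively", {
  m <- one_atom_mol(pos = c(0, 0, 0))
  g <- build_grid(list(m), spacing = 2, margin = 4)
  expect_equal(g$counts, c(5L, 5L, 5L))
  expect_equal(n_grid_points(g), 125L)
  pts <- grid_points(g)
  expect_equal(sort(unique(pts[, 1])), c(-4, -2, 0, 2, 4))
  # x-fastest enumeration
  expect_equal(pts[1:5, 1], c(-4, -2, 0, 2, 4))
  expect_equal(pts[1:5, 2], rep(-4, 5))

  g0 <- build_grid(list(m), spacing = 2, margin = 0)
  expect_equal(g0$counts, c(1L, 1L, 1L))
})

test_that("the grid contains every atom of every molecule within margin", {
  mols <- make_series(6, seed = 5)$molecules
  g <- build_grid(mols, spacing = 2, margin = 4)
  pts <- grid_points(g)
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  for (m in mols) {
    expect_true(all(t(coords(m)) >= lo - 1e-9))
    expect_true(all(t(coords(m)) <= hi + 2 + 1e-9))  # endpoint rounding
  }
})

test_that("steric field matches the Lennard-Jones closed form", {
  probe <- probe_spec()  # sp3 carbon
  atom <- one_atom_mol(element = "C")
  Rij <- 1.70 + probe$rmin
  eps <- sqrt(0.107 * probe$epsilon)

  at_min <- grid_spec(c(Rij, 0, 0), 1, c(1, 1, 1))
  expect_equal(steric_field(atom, at_min, probe), -eps, tolerance = 1e-12)

  far <- grid_spec(c(50, 0, 0), 1, c(1, 1, 1))
  expect_lt(abs(steric_field(atom, far, probe)), 1e-6)

  core <- grid_spec(c(0.1 * Rij, 0, 0), 1, c(1, 1, 1))
  expect_equal(steric_field(atom, core, probe), 30)

  on_top <- grid_spec(c(0, 0, 0), 1, c(1, 1, 1))
  expect_equal(steric_field(atom, on_top, probe), 30)  # r = 0, no error
})

test_that("electrostatic field matches the Coulomb closed form", {
  probe <- probe_spec(charge = 1)
  atom <- one_atom_mol(charge = 1)
  g <- grid_spec(c(3.320636, 0, 0), 1, c(1, 1, 1))
  # unclamped closed form: 332.0636 / 3.320636 = 100 kcal/mol
  expect_equal(electrostatic_field(atom, g, probe, cutoff = Inf), 100,
               tolerance = 1e-6)
  # the default truncation bound caps the same point at +30
  expect_equal(electrostatic_field(atom, g, probe), 30)

  # distance-dependent dielectric divides by r twice
  expect_equal(electrostatic_field(atom, g, probe, "distance", cutoff = Inf),
               100 / 3.320636, tolerance = 1e-6)

  neutral <- one_atom_mol(charge = 0)
  g2 <- build_grid(list(neutral), spacing = 2, margin = 4)
  expect_true(all(electrostatic_field(neutral, g2, probe) == 0))

  # sign flip of the probe charge negates all values
  mol <- one_atom_mol(charge = 0.37, pos = c(0.5, -0.2, 1))
  g3 <- build_grid(list(mol), spacing = 2, margin = 4)
  expect_equal(electrostatic_field(mol, g3, probe_spec(charge = -1)),
               -electrostatic_field(mol, g3, probe_spec(charge = 1)))

  # clamped at +-cutoff near the nucleus
  close <- grid_spec(c(1e-3, 0, 0), 1, c(1, 1, 1))
  expect_equal(electrostatic_field(atom, close, probe), 30)
  expect_equal(electrostatic_field(one_atom_mol(charge = -1), close, probe),
               -30)
})

test_that("fields are translation invariant and electrostatics superpose", {
  set.seed(42)
  mol <- make_series(3, seed = 42)$molecules[[2]]
  g <- build_grid(list(mol), spacing = 2.5, margin = 3)
  s0 <- steric_field(mol, g)
  e0 <- electrostatic_field(mol, g)

  shift <- c(7.1, -2.2, 3.9)
  mol2 <- mol
  mol2$atoms$x <- mol2$atoms$x + shift[1]
  mol2$atoms$y <- mol2$atoms$y + shift[2]
  mol2$atoms$z <- mol2$atoms$z + shift[3]
  g2 <- grid_spec(g$origin + shift, g$spacing, g$counts)
  expect_lt(max(abs(steric_field(mol2, g2) - s0)), 1e-9)
  expect_lt(max(abs(electrostatic_field(mol2, g2) - e0)), 1e-9)

  # superposition: two-atom field = sum of single-atom fields (oracle)
  two <- molecule("two", data.frame(element = c("N", "O"),
                                    x = c(0, 1.4), y = 0, z = 0,
                                    charge = c(0.3, -0.3)))
  two <- assign_vdw(two)
  ga <- grid_spec(c(-2, -2, -2), 1.7, c(4, 4, 4))
  singles <- lapply(1:2, function(i) {
    m <- molecule(paste0("s", i), two$atoms[i, , drop = FALSE])
    electrostatic_field(m, ga, cutoff = Inf)
  })
  expect_equal(electrostatic_field(two, ga, cutoff = Inf),
               singles[[1]] + singles[[2]], tolerance = 1e-10)
})

test_that("steric values are bounded by the cutoff and attain it in cores", {
  mol <- make_series(3, seed = 9)$molecules[[1]]
  g <- build_grid(list(mol), spacing = 1, margin = 2)
  s <- steric_field(mol, g)
  expect_true(all(s <= 30))
  # points essentially on atom centres must be clamped
  pts <- grid_points(g)
  d <- sqrt(outer(rowSums(pts^2), rowSums(coords(mol)^2), "+") -
              2 * pts %*% t(coords(mol)))
  inside <- apply(d, 1, min) < 0.5
  expect_true(any(inside))
  expect_true(all(s[inside] == 30))
})

test_that("fields require assigned parameters", {
  bare <- molecule("b", data.frame(element = "C", x = 0, y = 0, z = 0))
  g <- grid_spec(c(1, 1, 1), 1, c(2, 2, 2))
  expect_error(steric_field(bare, g), "vdW")
  expect_error(electrostatic_field(bare, g), "charges")
})
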