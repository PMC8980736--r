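# Pocket extraction and voxel encoding.

test_that("read_structure parses records, infers elements and resolves altlocs", {
  atoms <- read_structure(fixture_complex_pdb())
  expect_s3_class(atoms, "structure_atoms")
  expect_equal(nrow(atoms), 7L)
  expect_setequal(unique(atoms$class), c("protein", "hetero", "water"))
  expect_equal(atoms$element[atoms$name == "CA"], "C")
  expect_equal(atoms$element[atoms$name == "SG"], "S")

  # element column absent -> inferred from the atom name
  no_el <- pdb_text(pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, element = ""))
  expect_equal(read_structure(no_el)$element, "C")

  # two altloc records for one atom: highest occupancy wins
  alt <- pdb_text(
    pdb_line(1, "CA", "ALA", "A", 1, 1.0, 0, 0, occ = 0.6, element = "C", alt = "A"),
    pdb_line(2, "CA", "ALA", "A", 1, 2.0, 0, 0, occ = 0.4, element = "C", alt = "B")
  )
  got <- read_structure(alt)
  expect_equal(nrow(got), 1L)
  expect_equal(got$x, 1.0)
  expect_equal(got$alt, "A")

  # occupancy tie: first record wins
  tie <- pdb_text(
    pdb_line(1, "CA", "ALA", "A", 1, 1.0, 0, 0, occ = 0.5, element = "C", alt = "A"),
    pdb_line(2, "CA", "ALA", "A", 1, 2.0, 0, 0, occ = 0.5, element = "C", alt = "B")
  )
  expect_equal(read_structure(tie)$x, 1.0)

  expect_error(read_structure(pdb_text("")), "empty structure|unparseable")
})

test_that("water-only structures contribute no pocket atoms", {
  wat <- pdb_text(
    pdb_line(1, "O", "HOH", "A", 1, 0, 0, 0, element = "O", type = "HETATM"),
    pdb_line(2, "O", "HOH", "A", 2, 1, 1, 1, element = "O", type = "HETATM")
  )
  atoms <- read_structure(wat)
  expect_equal(nrow(select_pocket_atoms(atoms, c(0, 0, 0))), 0L)
})

test_that("pocket_center is the unweighted heavy-atom centroid", {
  one <- data.frame(element = "C", x = 1, y = 2, z = 3)
  expect_equal(unname(pocket_center(one)), c(1, 2, 3))

  two <- data.frame(element = c("C", "C"), x = c(0, 2), y = 0, z = 0)
  expect_equal(unname(pocket_center(two)), c(1, 0, 0))

  # hexagon symmetric about the origin
  th <- (0:5) * pi / 3
  ring <- data.frame(element = "C", x = cos(th), y = sin(th), z = 0)
  expect_equal(unname(pocket_center(ring)), c(0, 0, 0), tolerance = 1e-12)

  # hydrogens are ignored; heavy-atom-free input errors
  hyd <- data.frame(element = c("C", "H"), x = c(1, 100), y = 0, z = 0)
  expect_equal(unname(pocket_center(hyd))[1], 1)
  expect_error(pocket_center(data.frame(element = "H", x = 0, y = 0, z = 0)),
               "no heavy atoms")
})

test_that("select_pocket_atoms applies the half-open cube and class filter", {
  center <- c(0, 0, 0)
  atoms <- data.frame(
    element = "C",
    x = c(0, 10.1, 9.9, -9.9, 10.0),
    y = c(0, 0, 9.9, -9.9, 0),
    z = c(0, 0, 9.9, -9.9, 0),
    class = "protein"
  )
  sel <- select_pocket_atoms(atoms, center)
  # at center: in; +10.1: out; corner 9.9: in; corner -9.9: in; face 10.0: out
  expect_equal(sel$x, c(0, 9.9, -9.9))

  mixed <- data.frame(element = "C", x = 0, y = 0, z = 0,
                      class = c("protein", "hetero", "water"))
  expect_equal(nrow(select_pocket_atoms(mixed, center)), 1L)
  expect_equal(nrow(select_pocket_atoms(mixed, center, include_hetero = TRUE)), 2L)
})

test_that("element_channel follows the fixed pocket channel order", {
  expect_equal(element_channel("C"), 1L)
  expect_equal(element_channel("O"), 2L)
  expect_equal(element_channel("N"), 3L)
  expect_equal(element_channel("S"), 4L)
  expect_equal(element_channel("P"), 5L)
  expect_equal(element_channel("H"), 6L)
  expect_equal(element_channel("FE"), 7L)
  expect_equal(element_channel(c("c", " o ")), c(1L, 2L))
  expect_error(element_channel(""), "empty")
})

test_that("voxelize builds the canonical 10x10x10x8 one-hot grid", {
  center <- c(0, 0, 0)
  empty <- voxelize(data.frame(element = character(0), x = numeric(0),
                               y = numeric(0), z = numeric(0)), center)
  expect_equal(dim(empty), c(10L, 10L, 10L, 8L))
  expect_equal(sum(empty[, , , 1]), 1000)
  expect_equal(sum(empty[, , , 2:8]), 0)
  expect_equal(length(flatten_pocket(empty)), 8000L)

  # a carbon exactly at the center lands in voxel floor(10/2)=5 (0-based)
  one <- voxelize(data.frame(element = "C", x = 0, y = 0, z = 0), center)
  expect_equal(one[6, 6, 6, 2], 1)
  expect_equal(one[6, 6, 6, 1], 0)
  expect_equal(sum(one[, , , 2:8]), 1)
  expect_equal(sum(one[, , , 1]), 999)

  # C and O sharing a voxel: channel-wise maximum keeps both
  both <- voxelize(data.frame(element = c("C", "O"),
                              x = c(0.1, 0.2), y = 0, z = 0), center)
  expect_equal(both[6, 6, 6, 2], 1)
  expect_equal(both[6, 6, 6, 3], 1)
  expect_equal(both[6, 6, 6, 1], 0)

  # atom outside the cube signals a selection/voxelization mismatch
  expect_error(voxelize(data.frame(element = "C", x = 11, y = 0, z = 0), center),
               "outside the pocket cube")

  # voxels per axis = side / resolution
  expect_equal(dim(voxelize(data.frame(element = "C", x = 0, y = 0, z = 0),
                            center, side = 16, resolution = 2))[1], 8L)
})

test_that("random grids satisfy the 0/1 and empty-channel complementarity invariants", {
  for (s in 1:200) {
    g <- voxelize(make_pocket(s), c(0, 0, 0))
    expect_true(all(g %in% c(0, 1)))
    occ <- matrix(g[, , , 2:8], nrow = 1000)
    expect_true(all((as.vector(g[, , , 1]) == 1) == (rowSums(occ) == 0)))
  }
})

test_that("voxelization is exactly equivariant under joint translation", {
  set.seed(42)
  for (rep in 1:25) {
    atoms <- make_pocket(900 + rep)
    t3 <- runif(3, -50, 50)
    shifted <- atoms
    shifted$x <- atoms$x + t3[1]
    shifted$y <- atoms$y + t3[2]
    shifted$z <- atoms$z + t3[3]
    g0 <- voxelize(atoms, c(0, 0, 0))
    g1 <- voxelize(shifted, t3)
    expect_identical(grid_values(g0), grid_values(g1))
  }
})

test_that("voxelize matches the brute-force per-atom scatter oracle", {
  for (s in 1:20) {
    atoms <- make_pocket(1200 + s, n_atoms = sample(1:20, 1))
    fast <- voxelize(atoms, c(0, 0, 0))
    slow <- brute_voxelize(atoms, c(0, 0, 0))
    expect_equal(grid_values(fast), slow)
  }
})

test_that("featurize_pocket centers on a bound ligand and voxelizes the pocket", {
  g <- featurize_pocket(fixture_complex_pdb(), ligand_resname = "LIG")
  expect_s3_class(g, "pocket_grid")
  expect_equal(attr(g, "center"), c(1, 2, 3))
  # 4 protein atoms occupy the grid; water and ligand are excluded
  expect_equal(sum(g[, , , 2:8]), 4)
  # explicit center override for apo structures
  g2 <- featurize_pocket(fixture_complex_pdb(), center = c(1, 2, 3))
  expect_identical(grid_values(g), grid_values(g2))
})
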