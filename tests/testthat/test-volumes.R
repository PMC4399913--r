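test_that("Kabsch superposition inverts exact rigid motions", {
  gpcrnet:::with_seed(121, X <- matrix(stats::rnorm(60), 20))
  tf0 <- superpose_kabsch(X, X)
  expect_lt(tf0$rmsd, 1e-12)
  expect_lt(max(abs(tf0$rotation - diag(3))), 1e-9)
  th <- 37 * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  Y <- X %*% t(R) + matrix(c(5, -3, 2), 20, 3, byrow = TRUE)
  tf <- superpose_kabsch(Y, X)
  expect_lt(tf$rmsd, 1e-9)
  expect_equal(det(tf$rotation), 1, tolerance = 1e-9)
  expect_lt(max(abs(apply_transform(Y, tf) - X)), 1e-9)
})

test_that("superposition RMSD under isotropic noise matches direct evaluation", {
  gpcrnet:::with_seed(122, {
    X <- matrix(stats::rnorm(300, sd = 8), 100)
    noise <- matrix(stats::rnorm(300, sd = 0.5), 100)
  })
  Y <- X + noise
  direct <- sqrt(mean(rowSums(noise^2)))  # RMSD of the generated set
  tf <- superpose_kabsch(Y, X)
  expect_lt(abs(tf$rmsd - direct) / direct, 0.10)
})

test_that("degenerate pairings are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(superpose_kabsch(line, line), "degenerate|collinear")
  expect_error(superpose_kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), "n >= 3")
})

test_that("single-sphere voxel volume approximates the analytic volume", {
  at <- data.frame(type = "HETATM", chain = "A", resno = 900L,
                   resid = "LIG", elety = "C1", x = 1.3, y = -2.1, z = 0.7)
  g <- ligand_volume(list(at), atom_radius = 2.0, spacing = 0.25)
  analytic <- 4 / 3 * pi * 2^3
  expect_lt(abs(grid_volume(g) - analytic) / analytic, 0.05)
  # refinement: halving the spacing changes the estimate by < 2%
  g2 <- ligand_volume(list(at), atom_radius = 2.0, spacing = 0.125)
  expect_lt(abs(grid_volume(g2) - grid_volume(g)) / grid_volume(g), 0.02)
  # union idempotence: the same structure twice gives the same grid
  g_twice <- ligand_volume(list(at, at), atom_radius = 2.0, spacing = 0.25)
  expect_equal(grid_volume(g_twice), grid_volume(g))
  expect_error(ligand_volume(list(at), ligand_resid = "ZZZ"), "empty")
})

test_that("grid overlap matches the analytic lens volume and set bounds", {
  at <- data.frame(type = "HETATM", chain = "A", resno = 900L,
                   resid = "LIG", elety = "C1", x = 0, y = 0, z = 0)
  at2 <- at; at2$x <- 2
  gA <- ligand_volume(list(at), atom_radius = 2.0, spacing = 0.25)
  gB <- ligand_volume(list(at2), atom_radius = 2.0, spacing = 0.25)
  ov <- overlap_region(gA, gB)
  r <- 2; dd <- 2
  lens <- pi * (4 * r + dd) * (2 * r - dd)^2 / 12
  expect_lt(abs(ov$volume - lens) / lens, 0.05)
  expect_lte(ov$volume, min(grid_volume(gA), grid_volume(gB)))
  # disjoint and nested cases
  at3 <- at; at3$x <- 50
  gC <- ligand_volume(list(at3), atom_radius = 2.0, spacing = 0.25)
  expect_equal(overlap_region(gA, gC)$volume, 0)
  gSmall <- ligand_volume(list(at), atom_radius = 1.0, spacing = 0.25)
  expect_equal(overlap_region(gSmall, gA)$volume, grid_volume(gSmall))
  gWrong <- ligand_volume(list(at), atom_radius = 2.0, spacing = 0.5)
  expect_error(overlap_region(gA, gWrong), "spacing")
})

test_that("volumes are stable under a common rigid transform of all inputs", {
  b <- make_toy_bundle(toy_receptor_spec(), pocket_resnos = c(40, 68, 96))
  g1 <- ligand_volume(list(b), atom_radius = 1.7, spacing = 0.5)
  at <- b$atoms
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3,
              byrow = TRUE)
  at[, c("x", "y", "z")] <-
    sweep(as.matrix(at[, c("x", "y", "z")]) %*% t(R), 2, c(3, -7, 11), "+")
  g2 <- ligand_volume(list(at), atom_radius = 1.7, spacing = 0.5)
  expect_lt(abs(grid_volume(g2) - grid_volume(g1)) / grid_volume(g1), 0.02)
})

test_that("el2 occupancy counts the planted fraction of atoms", {
  # a box-shaped target grid from one large probe atom
  probe <- data.frame(type = "HETATM", chain = "A", resno = 900L,
                      resid = "LIG", elety = "C1", x = 0, y = 0, z = 0)
  grid <- ligand_volume(list(probe), atom_radius = 4, spacing = 0.5)
  mk_atoms <- function(xyz) data.frame(
    type = "ATOM", chain = "A", resno = seq_len(nrow(xyz)), resid = "GLY",
    elety = "CA", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  inside <- matrix(stats::runif(21, -1, 1), 7)
  outside <- matrix(50 + stats::runif(9), 3)
  at <- mk_atoms(rbind(inside, outside))
  expect_equal(el2_occupancy(at, 1:10, grid), 0.7)
  expect_equal(el2_occupancy(mk_atoms(inside), 1:7, grid), 1.0)
  expect_equal(el2_occupancy(mk_atoms(outside), 1:3, grid), 0.0)
  expect_error(el2_occupancy(at, integer(0), grid), "empty")
})

test_that("7TM superposition pairs shared BW positions across bundles", {
  b1 <- make_toy_bundle(toy_receptor_spec(), name = "r1")
  b2 <- make_toy_bundle(toy_receptor_spec(n_res = c(24L, 22L, rep(24L, 5))),
                        name = "r2")
  tf <- superpose_7tm(b1, b1)
  expect_lt(tf$rmsd, 1e-9)
  tf2 <- superpose_7tm(b2, b1)
  expect_true(is.finite(tf2$rmsd))
})
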