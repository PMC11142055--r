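test_that("a convex mutually-contacting atom cluster has no pocket", {
  a <- 1.8
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * a / 2
  atoms <- data.frame(serial = 1:4, element = "C",
                      x = v[, 1], y = v[, 2], z = v[, 3], radius = 1.7,
                      residue_name = "LEU", residue_seq = 1:4,
                      chain_id = "A", is_heteroatom = FALSE)
  s <- new_structure_for_test(atoms)
  expect_length(detect_pockets(s, 1.4), 0)
})

test_that("cavity fixtures yield the constructed pocket, void and mouth counts", {
  open <- open_cavity()
  expect_length(open$pockets, 1)
  expect_equal(open$pockets[[1]]$n_mouths, 1)

  closed <- closed_cavity()
  expect_length(closed$pockets, 1)
  expect_equal(closed$pockets[[1]]$n_mouths, 0)    # interior void

  double <- double_cavity()
  expect_length(double$pockets, 1)
  expect_equal(double$pockets[[1]]$n_mouths, 2)
})

test_that("void volume matches the analytic sphere oracle within 20%", {
  for (fix in list(open_cavity(), closed_cavity())) {
    expected <- attr(fix$structure, "analytic_void_volume")
    expect_lt(abs(fix$pockets[[1]]$volume - expected) / expected, 0.2)
  }
})

test_that("pocket measurement derives residues and polarity from member atoms", {
  p <- open_cavity()$pockets[[1]]
  expect_true(p$area > 0)
  expect_true(p$volume > 0)
  # lining is 2/3 SER by construction
  expect_gte(p$polar_residue_count, 2)
  expect_equal(nrow(p$residues), nrow(p$atoms))   # one pseudo-residue per atom
  # a purely aliphatic lining has zero polar residues
  s <- make_cavity_structure(interior_radius = 5, opening_half_angles = 30,
                             atom_spacing = 2.2, lining = c("LEU", "VAL"),
                             seed = 4)
  pk <- detect_pockets(s, 1.4)
  expect_length(pk, 1)
  expect_equal(pk[[1]]$polar_residue_count, 0)
})

test_that("pocket volumes never exceed the convex hull volume", {
  for (fix in list(open_cavity(), closed_cavity(), double_cavity())) {
    total <- sum(vapply(fix$pockets, function(p) p$volume, numeric(1)))
    expect_lte(total, attr(fix$pockets, "hull_volume"))
  }
})

test_that("detection is invariant under rigid rotation and translation", {
  fix <- open_cavity()
  R <- rotation_xyz(0.4, -0.9, 1.3)
  s2 <- rotate_structure(fix$structure, R, shift = c(7, -12, 3))
  pk2 <- detect_pockets(s2, 1.4)
  expect_length(pk2, length(fix$pockets))
  p1 <- fix$pockets[[1]]; p2 <- pk2[[1]]
  expect_lt(abs(p1$area - p2$area) / p1$area, 1e-6)
  expect_lt(abs(p1$volume - p2$volume) / p1$volume, 1e-6)
  expect_equal(p2$n_mouths, p1$n_mouths)
  expect_identical(p2$atom_index, p1$atom_index)
})

test_that("growing the probe never increases the pocket count", {
  s <- open_cavity()$structure
  counts <- vapply(c(1.0, 1.4, 1.9, 2.5), function(pr) {
    length(detect_pockets(s, pr))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("druggability filter applies area, polar and mouth criteria in order", {
  mk <- function(area, polar, mouths) {
    structure(list(pocket_id = 1L, area = area,
                   polar_residue_count = polar, n_mouths = mouths,
                   volume = 100, atoms = data.frame(serial = 1)),
              class = "pocket_surface")
  }
  res <- filter_druggable(list(mk(499, 3, 1)))
  expect_equal(res$rejected$reason, "area")      # 500 threshold is strict
  res <- filter_druggable(list(mk(600, 1, 1)))
  expect_equal(res$rejected$reason, "polar")
  res <- filter_druggable(list(mk(600, 2, 2)))
  expect_equal(res$rejected$reason, "mouth")
  res <- filter_druggable(list(mk(600, 2, 1)))
  expect_length(res$accepted, 1)
  expect_equal(nrow(res$rejected), 0)
  # mouth criterion can be waived
  res <- filter_druggable(list(mk(600, 2, 0)), require_single_mouth = FALSE)
  expect_length(res$accepted, 1)
})

test_that("grid flood fill agrees with the tetrahedral void classification", {
  fix <- closed_cavity()
  g <- grid_reachability(fix$structure, 1.4, spacing = 0.4)
  oracle_void <- g$free & !g$reachable
  P <- as.matrix(fix$structure$atoms[, c("x", "y", "z")])
  tets <- matrix(match(as.vector(fix$pockets[[1]]$tetra),
                       seq_len(nrow(P))), ncol = 4)
  ours <- pocketscreen:::grid_cells_in_tetra(g, P, tets) & g$free
  jacc <- sum(oracle_void & ours) / sum(oracle_void | ours)
  expect_gte(jacc, 0.95)
})
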