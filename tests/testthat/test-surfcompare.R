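test_that("shape signatures are deterministic, normalised, and scale linearly", {
  p <- open_cavity()$pockets[[1]]
  sig1 <- shape_signature(p, seed = 5)
  sig2 <- shape_signature(p, seed = 5)
  expect_identical(sig1$probabilities, sig2$probabilities)
  expect_equal(sum(sig1$probabilities), 1, tolerance = 1e-9)
  expect_true(all(diff(sig1$bin_edges) > 0))

  # doubling the surface doubles the distance support, not the shape
  surf <- unit_sphere_surface()
  s1 <- shape_signature(surf, seed = 9)
  surf2 <- list(vertices = surf$vertices * 2, triangles = surf$triangles)
  s2 <- shape_signature(surf2, seed = 9)
  expect_equal(s2$bin_edges, 2 * s1$bin_edges, tolerance = 1e-12)
  expect_equal(s2$probabilities, s1$probabilities)
})

test_that("sphere-surface distance distribution has the analytic mean chord", {
  surf <- unit_sphere_surface()
  sig <- shape_signature(surf, n_points = 512, n_pairs = 8192, seed = 21)
  expect_lt(abs(mean(sig$distances) - 4 / 3) / (4 / 3), 0.05)
})

test_that("KS statistic equals direct ECDF enumeration on small samples", {
  # {1,2,3} vs {4,5,6}: disjoint supports
  d <- ks_compare(as_shape_signature(c(1, 2, 3)), as_shape_signature(c(4, 5, 6)))
  expect_equal(d$D, 1)
  # {1,2} vs {1,3}: max gap 0.5 on [2,3)
  d <- ks_compare(as_shape_signature(c(1, 2)), as_shape_signature(c(1, 3)))
  expect_equal(d$D, 0.5)
  # identity
  sig <- as_shape_signature(c(0.3, 1.1, 2.2, 5))
  expect_equal(ks_compare(sig, sig)$D, 0)
})

test_that("KS comparison is symmetric, bounded, and matches stats::ks.test", {
  x <- with_seed_helper(3, abs(stats::rnorm(80)))
  y <- with_seed_helper(4, abs(stats::rnorm(100, 0.4)))
  a <- as_shape_signature(x); b <- as_shape_signature(y)
  f <- ks_compare(a, b); r <- ks_compare(b, a)
  expect_equal(f$D, r$D)
  expect_true(f$D >= 0 && f$D <= 1)
  ref <- suppressWarnings(stats::ks.test(x, y))
  expect_equal(f$D, unname(ref$statistic))
  expect_equal(f$p, ref$p.value, tolerance = 0.05)
})

test_that("superposition recovers identity and applied rotations", {
  fix <- open_cavity()
  cs <- chem_surface(fix$pockets[[1]], fix$structure)
  n <- nrow(cs$points)
  idcor <- cbind(seq_len(n), seq_len(n))
  al <- superpose(cs, cs, idcor)
  expect_lt(al$cRMSD, 1e-9)
  expect_lt(al$oRMSD, 1e-6)
  expect_equal(al$rotation, diag(3), tolerance = 1e-9)
  expect_equal(det(al$rotation), 1, tolerance = 1e-9)

  R <- rotation_xyz(0, 0, pi / 2)            # 90 degrees about z
  csb <- cs
  csb$points <- cs$points %*% t(R)
  csb$orientations <- cs$orientations %*% t(R)
  al2 <- superpose(cs, csb, idcor)
  expect_lt(al2$cRMSD, 1e-6)
  expect_lt(max(abs(al2$rotation %*% R - diag(3))), 1e-6)
  expect_lt(al2$oRMSD, 1e-6)
})

test_that("superposition cRMSD is symmetric and labels are enforced", {
  ch <- chiral_pair()
  idcor <- cbind(1:4, 1:4)
  ab <- superpose(ch$a, ch$b, idcor)
  ba <- superpose(ch$b, ch$a, idcor)
  expect_equal(ab$cRMSD, ba$cRMSD, tolerance = 1e-9)
  badcor <- cbind(1:4, c(1, 2, 4, 3))        # pairs mismatched labels
  expect_error(superpose(ch$a, ch$b, badcor), "label mismatch")
  expect_error(superpose(ch$a, ch$b, idcor[1:2, ]), "at least 3")
})

test_that("mirror-image superposition matches a brute-force rotation search", {
  ch <- chiral_pair()
  idcor <- cbind(1:4, 1:4)
  al <- superpose(ch$a, ch$b, idcor)
  expect_gt(al$cRMSD, 0.1)                   # chirality: no exact proper fit

  X <- sweep(ch$a$points, 2, colMeans(ch$a$points))
  Y <- sweep(ch$b$points, 2, colMeans(ch$b$points))
  rmsd_of <- function(R) sqrt(mean(rowSums((X - Y %*% t(R))^2)))
  grid_search <- function(centers, widths, step) {
    best <- Inf; arg <- centers
    for (a1 in seq(centers[1] - widths[1], centers[1] + widths[1], by = step))
      for (a2 in seq(centers[2] - widths[2], centers[2] + widths[2], by = step))
        for (a3 in seq(centers[3] - widths[3], centers[3] + widths[3], by = step)) {
          v <- rmsd_of(rotation_xyz(a1, a2, a3))
          if (v < best) { best <- v; arg <- c(a1, a2, a3) }
        }
    list(best = best, arg = arg)
  }
  coarse <- grid_search(c(0, 0, pi), c(pi, pi / 2, pi), 6 * pi / 180)
  fine <- grid_search(coarse$arg, rep(6 * pi / 180, 3), 0.25 * pi / 180)
  expect_lte(al$cRMSD, fine$best + 1e-9)     # SVD solution is optimal
  expect_lt(abs(al$cRMSD - fine$best) / al$cRMSD, 0.01)
})

test_that("random-alignment null p values behave at the boundaries", {
  fix <- open_cavity()
  cs <- chem_surface(fix$pockets[[1]], fix$structure)
  n <- nrow(cs$points)
  al <- superpose(cs, cs, cbind(seq_len(n), seq_len(n)))
  p1 <- alignment_null_pvalue(cs, cs, al, n_random = 99, seed = 2)
  expect_equal(p1, 1 / 100)                  # nothing beats cRMSD 0
  p2 <- alignment_null_pvalue(cs, cs, al, n_random = 99, seed = 2)
  expect_identical(p1, p2)                   # seed determinism
  worst <- al; worst$cRMSD <- 1e6
  expect_equal(alignment_null_pvalue(cs, cs, worst, n_random = 99, seed = 2), 1)
})

test_that("voxel Tanimoto matches analytic overlap and converges in grid", {
  a <- cube_region(); b <- cube_region(c(0.5, 0, 0))
  t1 <- volume_tanimoto(a, b, NULL, grid_spacing = 0.05)
  expect_equal(t1, 1 / 3, tolerance = 0.02)
  expect_equal(volume_tanimoto(a, a, NULL, 0.05), 1)
  expect_equal(volume_tanimoto(a, cube_region(c(10, 0, 0)), NULL, 0.1), 0)
  t2 <- volume_tanimoto(a, b, NULL, grid_spacing = 0.025)
  expect_lt(abs(t2 - t1) / t1, 0.05)         # grid convergence
  # alignment is applied to b before voxelization
  shift <- list(rotation = diag(3), translation = c(-0.5, 0, 0))
  expect_equal(volume_tanimoto(a, b, shift, 0.05), 1)
})

test_that("composite score is monotone, linear in weights, and maximal for self", {
  best <- composite_score(0, 1 / 1000, 1)
  worst <- composite_score(1, 1, 0)
  expect_equal(worst$composite, 0)
  expect_gt(best$composite, 0.99)
  w2 <- composite_score(0.3, 0.4, 0.6,
                        weights = c(shape = 2 / 3, align = 2 / 3, overlap = 2 / 3))
  w1 <- composite_score(0.3, 0.4, 0.6)
  expect_equal(w2$composite, 2 * w1$composite)
  expect_error(composite_score(0.3, 0.4, 0.6,
                               weights = c(shape = -1, align = 1, overlap = 1)),
               "negative")
  # monotone: any component worsening lowers the score
  expect_gt(composite_score(0.2, 0.4, 0.6)$composite,
            composite_score(0.5, 0.4, 0.6)$composite)
  expect_gt(composite_score(0.2, 0.4, 0.6)$composite,
            composite_score(0.2, 0.8, 0.6)$composite)
  expect_gt(composite_score(0.2, 0.4, 0.6)$composite,
            composite_score(0.2, 0.4, 0.3)$composite)
})

test_that("a pocket is at least as similar to itself as to a different pocket", {
  fix <- open_cavity()
  small <- cached("small_cavity", {
    s <- make_cavity_structure(interior_radius = 4, opening_half_angles = 45,
                               atom_spacing = 2.0, seed = 6)
    list(structure = s, pockets = detect_pockets(s, 1.4))
  })
  score_vs <- function(pa, sa, pb, sb) {
    siga <- shape_signature(pa, seed = 31)
    sigb <- shape_signature(pb, seed = 32)
    ks <- ks_compare(siga, sigb)
    ca <- chem_surface(pa, sa); cb <- chem_surface(pb, sb)
    cor <- derive_correspondence(ca, cb)
    al <- superpose(ca, cb, cor)
    pv <- alignment_null_pvalue(ca, cb, al, n_random = 99, seed = 7)
    tan <- volume_tanimoto(pa, pb, al, grid_spacing = 0.5)
    composite_score(ks$D, pv, tan)$composite
  }
  p <- fix$pockets[[1]]; s <- fix$structure
  q <- small$pockets[[1]]; sq <- small$structure
  expect_gt(score_vs(p, s, p, s), score_vs(p, s, q, sq))
})
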