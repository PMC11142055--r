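# Shared fixtures, built in code and cached per test run (pocket detection
# on a ~200-atom shell takes about a second; several tests reuse the same
# geometry).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

open_cavity <- function() cached("open_cavity", {
  s <- make_cavity_structure(interior_radius = 6, opening_half_angles = 30,
                             atom_spacing = 2.2, seed = 1)
  list(structure = s, pockets = detect_pockets(s, 1.4))
})

closed_cavity <- function() cached("closed_cavity", {
  s <- make_cavity_structure(interior_radius = 6,
                             opening_half_angles = numeric(0),
                             atom_spacing = 2.2, seed = 2)
  list(structure = s, pockets = detect_pockets(s, 1.4))
})

double_cavity <- function() cached("double_cavity", {
  s <- make_cavity_structure(interior_radius = 6,
                             opening_half_angles = c(30, 30),
                             atom_spacing = 2.2, seed = 3)
  list(structure = s, pockets = detect_pockets(s, 1.4))
})

# Triangulated unit-radius sphere surface (convex-hull faces of a jittered
# Fibonacci point set): analytic mean pair distance is 4/3.
unit_sphere_surface <- function(n = 220, seed = 11) cached("unit_sphere", {
  pts <- with_seed_helper(seed, {
    i <- seq_len(n) - 0.5
    z <- 1 - 2 * i / n
    th <- acos(z)
    ph <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
    p <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    r <- 1 + stats::runif(n, -0.005, 0.005)
    p * r
  })
  dt <- delaunay3d(pts)
  hull <- list()
  face_of <- rbind(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))
  for (t in seq_len(nrow(dt$tetra))) {
    for (j in 1:4) {
      if (is.na(dt$neighbors[t, j])) {
        hull[[length(hull) + 1]] <- dt$tetra[t, face_of[j, ]]
      }
    }
  }
  list(vertices = pts, triangles = do.call(rbind, hull))
})

with_seed_helper <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Unit cube decomposed into 5 tetrahedra (for voxel-overlap oracles).
cube_region <- function(origin = c(0, 0, 0)) {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  v <- sweep(v, 2, origin, "+")
  colnames(v) <- NULL
  tt <- rbind(c(1, 2, 3, 5), c(2, 3, 4, 8), c(2, 5, 6, 8),
              c(3, 5, 7, 8), c(2, 3, 5, 8))
  list(vertices = v, tetra = tt)
}

# A chiral (non-planar) labeled point set and its mirror image: no proper
# rotation can superpose them exactly.
chiral_pair <- function() {
  pts <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2.6, 0), c(0.4, 0.6, 3.4))
  mir <- pts %*% diag(c(1, 1, -1))
  lab <- c("polar", "polar", "nonpolar", "charged")
  ori <- diag(3)[c(1, 2, 3, 1), ]
  a <- chem_surface(pts, labels = lab, orientations = ori)
  b <- chem_surface(mir, labels = lab, orientations = ori %*% diag(c(1, 1, -1)))
  list(a = a, b = b)
}

rotate_structure <- function(structure, R, shift = c(0, 0, 0)) {
  P <- as.matrix(structure$atoms[, c("x", "y", "z")]) %*% t(R)
  P <- sweep(P, 2, shift, "+")
  structure$atoms$x <- P[, 1]
  structure$atoms$y <- P[, 2]
  structure$atoms$z <- P[, 3]
  structure
}

rotation_xyz <- function(ax, ay, az) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  Rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

new_structure_for_test <- function(atoms) {
  atoms$atom_name <- atoms$element
  structure(list(atoms = atoms, id = "test"), class = "structure3d")
}

write_multimodel_pdb <- function(path) {
  atom <- function(serial, name, res, seq, x, y, z, el, rec = "ATOM  ") {
    sprintf("%s%5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            rec, serial, name, res, seq, x, y, z, el)
  }
  block <- function(off) c(
    atom(1, "N", "SER", 1, off, 0, 0, "N"),
    atom(2, "CA", "SER", 1, off + 1.458, 0, 0, "C"),
    atom(3, "C", "SER", 1, off + 2.009, 1.42, 0, "C"),
    atom(4, "O", "SER", 1, off + 1.251, 2.39, 0, "O"),
    atom(5, "OG", "SER", 1, off + 1.958, -0.773, 1.12, "O"))
  writeLines(c("MODEL        1", block(0), "ENDMDL",
               "MODEL        2", block(9), "ENDMDL", "END"), path)
  path
}

write_water_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "HETATM    4  O   HOH A 101       5.000   5.000   5.000  1.00  0.00           O",
    "HETATM    5  O   HOH A 102       6.000   5.000   5.000  1.00  0.00           O",
    "END")
  writeLines(lines, path)
  path
}
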