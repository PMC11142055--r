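# Pocket detection by tetrahedral decomposition with discrete flow.
#
# The solvent-excluded interior of a structure is approximated on the
# unweighted Delaunay triangulation of atom centers.  A tetrahedron is
# "empty" when its circumsphere, corrected for the mean van der Waals radius
# of its member atoms, admits a solvent probe.  Empty tetrahedra flow along
# faces toward their circumcenters; basins that drain to an interior sink
# (rather than to the unbounded exterior) are pockets, and an empty region
# with no exterior-facing faces at all is an interior void.

face_opposite <- rbind(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))

#' Detect solvent-accessible surface pockets
#'
#' Computes the Delaunay decomposition of the atom centers, classifies
#' probe-admitting (empty) tetrahedra, runs discrete flow to separate bulk
#' solvent from pocket basins, and measures each pocket (area, void volume,
#' mouths, lining residues).  Pockets are returned sorted by volume
#' (descending), ties broken by smallest member atom serial.
#'
#' @param structure A `structure3d` with assigned radii.
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4, water).
#' @param samples_per_tetra Monte Carlo samples per tetrahedron for the void
#'   volume estimate (drawn in barycentric coordinates under a fixed
#'   internal seed, so the estimate is exactly rigid-motion equivariant).
#' @param min_volume Pocket basins with probe-accessible void volume below
#'   this are discarded (default: the volume of one probe sphere - a pocket
#'   must at least hold a probe).
#' @return List of `pocket_surface` objects.  Attribute `hull_volume` holds
#'   the convex hull volume of the atom centers.
#' @export
detect_pockets <- function(structure, probe_radius = 1.4,
                           samples_per_tetra = 64,
                           min_volume = 4 / 3 * pi * probe_radius^3) {
  stopifnot(inherits(structure, "structure3d"), probe_radius > 0)
  P <- coords_matrix(structure)
  radii <- structure$atoms$radius
  if (anyNA(radii)) stop("structure has unassigned radii; run assign_radii()")
  dt <- delaunay3d(P)
  tet <- dt$tetra
  m <- nrow(tet)
  mean_r <- (radii[tet[, 1]] + radii[tet[, 2]] + radii[tet[, 3]] +
               radii[tet[, 4]]) / 4
  empty <- sqrt(dt$r2) - mean_r >= probe_radius
  empty[!is.finite(dt$r2)] <- FALSE

  wide <- wide_faces(P, radii, tet, probe_radius)
  dest <- flow_destinations(P, dt, empty, wide)
  # pocket tetrahedra: empty, draining to an interior sink (dest > 0);
  # basins merge only across faces a probe could pass through
  in_pocket <- empty & dest > 0
  comp <- label_components(dt$neighbors, in_pocket, wide)

  pockets <- list()
  for (cid in seq_len(max(comp, 0))) {
    tids <- which(comp == cid)
    pockets[[length(pockets) + 1]] <-
      measure_pocket_tetra(structure, P, radii, dt, tids, empty, dest, wide,
                           probe_radius, samples_per_tetra)
  }
  if (length(pockets) > 0) {
    vol <- vapply(pockets, function(p) p$volume, numeric(1))
    keep <- vol >= min_volume
    pockets <- pockets[keep]
    vol <- vol[keep]
  }
  if (length(pockets) > 0) {
    minser <- vapply(pockets, function(p) min(p$atoms$serial), numeric(1))
    ord <- order(-vol, minser)
    pockets <- pockets[ord]
    for (i in seq_along(pockets)) pockets[[i]]$pocket_id <- i
  }
  attr(pockets, "hull_volume") <- sum(dt$vol)
  attr(pockets, "probe_radius") <- probe_radius
  pockets
}

# Per-(tetra, face) wideness: TRUE when the face circumcircle radius minus
# the mean vdW radius of its three atoms exceeds the probe radius, i.e. a
# probe can pass through the face.  Face j is opposite vertex j.
wide_faces <- function(P, radii, tet, probe_radius) {
  m <- nrow(tet)
  out <- matrix(FALSE, m, 4)
  for (j in 1:4) {
    tri <- cbind(tet[, face_opposite[j, 1]], tet[, face_opposite[j, 2]],
                 tet[, face_opposite[j, 3]])
    rc <- triangle_circumradius(P, tri)
    mr <- (radii[tri[, 1]] + radii[tri[, 2]] + radii[tri[, 3]]) / 3
    out[, j] <- (rc - mr) > probe_radius
  }
  out
}

# Follow discrete flow from every empty tetrahedron.  Flow runs toward the
# circumcenter and can only cross faces wide enough to pass a probe;
# blocked flow pools (sink).  Returns, per tetrahedron: -1 flows to the
# unbounded exterior, k > 0 drains to sink k, 0 for non-empty tetrahedra.
flow_destinations <- function(P, dt, empty, wide) {
  m <- nrow(dt$tetra)
  step <- integer(m)            # 0 = sink, -1 = exterior, else next tetra
  for (t in which(empty)) {
    b <- barycentric_coords(P, dt$tetra[t, ], dt$center[t, ])
    if (is.null(b)) { step[t] <- 0L; next }
    j <- which.min(b)
    if (b[j] >= -1e-12) { step[t] <- 0L; next }   # contains its circumcenter
    if (!wide[t, j]) { step[t] <- 0L; next }      # face too narrow: pools
    nb <- dt$neighbors[t, j]
    if (is.na(nb)) {
      step[t] <- -1L                              # drains through the hull
    } else if (!empty[nb]) {
      step[t] <- 0L                               # blocked face: local sink
    } else {
      step[t] <- nb
    }
  }
  dest <- integer(m)
  for (t in which(empty)) {
    if (dest[t] != 0L) next
    path <- t
    cur <- t
    repeat {
      nxt <- step[cur]
      if (nxt == 0L) { res <- cur; break }        # sink
      if (nxt == -1L) { res <- -1L; break }       # exterior
      if (dest[nxt] != 0L) { res <- dest[nxt]; break }
      if (nxt %in% path) { res <- cur; break }    # numerical cycle: sink
      path <- c(path, nxt)
      cur <- nxt
    }
    dest[path] <- res
  }
  dest
}

# Connected components over face adjacency, restricted to `mask`; when
# `wide` is given, only probe-passable faces connect.
label_components <- function(neighbors, mask, wide = NULL) {
  m <- length(mask)
  comp <- integer(m)
  cid <- 0L
  for (s in which(mask)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      t <- queue[[1]]; queue <- queue[-1]
      for (j in 1:4) {
        nb <- neighbors[t, j]
        if (is.na(nb) || !mask[nb] || comp[nb] != 0L) next
        if (!is.null(wide) && !wide[t, j]) next
        comp[nb] <- cid
        queue <- c(queue, nb)
      }
    }
  }
  comp
}

measure_pocket_tetra <- function(structure, P, radii, dt, tids, empty, dest,
                                 wide, probe_radius, samples_per_tetra) {
  tet <- dt$tetra
  nbm <- dt$neighbors
  in_set <- logical(nrow(tet)); in_set[tids] <- TRUE
  wall <- list(); mouth <- list()
  for (t in tids) {
    for (j in 1:4) {
      nb <- nbm[t, j]
      if (!is.na(nb) && in_set[nb]) next
      face <- tet[t, face_opposite[j, ]]
      # a boundary face is a mouth when it opens (wide enough for a probe)
      # onto bulk solvent or through the hull; otherwise an atom wall
      open_face <- wide[t, j] &&
        (is.na(nb) || (empty[nb] && dest[nb] == -1L))
      if (open_face) {
        mouth[[length(mouth) + 1]] <- face
      } else {
        wall[[length(wall) + 1]] <- face
      }
    }
  }
  wall <- do.call(rbind, wall)
  mouth_faces <- if (length(mouth) > 0) do.call(rbind, mouth) else NULL
  atom_idx <- sort(unique(as.vector(tet[tids, , drop = FALSE])))
  atoms <- structure$atoms[atom_idx, , drop = FALSE]
  area <- if (is.null(wall)) 0 else sum(triangle_areas(P, wall))
  vol <- void_volume_mc(P, radii, tet[tids, , drop = FALSE],
                        dt$center[tids, , drop = FALSE],
                        sqrt(dt$r2[tids]), dt$vol[tids],
                        probe_radius, samples_per_tetra)
  mouths <- mouth_components(P, mouth_faces)

  res <- unique(atoms[, c("chain_id", "residue_seq", "residue_name")])
  pol <- suppressWarnings(classify_residue_polarity(res$residue_name))
  res$polarity <- pol

  structure(list(
    pocket_id = NA_integer_,
    atom_index = atom_idx,
    atoms = atoms,
    triangles = wall,                 # wall faces, structure atom indices
    tetra = tet[tids, , drop = FALSE],
    area = area,
    volume = vol,
    mouths = mouths,
    n_mouths = length(mouths),
    residues = res,
    polar_residue_count = sum(pol %in% c("polar", "charged")),
    probe_radius = probe_radius,
    structure_id = structure$id
  ), class = "pocket_surface")
}

#' @export
print.pocket_surface <- function(x, ...) {
  cat(sprintf(
    "<pocket_surface> id %s: area %.1f A^2, void volume %.1f A^3, %d mouth(s), %d atoms, %d polar residue(s)\n",
    x$pocket_id, x$area, x$volume, x$n_mouths, nrow(x$atoms),
    x$polar_residue_count))
  invisible(x)
}

# Monte Carlo void volume: fraction of each empty tetrahedron farther than
# (r_vdw + probe) from every atom, i.e. where a probe center can sit.
# Fixed internal seed keyed to tetrahedron order.
void_volume_mc <- function(P, radii, tets, centers, crad, vols,
                           probe_radius, k) {
  maxr <- max(radii) + probe_radius
  total <- 0
  with_seed(760421L, {
    for (i in seq_len(nrow(tets))) {
      v <- P[tets[i, ], , drop = FALSE]
      w <- matrix(stats::rexp(4 * k), k, 4)
      w <- w / rowSums(w)
      pts <- w %*% v
      near <- which(dist2_to_point(P, centers[i, ]) <=
                      (crad[i] + maxr + 1e-9)^2)
      if (length(near) == 0) {
        total <- total + vols[i]
        next
      }
      free <- rep(TRUE, k)
      for (a in near) {
        ra2 <- (radii[a] + probe_radius)^2
        free <- free & (dist2_to_point(pts, P[a, ]) > ra2)
        if (!any(free)) break
      }
      total <- total + vols[i] * mean(free)
    }
  })
  total
}

# Group mouth faces into mouths by shared-edge connectivity; derive the rim
# (vertices of edges used by exactly one mouth face) and aperture area.
mouth_components <- function(P, mouth_faces) {
  if (is.null(mouth_faces) || nrow(mouth_faces) == 0) return(list())
  mf <- mouth_faces
  nf <- nrow(mf)
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edges <- rbind(cbind(mf[, 1], mf[, 2]), cbind(mf[, 1], mf[, 3]),
                 cbind(mf[, 2], mf[, 3]))
  keys <- ekey(edges[, 1], edges[, 2])
  fid <- rep(seq_len(nf), times = 3)
  by_edge <- split(fid, keys)
  comp <- integer(nf)
  cid <- 0L
  adj <- vector("list", nf)
  for (g in by_edge) {
    if (length(g) > 1) {
      for (a in g) adj[[a]] <- unique(c(adj[[a]], setdiff(g, a)))
    }
  }
  for (s in seq_len(nf)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s; comp[s] <- cid
    while (length(queue) > 0) {
      t <- queue[[1]]; queue <- queue[-1]
      for (nb in adj[[t]]) {
        if (comp[nb] == 0L) { comp[nb] <- cid; queue <- c(queue, nb) }
      }
    }
  }
  lapply(seq_len(cid), function(ci) {
    f <- mf[comp == ci, , drop = FALSE]
    ek <- c(ekey(f[, 1], f[, 2]), ekey(f[, 1], f[, 3]), ekey(f[, 2], f[, 3]))
    once <- names(which(table(ek) == 1))
    rim <- unique(as.integer(unlist(strsplit(once, " "))))
    rim <- order_rim(P, rim)
    list(rim_atoms = rim,
         aperture_area = sum(triangle_areas(P, f)),
         faces = f)
  })
}

# Order rim atoms into a cycle by angle in their best-fit plane.
order_rim <- function(P, rim) {
  if (length(rim) < 3) return(rim)
  X <- P[rim, , drop = FALSE]
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc)
  ang <- atan2(Xc %*% sv$v[, 2], Xc %*% sv$v[, 1])
  rim[order(ang)]
}

#' Re-measure a detected pocket
#'
#' Recomputes area, void volume, mouth count and the polar-residue count of
#' a pocket against its source structure.  [detect_pockets()] already
#' returns measured pockets; this is the explicit re-measurement entry
#' point.
#'
#' @param pocket A `pocket_surface` from [detect_pockets()].
#' @param structure The same `structure3d` the pocket was detected on.
#' @param samples_per_tetra Monte Carlo samples per tetrahedron.
#' @return The pocket with `area`, `volume`, `n_mouths`,
#'   `polar_residue_count` refreshed.
#' @export
measure_pocket <- function(pocket, structure, samples_per_tetra = 64) {
  stopifnot(inherits(pocket, "pocket_surface"))
  P <- coords_matrix(structure)
  radii <- structure$atoms$radius
  tets <- pocket$tetra
  cs <- circumspheres(P, tets)
  vols <- abs(tetra_volume(P, tets))
  pocket$volume <- void_volume_mc(P, radii, tets, cs$center, sqrt(cs$r2),
                                  vols, pocket$probe_radius,
                                  samples_per_tetra)
  if (!is.null(pocket$triangles)) {
    pocket$area <- sum(triangle_areas(P, pocket$triangles))
  }
  pocket$n_mouths <- length(pocket$mouths)
  pol <- pocket$residues$polarity
  pocket$polar_residue_count <- sum(pol %in% c("polar", "charged"))
  pocket
}

#' Apply the druggability filter to detected pockets
#'
#' A pocket is accepted when its area is at least `min_area`, it is lined by
#' at least `min_polar` polar (or charged) residues, and - when
#' `require_single_mouth` - it opens to solvent through exactly one mouth.
#' Each rejected pocket carries the first failing criterion, checked in the
#' order area, polar lining, mouth count.
#'
#' @param pockets List of measured `pocket_surface` objects.
#' @param min_area Minimum boundary area, Angstrom^2 (default 500).
#' @param min_polar Minimum distinct polar residues lining the pocket
#'   (default 2).
#' @param require_single_mouth Require exactly one mouth (default TRUE).
#' @return List with `accepted` (list of pockets) and `rejected`
#'   (data frame: pocket_id, reason).
#' @export
filter_druggable <- function(pockets, min_area = 500, min_polar = 2,
                             require_single_mouth = TRUE) {
  accepted <- list()
  rej_id <- integer(0); rej_reason <- character(0)
  for (p in pockets) {
    reason <- NULL
    if (p$area < min_area) {
      reason <- "area"
    } else if (p$polar_residue_count < min_polar) {
      reason <- "polar"
    } else if (require_single_mouth && p$n_mouths != 1) {
      reason <- "mouth"
    }
    if (is.null(reason)) {
      accepted[[length(accepted) + 1]] <- p
    } else {
      rej_id <- c(rej_id, p$pocket_id)
      rej_reason <- c(rej_reason, reason)
    }
  }
  list(accepted = accepted,
       rejected = data.frame(pocket_id = rej_id, reason = rej_reason,
                             stringsAsFactors = FALSE))
}

#' Probe-reachability classification on a dense grid
#'
#' Independent geometric oracle for pocket/void classification: voxelizes
#' space around the structure, marks cells whose center lies farther than
#' (van der Waals radius + probe) from every atom as free, and flood-fills
#' free space from the box boundary.  Free cells the flood never reaches are
#' interior void cells.
#'
#' @param structure A `structure3d` with radii.
#' @param probe_radius Probe radius, Angstrom.
#' @param spacing Grid spacing, Angstrom (default 0.25).
#' @param padding Box padding beyond the atom extent, Angstrom.
#' @return List with `origin`, `spacing`, `dim`, logical arrays `free` and
#'   `reachable`, and `cell_centers()` helper data.
#' @export
grid_reachability <- function(structure, probe_radius = 1.4, spacing = 0.25,
                              padding = 2.5) {
  P <- coords_matrix(structure)
  radii <- structure$atoms$radius + probe_radius
  lo <- apply(P, 2, min) - padding
  hi <- apply(P, 2, max) + padding
  dims <- pmax(ceiling((hi - lo) / spacing) + 1L, 2L)
  free <- array(TRUE, dim = dims)
  for (a in seq_len(nrow(P))) {
    r <- radii[a]
    i0 <- pmax(floor((P[a, ] - r - lo) / spacing) + 1, 1)
    i1 <- pmin(ceiling((P[a, ] + r - lo) / spacing) + 1, dims)
    ix <- i0[1]:i1[1]; iy <- i0[2]:i1[2]; iz <- i0[3]:i1[3]
    gx <- lo[1] + (ix - 1) * spacing
    gy <- lo[2] + (iy - 1) * spacing
    gz <- lo[3] + (iz - 1) * spacing
    dx2 <- (gx - P[a, 1])^2
    dy2 <- (gy - P[a, 2])^2
    dz2 <- (gz - P[a, 3])^2
    blocked <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r^2
    free[ix, iy, iz] <- free[ix, iy, iz] & !blocked
  }
  reachable <- array(FALSE, dim = dims)
  reachable[1, , ] <- free[1, , ]; reachable[dims[1], , ] <- free[dims[1], , ]
  reachable[, 1, ] <- reachable[, 1, ] | free[, 1, ]
  reachable[, dims[2], ] <- reachable[, dims[2], ] | free[, dims[2], ]
  reachable[, , 1] <- reachable[, , 1] | free[, , 1]
  reachable[, , dims[3]] <- reachable[, , dims[3]] | free[, , dims[3]]
  repeat {
    grown <- reachable
    grown[-1, , ] <- grown[-1, , ] | reachable[-dims[1], , ]
    grown[-dims[1], , ] <- grown[-dims[1], , ] | reachable[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | reachable[, -dims[2], ]
    grown[, -dims[2], ] <- grown[, -dims[2], ] | reachable[, -1, ]
    grown[, , -1] <- grown[, , -1] | reachable[, , -dims[3]]
    grown[, , -dims[3]] <- grown[, , -dims[3]] | reachable[, , -1]
    grown <- grown & free
    if (identical(grown, reachable)) break
    reachable <- grown
  }
  list(origin = lo, spacing = spacing, dim = dims, free = free,
       reachable = reachable)
}

# Mark grid cells lying inside any of the given tetrahedra (used to compare
# pocket tetrahedra against the grid oracle).
grid_cells_in_tetra <- function(grid, P, tets) {
  dims <- grid$dim
  inside <- array(FALSE, dim = dims)
  for (i in seq_len(nrow(tets))) {
    v <- P[tets[i, ], , drop = FALSE]
    lo <- apply(v, 2, min); hi <- apply(v, 2, max)
    i0 <- pmax(floor((lo - grid$origin) / grid$spacing) + 1, 1)
    i1 <- pmin(ceiling((hi - grid$origin) / grid$spacing) + 1, dims)
    if (any(i0 > i1)) next
    ix <- i0[1]:i1[1]; iy <- i0[2]:i1[2]; iz <- i0[3]:i1[3]
    gx <- grid$origin[1] + (ix - 1) * grid$spacing
    gy <- grid$origin[2] + (iy - 1) * grid$spacing
    gz <- grid$origin[3] + (iz - 1) * grid$spacing
    pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    M <- rbind(v[2, ] - v[1, ], v[3, ] - v[1, ], v[4, ] - v[1, ])
    b <- tryCatch(t(solve(t(M), t(sweep(pts, 2, v[1, ])))),
                  error = function(e) NULL)
    if (is.null(b)) next
    ok <- b[, 1] >= -1e-9 & b[, 2] >= -1e-9 & b[, 3] >= -1e-9 &
      rowSums(b) <= 1 + 1e-9
    if (!any(ok)) next
    sub <- array(FALSE, dim = c(length(ix), length(iy), length(iz)))
    sub[ok] <- TRUE
    inside[ix, iy, iz] <- inside[ix, iy, iz] | sub
  }
  inside
}
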