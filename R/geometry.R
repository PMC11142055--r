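# 3D Delaunay triangulation (Bowyer-Watson incremental insertion) and
# simplex utilities.  Pure R; problem sizes here are a few hundred atoms.

# Circumsphere of tetrahedra. P: n x 3 points; tet: m x 4 index matrix.
# Returns list(center = m x 3, r2 = m).  Degenerate (flat) tetrahedra get
# r2 = Inf so they are always re-triangulated away.
circumspheres <- function(P, tet) {
  m <- nrow(tet)
  ctr <- matrix(NA_real_, m, 3)
  r2 <- rep(Inf, m)
  for (i in seq_len(m)) {
    v <- P[tet[i, ], , drop = FALSE]
    A <- 2 * sweep(v[2:4, , drop = FALSE], 2, v[1, ])
    rhs <- rowSums(v[2:4, , drop = FALSE]^2) - sum(v[1, ]^2)
    cc <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (!is.null(cc) && all(is.finite(cc))) {
      ctr[i, ] <- cc
      r2[i] <- sum((v[1, ] - cc)^2)
    }
  }
  list(center = ctr, r2 = r2)
}

tetra_volume <- function(P, tet) {
  m <- nrow(tet)
  v <- numeric(m)
  for (i in seq_len(m)) {
    a <- P[tet[i, 1], ]; b <- P[tet[i, 2], ]
    c_ <- P[tet[i, 3], ]; d <- P[tet[i, 4], ]
    v[i] <- det(rbind(b - a, c_ - a, d - a)) / 6
  }
  v
}

triangle_areas <- function(P, tri) {
  a <- P[tri[, 1], , drop = FALSE]
  b <- P[tri[, 2], , drop = FALSE]
  c_ <- P[tri[, 3], , drop = FALSE]
  u <- b - a; v <- c_ - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# Circumcircle radius of triangles (for the wide-face test).
triangle_circumradius <- function(P, tri) {
  a <- P[tri[, 1], , drop = FALSE]
  b <- P[tri[, 2], , drop = FALSE]
  c_ <- P[tri[, 3], , drop = FALSE]
  la <- sqrt(rowSums((b - c_)^2))
  lb <- sqrt(rowSums((a - c_)^2))
  lc <- sqrt(rowSums((a - b)^2))
  area <- triangle_areas(P, tri)
  out <- la * lb * lc / (4 * pmax(area, .Machine$double.eps))
  out
}

sort3 <- function(a, b, c_) {
  lo <- pmin(a, b, c_)
  hi <- pmax(a, b, c_)
  cbind(lo, a + b + c_ - lo - hi, hi)
}

#' 3D Delaunay triangulation of a point set
#'
#' Incremental Bowyer-Watson construction.  Intended for the few-hundred
#' point scale of single-structure pocket analysis.  Input should be free of
#' exact geometric degeneracies (the synthetic-structure generators add
#' sub-Angstrom positional noise for this reason).
#'
#' @param pts n x 3 numeric matrix of point coordinates.
#' @return List with `tetra` (m x 4 vertex indices, positively oriented),
#'   `center`/`r2` circumsphere data, `vol` tetrahedron volumes, and
#'   `neighbors` (m x 4; entry (t, j) is the tetrahedron sharing the face
#'   opposite vertex j of t, or NA on the convex hull).
#' @export
delaunay3d <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 4) stop("need at least 4 points for a 3D triangulation")
  ctr <- colMeans(pts)
  span <- sqrt(max(dist2_to_point(pts, ctr)))
  if (qr(sweep(pts, 2, ctr))$rank < 3) {
    stop("degenerate geometry: points are coplanar or collinear")
  }
  R <- span * 200 + 200
  sv <- rbind(ctr + R * c(1, 1, 1), ctr + R * c(1, -1, -1),
              ctr + R * c(-1, 1, -1), ctr + R * c(-1, -1, 1))
  P <- rbind(pts, sv)
  tet <- matrix(n + 1:4, 1, 4)
  cs <- circumspheres(P, tet)
  cx <- cs$center[, 1]; cy <- cs$center[, 2]; cz <- cs$center[, 3]
  r2 <- cs$r2

  for (i in seq_len(n)) {
    p <- P[i, ]
    d2 <- (cx - p[1])^2 + (cy - p[2])^2 + (cz - p[3])^2
    bad <- which(d2 < r2)
    if (length(bad) == 0) {
      # numerically on-sphere: fall back to the containing tetrahedron
      bad <- locate_tetra(P, tet, p)
      if (length(bad) == 0) stop("triangulation failure at point ", i)
    }
    # boundary faces = faces of the bad set appearing exactly once
    bt <- tet[bad, , drop = FALSE]
    nb <- nrow(bt)
    f1 <- sort3(bt[, 2], bt[, 3], bt[, 4])
    f2 <- sort3(bt[, 1], bt[, 3], bt[, 4])
    f3 <- sort3(bt[, 1], bt[, 2], bt[, 4])
    f4 <- sort3(bt[, 1], bt[, 2], bt[, 3])
    faces <- rbind(f1, f2, f3, f4)
    key <- paste(faces[, 1], faces[, 2], faces[, 3])
    once <- !(duplicated(key) | duplicated(key, fromLast = TRUE))
    bfaces <- faces[once, , drop = FALSE]
    newtet <- cbind(bfaces, i)
    ncs <- circumspheres(P, newtet)
    keep <- setdiff(seq_len(nrow(tet)), bad)
    tet <- rbind(tet[keep, , drop = FALSE], newtet)
    cx <- c(cx[keep], ncs$center[, 1])
    cy <- c(cy[keep], ncs$center[, 2])
    cz <- c(cz[keep], ncs$center[, 3])
    r2 <- c(r2[keep], ncs$r2)
  }

  real <- rowSums(tet > n) == 0
  tet <- tet[real, , drop = FALSE]
  cx <- cx[real]; cy <- cy[real]; cz <- cz[real]; r2 <- r2[real]
  vol <- tetra_volume(pts, tet)
  flip <- vol < 0
  if (any(flip)) {
    tmp <- tet[flip, 3]
    tet[flip, 3] <- tet[flip, 4]
    tet[flip, 4] <- tmp
    vol <- abs(vol)
  }
  nb <- tetra_neighbors(tet)
  list(tetra = tet, center = cbind(cx, cy, cz), r2 = r2, vol = vol,
       neighbors = nb, n_points = n)
}

locate_tetra <- function(P, tet, p) {
  for (i in seq_len(nrow(tet))) {
    b <- barycentric_coords(P, tet[i, ], p)
    if (!is.null(b) && min(b) >= -1e-9) return(i)
  }
  integer(0)
}

barycentric_coords <- function(P, verts, p) {
  v <- P[verts, , drop = FALSE]
  M <- rbind(v[2, ] - v[1, ], v[3, ] - v[1, ], v[4, ] - v[1, ])
  b234 <- tryCatch(solve(t(M), p - v[1, ]), error = function(e) NULL)
  if (is.null(b234)) return(NULL)
  c(1 - sum(b234), b234)
}

# Neighbor matrix across shared faces. Faces of tetra t: face j is opposite
# vertex j.
tetra_neighbors <- function(tet) {
  m <- nrow(tet)
  face_of <- rbind(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))
  keys <- character(4 * m)
  tid <- rep(seq_len(m), times = 4)
  fid <- rep(1:4, each = m)
  for (j in 1:4) {
    f <- sort3(tet[, face_of[j, 1]], tet[, face_of[j, 2]], tet[, face_of[j, 3]])
    keys[(j - 1) * m + seq_len(m)] <- paste(f[, 1], f[, 2], f[, 3])
  }
  nb <- matrix(NA_integer_, m, 4)
  o <- order(keys)
  k <- keys[o]
  same <- which(k[-1] == k[-length(k)])
  for (s in same) {
    a <- o[s]; b <- o[s + 1]
    nb[tid[a], fid[a]] <- tid[b]
    nb[tid[b], fid[b]] <- tid[a]
  }
  nb
}
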