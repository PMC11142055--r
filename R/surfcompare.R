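# Pocket-surface comparison: global shape distributions compared with
# Kolmogorov-Smirnov statistics, chemically-labeled least-squares
# superposition (coordinate and orientation RMSD), a random-alignment null,
# voxel volume-overlap Tanimoto, and a composite similarity score.

#' Shape signature of a pocket surface
#'
#' Rotation/translation-invariant global shape descriptor: the probability
#' distribution of Euclidean distances between random point pairs sampled
#' uniformly (by area) on the pocket's boundary triangles.
#'
#' @param pocket A `pocket_surface`, or any object with fields `triangles`
#'   (m x 3 vertex indices) and `vertices` (coordinates); for pockets the
#'   vertex coordinates are taken from the pocket's atom table.
#' @param n_points Surface points to sample (>= 10; default 512).
#' @param n_pairs Random point pairs (default 4096).
#' @param n_bins Histogram bins over [0, max distance] (default 64).
#' @param seed RNG seed (sampling is deterministic given the seed).
#' @return A `shape_signature`: bin_edges, probabilities (sum to 1),
#'   n_points, n_pairs, seed, and the sampled pair distances.
#' @export
shape_signature <- function(pocket, n_points = 512, n_pairs = 4096,
                            n_bins = 64, seed = 1) {
  stopifnot(n_points >= 10, n_pairs >= 1, n_bins >= 2)
  if (inherits(pocket, "pocket_surface")) {
    if (is.null(pocket$triangles) || nrow(pocket$triangles) == 0) {
      stop("pocket has no boundary triangles")
    }
    V <- as.matrix(pocket$atoms[, c("x", "y", "z")])
    idx <- match(as.vector(pocket$triangles), pocket$atom_index)
    tri <- matrix(idx, ncol = 3)
  } else {
    V <- as.matrix(pocket$vertices)
    tri <- as.matrix(pocket$triangles)
  }
  if (anyNA(tri)) stop("triangle indices do not match the vertex table")
  areas <- triangle_areas(V, tri)
  if (sum(areas) <= 0) stop("empty surface: zero total triangle area")
  d <- with_seed(seed, {
    ti <- sample.int(nrow(tri), n_points, replace = TRUE,
                     prob = areas / sum(areas))
    r1 <- sqrt(stats::runif(n_points))
    r2 <- stats::runif(n_points)
    a <- V[tri[ti, 1], , drop = FALSE]
    b <- V[tri[ti, 2], , drop = FALSE]
    c_ <- V[tri[ti, 3], , drop = FALSE]
    pts <- (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * c_
    i <- sample.int(n_points, n_pairs, replace = TRUE)
    j <- sample.int(n_points, n_pairs, replace = TRUE)
    sqrt(rowSums((pts[i, , drop = FALSE] - pts[j, , drop = FALSE])^2))
  })
  as_shape_signature(d, n_bins = n_bins, n_points = n_points, seed = seed)
}

#' Build a shape signature from raw distance samples
#'
#' @param distances Numeric vector of pair distances.
#' @param n_bins Number of equal-width bins over [0, max distance].
#' @param n_points Point sample size the distances came from (metadata).
#' @param seed Seed metadata.
#' @return A `shape_signature`.
#' @export
as_shape_signature <- function(distances, n_bins = 64,
                               n_points = NA_integer_, seed = NA_integer_) {
  stopifnot(length(distances) >= 1, all(is.finite(distances)),
            all(distances >= 0))
  top <- max(distances)
  if (top <= 0) top <- 1
  edges <- seq(0, top, length.out = n_bins + 1)
  h <- graphics::hist(distances, breaks = edges, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  structure(list(
    bin_edges = edges,
    probabilities = h$counts / length(distances),
    n_points = n_points,
    n_pairs = length(distances),
    seed = seed,
    distances = distances
  ), class = "shape_signature")
}

#' @export
print.shape_signature <- function(x, ...) {
  cat(sprintf(
    "<shape_signature> %d pairs over %d bins, support [0, %.2f] A, mean %.2f A\n",
    x$n_pairs, length(x$probabilities), max(x$bin_edges),
    mean(x$distances)))
  invisible(x)
}

#' Kolmogorov-Smirnov comparison of two shape signatures
#'
#' D is the maximum absolute difference between the two empirical CDFs over
#' the union of their sample points (or bin edges when raw distances are
#' unavailable).  The p value uses the two-sample asymptotic KS formula
#' with effective sample size n1*n2/(n1+n2).
#'
#' @param sig_a,sig_b `shape_signature` objects.
#' @return List with `D` (in [0,1]) and `p`.
#' @export
ks_compare <- function(sig_a, sig_b) {
  stopifnot(inherits(sig_a, "shape_signature"),
            inherits(sig_b, "shape_signature"))
  if (!is.null(sig_a$distances) && !is.null(sig_b$distances)) {
    xa <- sort(sig_a$distances); xb <- sort(sig_b$distances)
    grid <- sort(unique(c(xa, xb)))
    Fa <- findInterval(grid, xa) / length(xa)
    Fb <- findInterval(grid, xb) / length(xb)
    n1 <- length(xa); n2 <- length(xb)
  } else {
    grid <- sort(unique(c(sig_a$bin_edges, sig_b$bin_edges)))
    Fa <- signature_cdf(sig_a, grid)
    Fb <- signature_cdf(sig_b, grid)
    n1 <- sig_a$n_pairs; n2 <- sig_b$n_pairs
  }
  D <- max(abs(Fa - Fb))
  n_eff <- n1 * n2 / (n1 + n2)
  p <- ks_asymptotic_p(D, n_eff)
  list(D = D, p = p)
}

signature_cdf <- function(sig, x) {
  cum <- c(0, cumsum(sig$probabilities))
  edges <- sig$bin_edges
  stats::approx(edges, cum, xout = x, yleft = 0, yright = 1,
                rule = 2)$y
}

# Asymptotic two-sided KS tail probability with the small-sample
# correction of Stephens (1970).
ks_asymptotic_p <- function(D, n_eff) {
  if (D <= 0) return(1)
  lambda <- (sqrt(n_eff) + 0.12 + 0.11 / sqrt(n_eff)) * D
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Construct a chemically-labeled surface
#'
#' A `chem_surface` is a set of labeled points with unit orientation
#' vectors.  Built from a pocket, the points are the pocket's lining atom
#' positions, labels are the polarity class of the sourcing residue, and
#' each orientation is the unit vector from the residue's alpha-carbon to
#' its side-chain heavy-atom centroid (for residues without that geometry -
#' glycine, or the pseudo-residues of synthetic shells - the outward vector
#' from the structure centroid is used).
#'
#' @param x A `pocket_surface` (with `structure` supplied), or an n x 3
#'   coordinate matrix.
#' @param structure The source `structure3d` (pocket input only).
#' @param labels Character labels per point (matrix input only).
#' @param orientations n x 3 matrix of direction vectors (matrix input
#'   only); normalised internally.
#' @return A `chem_surface`: `points`, `labels`, `orientations`.
#' @export
chem_surface <- function(x, structure = NULL, labels = NULL,
                         orientations = NULL) {
  if (inherits(x, "pocket_surface")) {
    if (is.null(structure)) stop("supply the source structure")
    pts <- as.matrix(x$atoms[, c("x", "y", "z")])
    lab <- x$atoms$polarity %||%
      suppressWarnings(classify_residue_polarity(x$atoms$residue_name))
    ori <- residue_orientations(x$atoms, structure)
  } else {
    pts <- as.matrix(x)
    if (is.null(labels) || is.null(orientations)) {
      stop("labels and orientations are required for matrix input")
    }
    lab <- labels
    ori <- as.matrix(orientations)
  }
  stopifnot(nrow(pts) == length(lab), nrow(pts) == nrow(ori))
  nrm <- sqrt(rowSums(ori^2))
  if (any(nrm < .Machine$double.eps)) stop("zero orientation vector")
  ori <- ori / nrm
  structure(list(points = pts, labels = as.character(lab),
                 orientations = ori), class = "chem_surface")
}

residue_orientations <- function(atoms, structure) {
  all_atoms <- structure$atoms
  ctr <- colMeans(coords_matrix(structure))
  backbone <- c("N", "CA", "C", "O", "OXT")
  t(vapply(seq_len(nrow(atoms)), function(i) {
    key <- all_atoms$chain_id == atoms$chain_id[i] &
      all_atoms$residue_seq == atoms$residue_seq[i]
    res <- all_atoms[key, , drop = FALSE]
    nm <- res$atom_name %||% res$element
    ca <- res[nm == "CA", c("x", "y", "z"), drop = FALSE]
    sc <- res[!(nm %in% backbone), c("x", "y", "z"), drop = FALSE]
    if (nrow(ca) == 1 && nrow(sc) >= 1) {
      unit_vec(colMeans(as.matrix(sc)) - as.numeric(ca[1, ]))
    } else {
      unit_vec(as.numeric(atoms[i, c("x", "y", "z")]) - ctr)
    }
  }, numeric(3)))
}

#' Least-squares superposition of two labeled surfaces
#'
#' Finds the proper rotation and translation mapping surface `b` onto
#' surface `a` that minimise the summed squared distances over the given
#' correspondence, via singular value decomposition of the cross-covariance
#' (Kabsch; reflections corrected to det +1).
#'
#' @param a,b `chem_surface` objects.
#' @param correspondence Two-column integer matrix; row (i, j) pairs point
#'   i of `a` with point j of `b`.  Labels of paired points must match.
#' @return A `surface_alignment`: `rotation` (3 x 3, det +1),
#'   `translation`, `correspondence`, `cRMSD` (Angstrom), `oRMSD`
#'   (radians, root mean square angle between a's orientations and the
#'   rotated orientations of b).
#' @export
superpose <- function(a, b, correspondence) {
  stopifnot(inherits(a, "chem_surface"), inherits(b, "chem_surface"))
  cor <- as.matrix(correspondence)
  if (nrow(cor) < 3) stop("alignment error: need at least 3 correspondence pairs")
  la <- a$labels[cor[, 1]]; lb <- b$labels[cor[, 2]]
  if (any(la != lb)) stop("label mismatch in correspondence")
  X <- a$points[cor[, 1], , drop = FALSE]     # target
  Y <- b$points[cor[, 2], , drop = FALSE]     # moving
  if (qr(sweep(Y, 2, colMeans(Y)))$rank < 2 ||
      qr(sweep(X, 2, colMeans(X)))$rank < 2) {
    stop("alignment error: correspondence points are collinear")
  }
  mx <- colMeans(X); my <- colMeans(Y)
  H <- t(sweep(Y, 2, my)) %*% sweep(X, 2, mx)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- mx - as.numeric(R %*% my)
  Yfit <- sweep(Y %*% t(R), 2, tr, "+")
  cRMSD <- sqrt(mean(rowSums((X - Yfit)^2)))
  oa <- a$orientations[cor[, 1], , drop = FALSE]
  ob <- b$orientations[cor[, 2], , drop = FALSE] %*% t(R)
  dots <- pmin(pmax(rowSums(oa * ob), -1), 1)
  oRMSD <- sqrt(mean(acos(dots)^2))
  structure(list(rotation = R, translation = tr, correspondence = cor,
                 cRMSD = cRMSD, oRMSD = oRMSD),
            class = "surface_alignment")
}

#' @export
print.surface_alignment <- function(x, ...) {
  cat(sprintf("<surface_alignment> %d pairs, cRMSD %.4f A, oRMSD %.4f rad\n",
              nrow(x$correspondence), x$cRMSD, x$oRMSD))
  invisible(x)
}

# Mutual nearest neighbors among same-labeled points of two centered
# clouds; returns a 2-column index matrix.
mutual_nn_correspondence <- function(pa, la, pb, lb) {
  pairs <- list()
  for (lab in intersect(unique(la), unique(lb))) {
    ia <- which(la == lab); ib <- which(lb == lab)
    A <- pa[ia, , drop = FALSE]; B <- pb[ib, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    fwd <- apply(d2, 1, which.min)
    bwd <- apply(d2, 2, which.min)
    mut <- which(bwd[fwd] == seq_along(ia))
    if (length(mut) > 0) {
      pairs[[length(pairs) + 1]] <- cbind(ia[mut], ib[fwd[mut]])
    }
  }
  if (length(pairs) == 0) return(matrix(integer(0), 0, 2))
  do.call(rbind, pairs)
}

#' Correspondence for unaligned surfaces
#'
#' Centers both clouds, then pairs mutual nearest neighbors among
#' same-labeled points.  One of several plausible schemes; exposed so
#' callers can substitute their own.
#'
#' @param a,b `chem_surface` objects.
#' @return Two-column index matrix.
#' @export
derive_correspondence <- function(a, b) {
  pa <- sweep(a$points, 2, colMeans(a$points))
  pb <- sweep(b$points, 2, colMeans(b$points))
  mutual_nn_correspondence(pa, a$labels, pb, b$labels)
}

#' Random-alignment null p value for an observed superposition
#'
#' Generates `n_random` uniformly random rotations (quaternion sampling) of
#' surface `b`, re-derives the mutual-nearest-neighbor label-respecting
#' correspondence after each, and measures the resulting coordinate RMSD of
#' the centered clouds.  p = (1 + #{null cRMSD <= observed}) / (n_random+1).
#'
#' @param a,b `chem_surface` objects.
#' @param observed `surface_alignment` computed on (a, b).
#' @param n_random Number of random alignments (default 999).
#' @param seed RNG seed.
#' @return Permutation-style p value in (0, 1].
#' @export
alignment_null_pvalue <- function(a, b, observed, n_random = 999, seed = 1) {
  stopifnot(inherits(observed, "surface_alignment"), n_random >= 1)
  pa <- sweep(a$points, 2, colMeans(a$points))
  pb <- sweep(b$points, 2, colMeans(b$points))
  hits <- with_seed(seed, {
    count <- 0L
    for (r in seq_len(n_random)) {
      R <- random_rotation()
      pbr <- pb %*% t(R)
      cor <- mutual_nn_correspondence(pa, a$labels, pbr, b$labels)
      if (nrow(cor) < 3) next
      rmsd <- sqrt(mean(rowSums(
        (pa[cor[, 1], , drop = FALSE] - pbr[cor[, 2], , drop = FALSE])^2)))
      if (rmsd <= observed$cRMSD) count <- count + 1L
    }
    count
  })
  (1 + hits) / (n_random + 1)
}

# Uniform random rotation from a normalised Gaussian quaternion.
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(
    c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

#' Volume-overlap Tanimoto coefficient of two pockets
#'
#' Voxelizes each pocket's tetrahedral volume on a common grid (after
#' applying the alignment to pocket b) and returns
#' |A intersect B| / |A union B| over occupied voxels.
#'
#' @param a,b `pocket_surface` objects (or any objects with `tetra` index
#'   matrix and an atom table carrying x, y, z).
#' @param alignment `surface_alignment` mapping b onto a, or NULL for
#'   identity.
#' @param grid_spacing Voxel edge, Angstrom (default 0.5).
#' @return Tanimoto coefficient in [0, 1].
#' @export
volume_tanimoto <- function(a, b, alignment = NULL, grid_spacing = 0.5) {
  va <- pocket_tetra_coords(a)
  vb <- pocket_tetra_coords(b)
  if (!is.null(alignment)) {
    vb$vertices <- sweep(vb$vertices %*% t(alignment$rotation), 2,
                         alignment$translation, "+")
  }
  lo <- pmin(apply(va$vertices, 2, min), apply(vb$vertices, 2, min)) - grid_spacing
  hi <- pmax(apply(va$vertices, 2, max), apply(vb$vertices, 2, max)) + grid_spacing
  # half-cell offset keeps voxel centers off axis-aligned volume boundaries
  lo <- lo - grid_spacing / 2
  dims <- pmax(ceiling((hi - lo) / grid_spacing) + 1L, 2L)
  grid <- list(origin = lo, spacing = grid_spacing, dim = dims)
  occ_a <- grid_cells_in_tetra(grid, va$vertices, va$tetra)
  occ_b <- grid_cells_in_tetra(grid, vb$vertices, vb$tetra)
  if (!any(occ_a) || !any(occ_b)) stop("empty voxelization")
  sum(occ_a & occ_b) / sum(occ_a | occ_b)
}

pocket_tetra_coords <- function(p) {
  if (inherits(p, "pocket_surface")) {
    V <- as.matrix(p$atoms[, c("x", "y", "z")])
    tet <- matrix(match(as.vector(p$tetra), p$atom_index), ncol = 4)
  } else {
    V <- as.matrix(p$vertices)
    tet <- as.matrix(p$tetra)
  }
  list(vertices = V, tetra = tet)
}

#' Composite surface-similarity score
#'
#' Linear combination of the three similarity components:
#' `w_shape * (1 - ks_D) + w_align * (1 - align_p) + w_overlap * tanimoto`.
#' The combination rule is a package design choice (monotone increasing in
#' every similarity component); weights are configurable and default to
#' equal.
#'
#' @param ks_D KS shape-distribution statistic in [0, 1].
#' @param align_p Random-alignment null p value in [0, 1].
#' @param tanimoto Volume-overlap Tanimoto in [0, 1].
#' @param weights Named numeric: shape, align, overlap (non-negative).
#' @return List with the parts and the `composite` value.
#' @export
composite_score <- function(ks_D, align_p, tanimoto,
                            weights = c(shape = 1 / 3, align = 1 / 3,
                                        overlap = 1 / 3)) {
  stopifnot(all(c("shape", "align", "overlap") %in% names(weights)))
  if (any(weights < 0)) stop("config error: negative weights")
  stopifnot(ks_D >= 0, ks_D <= 1, align_p >= 0, align_p <= 1,
            tanimoto >= 0, tanimoto <= 1)
  comp <- unname(weights["shape"] * (1 - ks_D) +
                   weights["align"] * (1 - align_p) +
                   weights["overlap"] * tanimoto)
  list(ks_D = ks_D, align_p = align_p, tanimoto = tanimoto,
       weights = weights, composite = comp)
}
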