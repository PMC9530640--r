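## Ensemble superposition, C-alpha PCA, extreme-conformer extraction and
## morphing. The PCA is unweighted (C-alpha only makes mass weighting a
## constant factor) and uses the 1/(M-1) covariance estimator.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' paired point sets. Row convention: `mobile %*% rotation + translation`
#' approximates `reference`.
#'
#' @param mobile,reference N x 3 coordinate matrices, N >= 3.
#' @return list with `rotation` (3 x 3, determinant +1), `translation`
#'   (length 3) and `rmsd` (Angstrom, after the transform).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  n <- nrow(mobile)
  if (n < 3) stop("degenerate fit: fewer than 3 points")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  p <- sweep(mobile, 2, cm)
  q <- sweep(reference, 2, cr)
  ## collinear (rank < 2) point sets leave the rotation underdetermined
  if (svd(p)$d[2] < 1e-8 * max(1, svd(p)$d[1])) {
    stop("degenerate fit: points are collinear")
  }
  h <- crossprod(p, q)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  trans <- cr - drop(cm %*% rot)
  fitted <- sweep(mobile %*% rot, 2, trans, "+")
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  list(rotation = rot, translation = trans, rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz N x 3 matrix.
#' @param fit list with `rotation` and `translation` as returned by
#'   [kabsch_superpose()].
#' @return transformed N x 3 matrix.
#' @export
apply_transform <- function(xyz, fit) {
  sweep(as.matrix(xyz) %*% fit$rotation, 2, fit$translation, "+")
}

ensemble_calpha <- function(e, mask = NULL) {
  mats <- lapply(e$members, calpha_matrix, mask = mask)
  im <- mats[[1]]$index_map
  coords <- t(vapply(mats, function(m) as.vector(t(m$xyz)), numeric(3 * nrow(im))))
  list(coords = coords, index_map = im)
}

rows_to_xyz <- function(row) matrix(row, ncol = 3, byrow = TRUE)

#' Iteratively superpose an ensemble onto its mean
#'
#' Each member is superposed onto the running mean conformation; the mean is
#' recomputed until it shifts by less than `tol` (RMSD) or `max_iter`
#' iterations are reached (warning, last mean kept). Deterministic given the
#' member order.
#'
#' @param e a `zip_ensemble` with at least 2 members.
#' @param mask optional [region_mask()].
#' @param tol convergence tolerance on the mean shift, Angstrom RMSD.
#' @param max_iter iteration cap.
#' @return object of class `zip_aligned`: list with `coords` (M x 3N matrix
#'   of aligned C-alpha coordinates, one row per member), `mean` (N x 3),
#'   `index_map` and `ids`.
#' @export
iterative_mean_align <- function(e, mask = NULL, tol = 1e-6, max_iter = 50) {
  stopifnot(inherits(e, "zip_ensemble"))
  if (length(e$members) < 2) stop("ensemble too small: need >= 2 members")
  ec <- ensemble_calpha(e, mask)
  coords <- ec$coords
  m <- nrow(coords)
  n <- nrow(ec$index_map)
  mean_xyz <- rows_to_xyz(coords[1, ])
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    for (i in seq_len(m)) {
      xyz <- rows_to_xyz(coords[i, ])
      fit <- kabsch_superpose(xyz, mean_xyz)
      coords[i, ] <- as.vector(t(apply_transform(xyz, fit)))
    }
    new_mean <- rows_to_xyz(colMeans(coords))
    shift <- sqrt(mean(rowSums((new_mean - mean_xyz)^2)))
    mean_xyz <- new_mean
    if (shift < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("mean alignment did not converge in ", max_iter,
            " iterations; proceeding with last mean")
  }
  structure(list(coords = coords, mean = mean_xyz, index_map = ec$index_map,
                 ids = e$ids, n_residues = n),
            class = "zip_aligned")
}

#' Principal component analysis of an aligned ensemble
#'
#' Eigendecomposition of the coordinate covariance about the ensemble mean
#' (1/(M-1) estimator), computed through the singular value decomposition of
#' the centred coordinate matrix. The sign of each component is fixed so
#' that the member with the lexicographically smallest id projects
#' non-positively; the two PC1-extreme conformers are recorded.
#'
#' @param aligned a `zip_aligned` object from [iterative_mean_align()], or a
#'   bare M x 3N coordinate matrix.
#' @param k number of components to retain; default `min(M - 1, 3N)`.
#' @return object of class `zip_landscape`: `eigenvalues` (all, descending,
#'   Angstrom^2), `eigenvectors` (3N x k, orthonormal), `projections`
#'   (M x k, Angstrom), `total_variance`, `mean`, `index_map`, `ids`,
#'   `extreme_low`, `extreme_high`.
#' @export
landscape_pca <- function(aligned, k = NULL) {
  if (inherits(aligned, "zip_aligned")) {
    coords <- aligned$coords
    ids <- aligned$ids
    index_map <- aligned$index_map
    mean_xyz <- aligned$mean
  } else {
    coords <- as.matrix(aligned)
    ids <- sprintf("member%03d", seq_len(nrow(coords)))
    index_map <- NULL
    mean_xyz <- rows_to_xyz(colMeans(coords))
  }
  m <- nrow(coords)
  if (m < 2) stop("PCA needs at least 2 conformers")
  p <- ncol(coords)
  kmax <- min(m - 1, p)
  if (is.null(k)) k <- kmax
  k <- min(k, kmax)
  centred <- sweep(coords, 2, colMeans(coords))
  sv <- svd(centred, nu = kmax, nv = kmax)
  eigenvalues <- sv$d^2 / (m - 1)
  eigenvalues <- eigenvalues[seq_len(kmax)]
  vectors <- sv$v
  projections <- centred %*% vectors
  ## deterministic sign: smallest id projects non-positively on every PC
  anchor <- order(ids)[1]
  flip <- projections[anchor, ] > 0
  vectors[, flip] <- -vectors[, flip]
  projections[, flip] <- -projections[, flip]
  vectors <- vectors[, seq_len(k), drop = FALSE]
  projections <- projections[, seq_len(k), drop = FALSE]
  rownames(projections) <- ids
  colnames(projections) <- sprintf("PC%d", seq_len(k))
  total_variance <- sum(centred^2) / (m - 1)
  pc1 <- projections[, 1]
  res <- structure(list(eigenvalues = eigenvalues, eigenvectors = vectors,
                        projections = projections,
                        total_variance = total_variance,
                        mean = mean_xyz, index_map = index_map, ids = ids,
                        extreme_low = which.min(pc1),
                        extreme_high = which.max(pc1)),
                   class = "zip_landscape")
  res
}

#' @export
print.zip_landscape <- function(x, ...) {
  frac <- if (x$total_variance > 0) x$eigenvalues[1] / x$total_variance else NA
  cat("zip_landscape: ", nrow(x$projections), " conformers, PC1 variance fraction ",
      format(frac, digits = 3), "\n", sep = "")
  cat("  extremes: low = ", x$ids[x$extreme_low], ", high = ",
      x$ids[x$extreme_high], "\n", sep = "")
  invisible(x)
}

#' Indices of the PC1-extreme conformers
#'
#' Argmin and argmax of the PC1 projection; ties are broken by the lower
#' ensemble index. A fully degenerate landscape (all projections equal)
#' returns the first member twice with a warning.
#'
#' @param r a `zip_landscape` from [landscape_pca()].
#' @return integer vector `c(index_low, index_high)`.
#' @export
extract_extremes <- function(r) {
  stopifnot(inherits(r, "zip_landscape"))
  pc1 <- r$projections[, 1]
  if (diff(range(pc1)) < 1e-12) {
    warning("degenerate landscape: all PC1 projections equal")
    return(c(index_low = 1L, index_high = 1L))
  }
  c(index_low = which.min(pc1), index_high = which.max(pc1))
}

#' Morph trajectory between two conformers
#'
#' Cartesian linear interpolation between `a` and `b` after rigidly
#' superposing `b` onto `a` (fit on C-alpha atoms). Frame 1 equals `a`
#' exactly; the last frame equals the superposed `b`. Frames are geometric,
#' not physical, intermediates.
#'
#' @param a,b topology-identical [zip_structure()] conformers.
#' @param n_frames number of frames (>= 2).
#' @return a `zip_ensemble` whose members carry the interpolation parameter
#'   `t` in `attr(, "t")`.
#' @export
morph <- function(a, b, n_frames = 10) {
  stopifnot(inherits(a, "zip_structure"), inherits(b, "zip_structure"),
            n_frames >= 2)
  key_a <- paste(a$atom$chain, a$atom$resno, a$atom$resid, a$atom$elety)
  key_b <- paste(b$atom$chain, b$atom$resno, b$atom$resid, b$atom$elety)
  if (length(key_a) != length(key_b) || any(key_a != key_b)) {
    stop("topology mismatch between morph endpoints")
  }
  ca <- a$atom$elety == "CA" & !a$atom$het
  xyz_a <- as.matrix(a$atom[, c("x", "y", "z")])
  xyz_b <- as.matrix(b$atom[, c("x", "y", "z")])
  fit <- kabsch_superpose(xyz_b[ca, , drop = FALSE], xyz_a[ca, , drop = FALSE])
  xyz_b <- apply_transform(xyz_b, fit)
  ts <- seq(0, 1, length.out = n_frames)
  members <- lapply(seq_len(n_frames), function(i) {
    t_i <- ts[i]
    at <- a$atom
    xyz <- (1 - t_i) * xyz_a + t_i * xyz_b
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
    s <- zip_structure(at, id = sprintf("morph%03d", i))
    attr(s, "t") <- t_i
    s
  })
  validate_ensemble(members)
}
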