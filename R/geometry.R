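# Structural descriptors for C9 ring assemblies: least-squares circle
# fitting, N-terminal kink angle and length, backbone helicity, carotenoid
# bend angle, contact distances, superposition/RMSD.

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate-geometry error: zero-length vector")
  v / n
}

.angle_deg <- function(v1, v2) {
  u1 <- .unit(v1)
  u2 <- .unit(v2)
  acos(max(-1, min(1, sum(u1 * u2)))) * 180 / pi
}

.plane_basis <- function(normal) {
  n <- .unit(normal)
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .unit(a - sum(a * n) * n)
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  cbind(e1, e2)
}

#' Least-squares circle fit of ring points
#'
#' Points are projected onto the plane perpendicular to `plane_normal`
#' (for a membrane-embedded ring, the membrane normal; default z). The
#' returned center minimizes the radial-variance objective
#' \deqn{\Delta R^2 = \sum_i (r_i - \bar r)^2}
#' where \eqn{r_i} is the distance of point i from the center and
#' \eqn{\bar r} their mean; \eqn{\bar r} at the optimum is the ring radius.
#' The optimum is found by quasi-Newton descent with an analytic gradient,
#' started from the algebraic (Kasa) circle fit.
#'
#' @param points numeric n x 3 matrix (Angstrom), n >= 3.
#' @param plane_normal 3-vector, need not be unit length.
#' @return object of class `ring_fit` with `center` (2-vector in the fit
#'   plane), `r_bar`, `delta_r2`, `n_points`, `basis`, `normal`.
#' @export
fit_ring <- function(points, plane_normal = c(0, 0, 1)) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) {
    stop("degenerate-geometry error: need at least 3 points")
  }
  B <- .plane_basis(plane_normal)
  p2 <- points %*% B
  cen0 <- colMeans(p2)
  sv <- svd(sweep(p2, 2, cen0))$d
  if (sv[2] < 1e-9 * max(sv[1], 1)) {
    stop("degenerate-geometry error: points collinear after projection")
  }
  # Kasa algebraic fit as starting point
  A <- cbind(2 * p2[, 1], 2 * p2[, 2], 1)
  b <- p2[, 1]^2 + p2[, 2]^2
  k <- qr.solve(A, b)
  obj <- function(cc) {
    r <- sqrt((p2[, 1] - cc[1])^2 + (p2[, 2] - cc[2])^2)
    sum((r - mean(r))^2)
  }
  grad <- function(cc) {
    dx <- cc[1] - p2[, 1]
    dy <- cc[2] - p2[, 2]
    r <- sqrt(dx^2 + dy^2)
    w <- 2 * (r - mean(r)) / pmax(r, 1e-12)
    c(sum(w * dx), sum(w * dy))
  }
  fit <- stats::optim(k[1:2], obj, grad, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 500))
  r <- sqrt((p2[, 1] - fit$par[1])^2 + (p2[, 2] - fit$par[2])^2)
  structure(list(center = unname(fit$par), r_bar = mean(r),
                 delta_r2 = sum((r - mean(r))^2),
                 n_points = nrow(points),
                 basis = B, normal = .unit(plane_normal)),
            class = "ring_fit")
}

#' @export
print.ring_fit <- function(x, ...) {
  cat(sprintf("ring_fit: n = %d, r = %.3f A, deltaR2 = %.3g A^2\n",
              x$n_points, x$r_bar, x$delta_r2))
  invisible(x)
}

.centroid <- function(frame, sel, subunit = NULL) {
  idx <- resolve_selection(frame, sel, subunit)
  colMeans(frame_coords(frame, idx))
}

#' Default residue/atom ranges for the descriptors
#'
#' The alpha-polypeptide kink angle uses residue windows 1-3, 7-9 (kinked
#' N-terminal segment) and 12-14, 34-36 (main transmembrane helix). Ring
#' radii: alpha residues 26-32 (`r_up`) and 17-23 (`r_down`), beta residues
#' 77-82 (`R_up`) and 66-71 (`R_down`), the carotenoid C21-C30 tail (`t`)
#' and the B850 porphyrin centers (`T`). Note the source literature labels
#' the 26-32/77-82 rings inconsistently (cytoplasmic in the text,
#' periplasmic in a figure caption); descriptors here are keyed to residue
#' ranges, not surface names.
#'
#' @return named list of range definitions.
#' @export
descriptor_config <- function() {
  list(
    l_angle = list(seg_a = c(1L, 3L), seg_b = c(7L, 9L),
                   helix_a = c(12L, 14L), helix_b = c(34L, 36L)),
    r_up = list(role = "alpha", residues = c(26L, 32L)),
    r_down = list(role = "alpha", residues = c(17L, 23L)),
    R_up = list(role = "beta", residues = c(77L, 82L)),
    R_down = list(role = "beta", residues = c(66L, 71L)),
    t_atoms = paste0("C", 21:30),
    omega_groups = list(paste0("C", 9:13), paste0("C", 18:22),
                        paste0("C", 26:30)),
    T_mode = "per_pigment"
  )
}

#' Kink angle of the alpha-polypeptide N-terminus (L-angle)
#'
#' Angle between the N-terminal segment vector (centroid of residues 7-9
#' minus centroid of residues 1-3) and the main-helix vector (centroid of
#' residues 34-36 minus centroid of residues 12-14). Both vectors run
#' N-terminus to C-terminus, so an unkinked straight helix gives an angle
#' near 0 degrees. Centroids are unweighted heavy-atom centroids unless
#' `weights` supplies per-atom masses.
#'
#' @param frame a [structure_frame()].
#' @param subunit subunit index 0..8.
#' @param cfg ranges, see [descriptor_config()].
#' @return angle in degrees.
#' @export
l_angle <- function(frame, subunit, cfg = descriptor_config()$l_angle) {
  ch <- role_chain("alpha", subunit)
  cen <- function(rg, nm) .centroid(frame, selection(nm, ch, rg))
  v1 <- cen(cfg$seg_b, "l_angle seg 7-9") - cen(cfg$seg_a, "l_angle seg 1-3")
  v2 <- cen(cfg$helix_b, "l_angle helix 34-36") -
    cen(cfg$helix_a, "l_angle helix 12-14")
  .angle_deg(v1, v2)
}

#' Length of the alpha N-terminal segment
#'
#' Distance between the heavy-atom centroids of residues 1-3 and 7-9.
#'
#' @inheritParams l_angle
#' @return length in Angstrom.
#' @export
nterm_length <- function(frame, subunit,
                         cfg = descriptor_config()$l_angle) {
  ch <- role_chain("alpha", subunit)
  c1 <- .centroid(frame, selection("nterm 1-3", ch, cfg$seg_a))
  c2 <- .centroid(frame, selection("nterm 7-9", ch, cfg$seg_b))
  sqrt(sum((c2 - c1)^2))
}

.dihedral <- function(p1, p2, p3, p4) {
  bio3d::torsion.xyz(c(p1, p2, p3, p4), atm.inc = 4)
}

#' Backbone phi/psi dihedrals of one chain
#'
#' @param frame a [structure_frame()].
#' @param chain one-letter chain id.
#' @return data frame with `resid`, `phi`, `psi` (degrees, `NA` at termini
#'   or where backbone atoms are missing).
#' @export
phi_psi <- function(frame, chain) {
  sub <- frame[frame$chain == chain & frame$atom %in% c("N", "CA", "C"), ]
  if (nrow(sub) == 0L) stop("labeled-input error: chain ", chain, " empty")
  resids <- sort(unique(sub$resid))
  get <- function(r, a) {
    i <- which(sub$resid == r & sub$atom == a)
    if (length(i) != 1L) return(NULL)
    c(sub$x[i], sub$y[i], sub$z[i])
  }
  phi <- psi <- rep(NA_real_, length(resids))
  for (k in seq_along(resids)) {
    r <- resids[k]
    N <- get(r, "N"); CA <- get(r, "CA"); CC <- get(r, "C")
    if (is.null(N) || is.null(CA) || is.null(CC)) next
    Cm <- if ((r - 1) %in% resids) get(r - 1, "C") else NULL
    Np <- if ((r + 1) %in% resids) get(r + 1, "N") else NULL
    if (!is.null(Cm)) phi[k] <- .dihedral(Cm, N, CA, CC)
    if (!is.null(Np)) psi[k] <- .dihedral(N, CA, CC, Np)
  }
  data.frame(resid = resids, phi = phi, psi = psi)
}

#' Count residues in helical conformation
#'
#' A residue counts as helical when both its phi and psi dihedrals exist
#' and fall inside the alpha-helical window (defaults phi in
#' \[-100, -30\] and psi in \[-67, -7\] degrees). Terminal residues lacking
#' a neighbour for the dihedral are never counted.
#'
#' @param frame a [structure_frame()].
#' @param subunit subunit index (alpha chain used unless `chain` given).
#' @param residues integer vector of residue indices to score.
#' @param phi_window,psi_window inclusive degree windows.
#' @param chain optional explicit chain id.
#' @return integer count.
#' @export
helical_count <- function(frame, subunit, residues = 1:9,
                          phi_window = c(-100, -30),
                          psi_window = c(-67, -7),
                          chain = NULL) {
  if (is.null(chain)) chain <- role_chain("alpha", subunit)
  pp <- phi_psi(frame, chain)
  pp <- pp[pp$resid %in% residues, ]
  if (nrow(pp) == 0L) stop("labeled-input error: no backbone in range")
  ok <- !is.na(pp$phi) & !is.na(pp$psi) &
    pp$phi >= phi_window[1] & pp$phi <= phi_window[2] &
    pp$psi >= psi_window[1] & pp$psi <= psi_window[2]
  sum(ok)
}

#' Carotenoid bend angle (omega)
#'
#' Angle at the centroid of carbons C18-C22, formed with the centroids of
#' C9-C13 and C26-C30 of the same carotenoid chain. Collinear centroids
#' give 180 degrees.
#'
#' @inheritParams l_angle
#' @param groups list of three atom-name vectors, see
#'   [descriptor_config()].
#' @return angle in degrees.
#' @export
omega_angle <- function(frame, subunit,
                        groups = descriptor_config()$omega_groups) {
  ch <- role_chain("pigment", subunit)
  sub <- frame[frame$chain == ch & frame$resname == "RG1", ]
  if (nrow(sub) == 0L) stop("labeled-input error: no RG1 in subunit ", subunit)
  cen <- function(atoms) {
    i <- which(sub$atom %in% atoms)
    if (length(i) != length(atoms)) {
      stop("labeled-input error: RG1 carbons missing: ",
           paste(setdiff(atoms, sub$atom[i]), collapse = ","))
    }
    colMeans(cbind(sub$x[i], sub$y[i], sub$z[i]))
  }
  g1 <- cen(groups[[1]]); g2 <- cen(groups[[2]]); g3 <- cen(groups[[3]])
  .angle_deg(g1 - g2, g3 - g2)
}

#' Closest heavy-atom distance between two selections
#'
#' @param frame a [structure_frame()].
#' @param selA,selB [selection()]s.
#' @param subunit_a,subunit_b optional subunit restrictions.
#' @return minimum pairwise distance in Angstrom (0 with a warning when
#'   the selections share atoms).
#' @export
closest_distance <- function(frame, selA, selB,
                             subunit_a = NULL, subunit_b = NULL) {
  ia <- resolve_selection(frame, selA, subunit_a)
  ib <- resolve_selection(frame, selB, subunit_b)
  if (length(intersect(ia, ib)) > 0L) {
    warning("selections overlap; closest distance is 0")
    return(0)
  }
  A <- frame_coords(frame, ia)
  B <- frame_coords(frame, ib)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

.per_subunit_centroids <- function(frame, role, residues, atoms = NULL,
                                   resname = NULL) {
  pts <- list()
  for (s in 0:8) {
    ch <- role_chain(role, s)
    sub <- frame[frame$chain == ch, ]
    if (!is.null(resname)) sub <- sub[sub$resname == resname, ]
    if (!is.null(atoms)) {
      sub <- sub[sub$atom %in% atoms, ]
    } else {
      sub <- sub[sub$resid >= residues[1] & sub$resid <= residues[2] &
                   sub$elem != "H", ]
    }
    if (nrow(sub) > 0L) {
      pts[[length(pts) + 1L]] <- colMeans(cbind(sub$x, sub$y, sub$z))
    }
  }
  if (length(pts) < 3L) {
    stop("degenerate-geometry error: fewer than 3 subunits resolvable")
  }
  do.call(rbind, pts)
}

#' Per-pigment centroids of a pigment ring
#'
#' @param frame a [structure_frame()].
#' @param ring `"B800"` or `"B850"` (residue names B80/B85).
#' @return matrix of centroids, one row per pigment.
#' @export
pigment_centers <- function(frame, ring = c("B850", "B800")) {
  ring <- match.arg(ring)
  rn <- if (ring == "B850") "B85" else "B80"
  sub <- frame[frame$resname == rn & frame$elem != "H", ]
  if (nrow(sub) == 0L) stop("labeled-input error: no ", ring, " pigments")
  key <- paste(sub$chain, sub$resid)
  t(vapply(split(seq_len(nrow(sub)), key)[unique(key)], function(i) {
    colMeans(cbind(sub$x[i], sub$y[i], sub$z[i]))
  }, numeric(3)))
}

#' The six ring radii of a frame
#'
#' Fits circles (see [fit_ring()]) to the nine per-subunit heavy-atom
#' centroids of: alpha residues 26-32 (`r_up`) and 17-23 (`r_down`), beta
#' residues 77-82 (`R_up`) and 66-71 (`R_down`), the carotenoid C21-C30
#' tail (`t`), and the B850 porphyrin centers (`T`; all 18 pigments by
#' default, or 9 per-subunit pair centroids with `T_mode =
#' "per_subunit"`).
#'
#' @param frame a [structure_frame()].
#' @param cfg see [descriptor_config()].
#' @param plane_normal assembly symmetry axis (default z).
#' @return object of class `radii_set`: named list of `ring_fit`s plus a
#'   `radii` vector.
#' @export
radii_set <- function(frame, cfg = descriptor_config(),
                      plane_normal = c(0, 0, 1)) {
  fits <- list(
    r_up = fit_ring(.per_subunit_centroids(frame, "alpha",
                                           cfg$r_up$residues), plane_normal),
    r_down = fit_ring(.per_subunit_centroids(frame, "alpha",
                                             cfg$r_down$residues),
                      plane_normal),
    R_up = fit_ring(.per_subunit_centroids(frame, "beta",
                                           cfg$R_up$residues), plane_normal),
    R_down = fit_ring(.per_subunit_centroids(frame, "beta",
                                             cfg$R_down$residues),
                      plane_normal),
    t = fit_ring(.per_subunit_centroids(frame, "pigment", NULL,
                                        atoms = cfg$t_atoms,
                                        resname = "RG1"), plane_normal),
    T = if (identical(cfg$T_mode, "per_subunit")) {
      fit_ring(.per_subunit_centroids(frame, "pigment", NULL,
                                      atoms = NULL, resname = "B85"),
               plane_normal)
    } else {
      fit_ring(pigment_centers(frame, "B850"), plane_normal)
    }
  )
  structure(list(fits = fits,
                 radii = vapply(fits, function(f) f$r_bar, numeric(1))),
            class = "radii_set")
}

#' @export
print.radii_set <- function(x, ...) {
  cat("ring radii (A):\n")
  print(round(x$radii, 3))
  invisible(x)
}

#' Optimal superposition and RMSD
#'
#' Kabsch least-squares superposition of `mobile` onto `ref` over the
#' atoms of `sel` (proper rotation only, det = +1), via singular value
#' decomposition of the covariance of the centered coordinate sets.
#'
#' @param mobile,ref [structure_frame()]s with matching selections.
#' @param sel a [selection()]; defaults to all heavy atoms.
#' @return list with `rotation` (3x3), `translation` (3-vector), `rmsd`
#'   (Angstrom) and `xyz` (all mobile coordinates after superposition).
#'   The transform maps mobile coordinates as `(x - cm_mobile) R + cm_ref`.
#' @export
superpose_rmsd <- function(mobile, ref, sel = NULL) {
  if (is.null(sel)) {
    ia <- which(mobile$elem != "H")
    ib <- which(ref$elem != "H")
  } else {
    ia <- resolve_selection(mobile, sel)
    ib <- resolve_selection(ref, sel)
  }
  if (length(ia) != length(ib)) {
    stop("topology error: selection sizes differ (", length(ia), " vs ",
         length(ib), ")")
  }
  X <- frame_coords(mobile, ia)
  Y <- frame_coords(ref, ib)
  cmx <- colMeans(X)
  cmy <- colMeans(Y)
  Xc <- sweep(X, 2, cmx)
  Yc <- sweep(Y, 2, cmy)
  S <- t(Xc) %*% Yc
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  Xr <- Xc %*% R
  rmsd <- sqrt(mean(rowSums((Xr - Yc)^2)))
  all_xyz <- sweep(frame_coords(mobile), 2, cmx) %*% R
  all_xyz <- sweep(all_xyz, 2, cmy, "+")
  list(rotation = R, translation = cmy - cmx, rmsd = rmsd, xyz = all_xyz)
}

#' Representative frame of a trajectory
#'
#' All frames are superposed to the first over `sel`, the superposed
#' coordinates averaged, and each frame's RMSD to that average computed;
#' the index of the minimum is returned (ties broken by lowest index).
#'
#' @param traj list of [structure_frame()]s.
#' @param sel optional [selection()] (default all heavy atoms).
#' @return list with `index` (1-based) and `rmsd` (per-frame vector).
#' @export
representative_frame <- function(traj, sel = NULL) {
  stopifnot(length(traj) >= 1L)
  ref <- traj[[1]]
  idx <- if (is.null(sel)) which(ref$elem != "H") else
    resolve_selection(ref, sel)
  sup <- lapply(traj, function(fr) {
    superpose_rmsd(fr, ref, sel)$xyz[idx, , drop = FALSE]
  })
  avg <- Reduce("+", sup) / length(sup)
  rmsd <- vapply(sup, function(m) sqrt(mean(rowSums((m - avg)^2))),
                 numeric(1))
  list(index = which.min(rmsd), rmsd = rmsd)
}
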