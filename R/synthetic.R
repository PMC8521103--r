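# Synthetic C9-symmetric LH2-like assemblies. The generator builds one
# subunit from ideal-helix backbone proxies and exactly parameterized
# pigment proxies, replicates it by 360/n rotations about z, and adds
# optional Gaussian positional noise. Every geometric config parameter is
# recoverable exactly (zero noise) by the geometry module.

.BB_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8
)

.place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  # NeRF extension: position d with |c-d| = bond, angle(b,c,d), torsion(a,b,c,d)
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  b2 <- .unit(c - b)
  b1 <- .unit(b - a)
  n <- .unit(c(b1[2] * b2[3] - b1[3] * b2[2],
               b1[3] * b2[1] - b1[1] * b2[3],
               b1[1] * b2[2] - b1[2] * b2[1]))
  m <- c(n[2] * b2[3] - n[3] * b2[2],
         n[3] * b2[1] - n[1] * b2[3],
         n[1] * b2[2] - n[2] * b2[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + cbind(b2, m, n) %*% d2
}

#' Ideal backbone helix
#'
#' Builds an N/CA/C/O backbone chain with fixed ideal bond geometry and
#' uniform phi/psi dihedrals (defaults are the canonical alpha-helix
#' -57/-47 degrees, giving a rise of about 1.5 Angstrom and 100 degrees
#' twist per residue). The chain is oriented with its principal axis
#' along +z (N- to C-terminus in +z) and centered at the origin.
#'
#' @param n_res number of residues (>= 2).
#' @param phi,psi backbone dihedrals in degrees.
#' @return data frame with `resid`, `atom`, `x`, `y`, `z`.
#' @export
helix_backbone <- function(n_res, phi = -57, psi = -47) {
  stopifnot(n_res >= 2L)
  g <- .BB_GEOM
  N <- matrix(0, n_res, 3)
  CA <- matrix(0, n_res, 3)
  CC <- matrix(0, n_res, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  CC[1, ] <- CA[1, ] + g$b_ca_c *
    c(cos(pi - g$a_n_ca_c * pi / 180), sin(pi - g$a_n_ca_c * pi / 180), 0)
  for (i in seq_len(n_res - 1L)) {
    N[i + 1, ] <- .place_atom(N[i, ], CA[i, ], CC[i, ],
                              g$b_c_n, g$a_ca_c_n, psi)
    CA[i + 1, ] <- .place_atom(CA[i, ], CC[i, ], N[i + 1, ],
                               g$b_n_ca, g$a_c_n_ca, 180)
    CC[i + 1, ] <- .place_atom(CC[i, ], N[i + 1, ], CA[i + 1, ],
                               g$b_ca_c, g$a_n_ca_c, phi)
  }
  O <- matrix(0, n_res, 3)
  for (i in seq_len(n_res)) {
    O[i, ] <- .place_atom(N[i, ], CA[i, ], CC[i, ],
                          g$b_c_o, g$a_ca_c_o, psi + 180)
  }
  xyz <- rbind(N, CA, CC, O)
  ord <- as.vector(t(matrix(seq_len(4L * n_res), n_res, 4)))
  xyz <- xyz[ord, , drop = FALSE]
  # orient principal axis of CA trace along +z, centroid at origin
  cac <- sweep(CA, 2, colMeans(CA))
  ax <- svd(cac)$v[, 1]
  if (sum(ax * (CA[n_res, ] - CA[1, ])) < 0) ax <- -ax
  R <- .rotation_to_z(ax)
  xyz <- sweep(xyz, 2, colMeans(xyz)) %*% t(R)
  data.frame(
    resid = rep(seq_len(n_res), each = 4L),
    atom = rep(c("N", "CA", "C", "O"), n_res),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE
  )
}

.rotation_to_z <- function(v) {
  # rotation matrix sending unit vector v to +z (Rodrigues)
  v <- .unit(v)
  z <- c(0, 0, 1)
  c_ <- sum(v * z)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  k <- .unit(c(v[2] * z[3] - v[3] * z[2],
               v[3] * z[1] - v[1] * z[3],
               v[1] * z[2] - v[2] * z[1]))
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(acos(c_)) * K + (1 - c_) * K %*% K
}

.rotation_align <- function(a, b) {
  # rotation sending unit(a) to unit(b)
  t(.rotation_to_z(b)) %*% .rotation_to_z(a)
}

.rot_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

.rot_y <- function(theta) {
  matrix(c(cos(theta), 0, sin(theta),
           0, 1, 0,
           -sin(theta), 0, cos(theta)), 3, 3, byrow = TRUE)
}

#' Assembly configuration
#'
#' Geometry of the synthetic C9 assembly. Radii are in Angstrom, angles in
#' degrees. Ring radii are free parameters of the generator (no reference
#' geometry is reproduced); defaults follow canonical LH2 dimensions
#' (B850 ring ~23.5 A, B800 ~29 A) and the descriptor defaults correspond
#' to a physiological-temperature condition (kink angle 67.8 deg,
#' N-terminal segment length 12.1 A, carotenoid bend 151 deg).
#'
#' @param n_subunits number of subunits (3..9; default 9).
#' @param alpha_radius_top,alpha_radius_bottom radii of the alpha-helix
#'   rings fitted at residues 26-32 and 17-23.
#' @param beta_radius_top,beta_radius_bottom radii of the beta-helix rings
#'   fitted at residues 77-82 and 66-71.
#' @param b800_radius,b850_radius pigment-center ring radii.
#' @param rg1_tail_radius radius of the ring of carotenoid C21-C30 tail
#'   centroids.
#' @param l_angle_deg N-terminal kink angle.
#' @param nterm_length distance between the residue 1-3 and 7-9 centroids.
#' @param omega_deg carotenoid bend angle.
#' @param positional_noise_sd i.i.d. Gaussian noise per coordinate (A).
#' @param n_frames trajectory length for [generate_trajectory()].
#' @param seed RNG seed; all generator randomness flows from it.
#' @return object of class `assembly_config`.
#' @export
assembly_config <- function(n_subunits = 9L,
                            alpha_radius_top = 17.0,
                            alpha_radius_bottom = 18.0,
                            beta_radius_top = 26.5,
                            beta_radius_bottom = 27.5,
                            b800_radius = 29.0,
                            b850_radius = 23.5,
                            rg1_tail_radius = 19.0,
                            l_angle_deg = 67.8,
                            nterm_length = 12.1,
                            omega_deg = 151,
                            positional_noise_sd = 0.1,
                            n_frames = 10L,
                            seed = 1L) {
  cfg <- list(n_subunits = as.integer(n_subunits),
              alpha_radius_top = alpha_radius_top,
              alpha_radius_bottom = alpha_radius_bottom,
              beta_radius_top = beta_radius_top,
              beta_radius_bottom = beta_radius_bottom,
              b800_radius = b800_radius, b850_radius = b850_radius,
              rg1_tail_radius = rg1_tail_radius,
              l_angle_deg = l_angle_deg, nterm_length = nterm_length,
              omega_deg = omega_deg,
              positional_noise_sd = positional_noise_sd,
              n_frames = as.integer(n_frames), seed = as.integer(seed))
  class(cfg) <- "assembly_config"
  validate_assembly_config(cfg)
  cfg
}

#' @rdname assembly_config
#' @param cfg an `assembly_config`.
#' @export
validate_assembly_config <- function(cfg) {
  radii <- c(cfg$alpha_radius_top, cfg$alpha_radius_bottom,
             cfg$beta_radius_top, cfg$beta_radius_bottom,
             cfg$b800_radius, cfg$b850_radius, cfg$rg1_tail_radius)
  if (any(radii <= 0)) stop("config error: radii must be positive")
  if (cfg$l_angle_deg <= 0 || cfg$l_angle_deg >= 180) {
    stop("config error: l_angle_deg must lie in (0, 180)")
  }
  if (cfg$omega_deg <= 0 || cfg$omega_deg >= 180) {
    stop("config error: omega_deg must lie in (0, 180)")
  }
  if (cfg$positional_noise_sd < 0) {
    stop("config error: positional_noise_sd must be >= 0")
  }
  if (cfg$nterm_length <= 0) stop("config error: nterm_length must be > 0")
  if (cfg$n_subunits < 3L || cfg$n_subunits > 9L) {
    stop("config error: n_subunits must be 3..9")
  }
  if (cfg$n_frames < 1L) stop("config error: n_frames must be >= 1")
  invisible(cfg)
}

.solve_tilt <- function(u1, u2, r1, r2) {
  # place a z-aligned chain by rotation about y (tilt tau) and shift x0 so
  # that the radial distances of local centroids u1, u2 equal r1, r2
  fval <- function(p) {
    tau <- p[2]; x0 <- p[1]
    f <- function(u, r) {
      wx <- x0 + cos(tau) * u[1] + sin(tau) * u[3]
      sqrt(wx^2 + u[2]^2) - r
    }
    c(f(u1, r1), f(u2, r2))
  }
  p <- c(mean(c(r1, r2)), atan2(r2 - r1, u2[3] - u1[3]))
  for (i in 1:100) {
    f0 <- fval(p)
    if (max(abs(f0)) < 1e-13) break
    J <- matrix(0, 2, 2)
    h <- 1e-7
    for (j in 1:2) {
      ph <- p; ph[j] <- ph[j] + h
      J[, j] <- (fval(ph) - f0) / h
    }
    step <- tryCatch(solve(J, f0), error = function(e) NULL)
    if (is.null(step)) break
    p <- p - step
  }
  if (max(abs(fval(p))) > 1e-9) {
    stop("config error: helix placement infeasible for requested radii")
  }
  list(x0 = p[1], tau = p[2])
}

.apply_tilt <- function(xyz, sol, z0 = 0) {
  out <- xyz %*% t(.rot_y(sol$tau))
  out[, 1] <- out[, 1] + sol$x0
  out[, 3] <- out[, 3] + z0
  out
}

.range_centroid <- function(df, xyz, lo, hi) {
  i <- which(df$resid >= lo & df$resid <= hi)
  colMeans(xyz[i, , drop = FALSE])
}

.build_alpha <- function(cfg) {
  main <- helix_backbone(27L)
  main$resid <- main$resid + 9L       # residues 10..36
  mx <- as.matrix(main[, c("x", "y", "z")])
  u_dn <- .range_centroid(main, mx, 17, 23)
  u_up <- .range_centroid(main, mx, 26, 32)
  sol <- .solve_tilt(u_dn, u_up, cfg$alpha_radius_bottom,
                     cfg$alpha_radius_top)
  w0 <- .apply_tilt(rbind(u_dn, u_up), sol)
  z0 <- -mean(w0[, 3])
  mx <- .apply_tilt(mx, sol, z0)
  v2 <- .range_centroid(main, mx, 34, 36) - .range_centroid(main, mx, 12, 14)
  v2h <- .unit(v2)
  # N-terminal 9-residue segment: uniformly stretched/compressed along its
  # axis to the requested centroid span, then oriented at the kink angle
  seg <- helix_backbone(9L)
  sx <- as.matrix(seg[, c("x", "y", "z")])
  c13 <- .range_centroid(seg, sx, 1, 3)
  c79 <- .range_centroid(seg, sx, 7, 9)
  w <- c79 - c13
  wxy2 <- w[1]^2 + w[2]^2
  L <- cfg$nterm_length
  if (L^2 <= wxy2 + 1e-9) {
    stop("config error: nterm_length shorter than segment cross-section")
  }
  s <- sqrt(L^2 - wxy2) / abs(w[3])
  if (s > 4) stop("config error: kink segment cannot stretch to nterm_length")
  sx[, 3] <- sx[, 3] * s
  c13 <- .range_centroid(seg, sx, 1, 3)
  c79 <- .range_centroid(seg, sx, 7, 9)
  wh <- .unit(c79 - c13)
  ex <- c(1, 0, 0)
  p <- ex - sum(ex * v2h) * v2h
  if (sqrt(sum(p^2)) < 1e-9) stop("config error: degenerate kink plane")
  ph <- .unit(p)
  lr <- cfg$l_angle_deg * pi / 180
  u_t <- cos(lr) * v2h + sin(lr) * ph
  sx <- sx %*% t(.rotation_align(wh, u_t))
  c79n <- .range_centroid(seg, sx, 7, 9)
  n10 <- mx[which(main$resid == 10 & main$atom == "N"), ]
  shift <- (n10 - 3.0 * u_t) - c79n
  sx <- sweep(sx, 2, shift, "+")
  df <- rbind(
    data.frame(resid = seg$resid, atom = seg$atom, x = sx[, 1], y = sx[, 2],
               z = sx[, 3], stringsAsFactors = FALSE),
    data.frame(resid = main$resid, atom = main$atom, x = mx[, 1],
               y = mx[, 2], z = mx[, 3], stringsAsFactors = FALSE)
  )
  df$resname <- "ALA"
  df
}

.build_beta <- function(cfg) {
  bh <- helix_backbone(82L)
  bx <- as.matrix(bh[, c("x", "y", "z")])
  u_dn <- .range_centroid(bh, bx, 66, 71)
  u_up <- .range_centroid(bh, bx, 77, 82)
  sol <- .solve_tilt(u_dn, u_up, cfg$beta_radius_bottom, cfg$beta_radius_top)
  w0 <- .apply_tilt(rbind(u_dn, u_up), sol)
  z0 <- -mean(w0[, 3])
  bx <- .apply_tilt(bx, sol, z0)
  bx <- bx %*% t(.rot_z(pi / 9))    # offset beta ring by 20 deg
  data.frame(resid = bh$resid, atom = bh$atom, x = bx[, 1], y = bx[, 2],
             z = bx[, 3], resname = "ALA", stringsAsFactors = FALSE)
}

.porphyrin_proxy <- function(center, e1, e2, radius = 2.4) {
  # MG at the exact center plus 8 ring carbons placed symmetrically, so the
  # heavy-atom centroid is exactly `center`
  ang <- (0:7) * pi / 4
  ring <- t(sapply(ang, function(a) center + radius * (cos(a) * e1 +
                                                         sin(a) * e2)))
  data.frame(atom = c("MG", paste0("C", 1:8)),
             x = c(center[1], ring[, 1]), y = c(center[2], ring[, 2]),
             z = c(center[3], ring[, 3]), stringsAsFactors = FALSE)
}

.build_pigments <- function(cfg) {
  out <- list()
  # B800: porphyrin plane parallel to the membrane plane
  c800 <- c(cfg$b800_radius, 0, 14)
  d <- .porphyrin_proxy(c800, c(1, 0, 0), c(0, 1, 0))
  d$resid <- 1L; d$resname <- "B80"
  out[[1]] <- d
  # B850 pair at +/-10 deg: porphyrin plane spanned by ring tangent and z
  for (k in 1:2) {
    th <- if (k == 1) -pi / 18 else pi / 18
    cen <- c(cfg$b850_radius * cos(th), cfg$b850_radius * sin(th), 0)
    tanv <- c(-sin(th), cos(th), 0)
    d <- .porphyrin_proxy(cen, tanv, c(0, 0, 1))
    d$resid <- k + 1L; d$resname <- "B85"
    out[[k + 1L]] <- d
  }
  # RG1: 30-carbon chain in the radial x-z plane, bend angle omega at the
  # C18-C22 centroid, C21-C30 tail centroid exactly on rg1_tail_radius
  tR <- cfg$rg1_tail_radius
  g2 <- c(tR + 1.0, 0, 2.0)
  g3 <- c(tR, 0, 8.0)
  p_t <- c(tR, 0, 6.0)
  d23 <- .unit(g3 - g2)
  u <- as.numeric(.rot_y(cfg$omega_deg * pi / 180) %*% d23)
  if (u[3] > 0) u <- as.numeric(.rot_y(-cfg$omega_deg * pi / 180) %*% d23)
  g1 <- g2 + 9.0 * u
  da <- 1.2
  pos <- matrix(NA_real_, 30, 3)
  for (k in 0:4) pos[9 + k, ] <- g1 + (2 - k) * da * u
  for (k in 0:4) pos[18 + k, ] <- g2 + (k - 2) * da * d23
  for (k in 0:4) pos[26 + k, ] <- g3 + (k - 2) * da * d23
  for (k in 1:4) pos[13 + k, ] <- pos[13, ] + (k / 5) * (pos[18, ] - pos[13, ])
  for (k in 1:8) pos[9 - k, ] <- pos[9, ] + k * da * u
  m <- (10 * p_t - 5 * g3 - pos[21, ] - pos[22, ]) / 3
  cdir <- .unit(pos[26, ] - pos[22, ])
  pos[23, ] <- m - 0.8 * cdir
  pos[24, ] <- m
  pos[25, ] <- m + 0.8 * cdir
  d <- data.frame(atom = paste0("C", 1:30), x = pos[, 1], y = pos[, 2],
                  z = pos[, 3], stringsAsFactors = FALSE)
  d$resid <- 4L; d$resname <- "RG1"
  out[[4]] <- d
  do.call(rbind, lapply(out, function(x) {
    x[, c("resid", "atom", "x", "y", "z", "resname")]
  }))
}

#' Generate a synthetic C9 assembly frame
#'
#' One subunit (alpha pseudo-helix of 36 residues with a kinked N-terminal
#' segment, 82-residue beta pseudo-helix, one B800 and two B850 porphyrin
#' proxies, one 30-carbon carotenoid chain) is built from the config and
#' replicated by rotations of 360/n about z. Zero-noise frames reproduce
#' every geometric config parameter exactly when measured by the geometry
#' module.
#'
#' @param cfg an [assembly_config()].
#' @param .seed seed the RNG from `cfg$seed` before drawing noise
#'   (disabled internally by [generate_trajectory()], which seeds once).
#' @return a [structure_frame()].
#' @export
generate_assembly <- function(cfg = assembly_config(), .seed = TRUE) {
  validate_assembly_config(cfg)
  alpha <- .build_alpha(cfg)
  beta <- .build_beta(cfg)
  pig <- .build_pigments(cfg)
  rows <- list()
  for (s in seq_len(cfg$n_subunits) - 1L) {
    Rz <- .rot_z(2 * pi * s / cfg$n_subunits)
    rot <- function(df, chain) {
      xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(Rz)
      data.frame(atom = df$atom, elem = .element_from_name(df$atom),
                 resname = df$resname, resid = df$resid, chain = chain,
                 subunit = s, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- rot(alpha, role_chain("alpha", s))
    rows[[length(rows) + 1L]] <- rot(beta, role_chain("beta", s))
    rows[[length(rows) + 1L]] <- rot(pig, role_chain("pigment", s))
  }
  fr <- structure_frame(do.call(rbind, rows), time = 0)
  if (cfg$positional_noise_sd > 0) {
    if (.seed) set.seed(cfg$seed)
    xyz <- frame_coords(fr) +
      matrix(stats::rnorm(3L * nrow(fr), sd = cfg$positional_noise_sd),
             ncol = 3L)
    fr <- set_frame_coords(fr, xyz)
  }
  fr
}

#' Generate a pseudo-trajectory
#'
#' Frame t is a fresh assembly built from the config with each drifted
#' parameter interpolated linearly from its config value to value + drift
#' across the trajectory, plus i.i.d. Gaussian positional noise. All
#' randomness flows from `cfg$seed`; identical seeds give identical
#' output. This emulates slow conformational trends at toy scale and is a
#' test harness for the analysis, not molecular dynamics.
#'
#' @param cfg an [assembly_config()].
#' @param drift named list of total linear ramps over the trajectory, e.g.
#'   `list(alpha_radius_top = -0.5)`.
#' @return list of [structure_frame()]s.
#' @export
generate_trajectory <- function(cfg = assembly_config(), drift = NULL) {
  validate_assembly_config(cfg)
  if (!is.null(drift)) {
    bad <- setdiff(names(drift), names(cfg))
    if (length(bad) > 0L) {
      stop("config error: unknown drift parameter(s): ",
           paste(bad, collapse = ", "))
    }
  }
  set.seed(cfg$seed)
  n <- cfg$n_frames
  lapply(seq_len(n), function(t) {
    ct <- cfg
    if (!is.null(drift) && n > 1L) {
      for (p in names(drift)) {
        ct[[p]] <- cfg[[p]] + drift[[p]] * (t - 1) / (n - 1)
      }
    }
    fr <- generate_assembly(ct, .seed = FALSE)
    attr(fr, "time") <- as.numeric(t - 1L)
    fr
  })
}

#' Exciton-model configuration
#'
#' Site energies in eV, transition dipoles in Debye. The B800 site energy
#' is shifted by `b800_shift` (default -0.07 eV) when tables are
#' generated, the conventional calibration that places the B800 band at
#' 800 nm. `sigma_broadening` is the inhomogeneous Gaussian width
#' (default 0.022 eV). The absolute BChl site energy is a free input; the
#' shared default (1.628 eV for both rings) was calibrated once so that,
#' on the default synthetic geometry, the shifted B800 sites give a band
#' near 800 nm and the excitonically red-shifted B850 band falls near
#' 859 nm.
#'
#' @param e_b800,e_b850 unshifted site energies (eV).
#' @param b800_shift additive B800 calibration shift (eV).
#' @param mu_magnitude BChl transition-dipole magnitude (Debye).
#' @param dipole_orientation `"alternating"` (B850 tangents with
#'   alternating out-of-plane tilt, mimicking the dimerized pair) or
#'   `"tangential"`.
#' @param sigma_broadening Gaussian broadening sd (eV).
#' @param e_rg1,mu_rg1 carotenoid site energy (eV) and dipole (Debye),
#'   used only when carotenoid rows are requested.
#' @return object of class `exciton_config`.
#' @export
exciton_config <- function(e_b800 = 1.628, e_b850 = 1.628,
                           b800_shift = -0.07, mu_magnitude = 6.3,
                           dipole_orientation = c("alternating",
                                                  "tangential"),
                           sigma_broadening = 0.022,
                           e_rg1 = 2.30, mu_rg1 = 13.0) {
  dipole_orientation <- match.arg(dipole_orientation)
  if (sigma_broadening <= 0) stop("config error: sigma_broadening must be > 0")
  if (mu_magnitude <= 0) stop("config error: mu_magnitude must be > 0")
  structure(list(e_b800 = e_b800, e_b850 = e_b850, b800_shift = b800_shift,
                 mu_magnitude = mu_magnitude,
                 dipole_orientation = dipole_orientation,
                 sigma_broadening = sigma_broadening,
                 e_rg1 = e_rg1, mu_rg1 = mu_rg1),
            class = "exciton_config")
}

#' Pigment table of a synthetic frame
#'
#' One row per pigment: positions at the porphyrin-proxy heavy-atom
#' centroids; B800 dipoles tangential to the ring, B850 dipoles tangential
#' with alternating out-of-plane tilt (or purely tangential, per config);
#' all magnitudes equal `mu_magnitude`. B800 site energies are
#' `e_b800 + b800_shift`. With `include_rg1`, carotenoid rows are added
#' (position at the C21-C30 tail centroid — the segment in contact with
#' B850 — dipole along the tail direction); these never enter the BChl
#' Hamiltonian by default.
#'
#' @param frame a [structure_frame()] with labeled pigment proxies.
#' @param xcfg an [exciton_config()].
#' @param include_rg1 add carotenoid rows.
#' @return a `pigment_table` data frame.
#' @export
generate_pigment_table <- function(frame, xcfg = exciton_config(),
                                   include_rg1 = FALSE) {
  rows <- list()
  tilt <- 10 * pi / 180
  add <- function(id, ring, e, pos, mu) {
    data.frame(pigment_id = id, ring = ring, site_energy_eV = e,
               pos_x = pos[1], pos_y = pos[2], pos_z = pos[3],
               mu_x = mu[1], mu_y = mu[2], mu_z = mu[3],
               stringsAsFactors = FALSE)
  }
  b850_k <- 0L
  for (s in 0:8) {
    ch <- role_chain("pigment", s)
    sub <- frame[frame$chain == ch, ]
    if (nrow(sub) == 0L) next
    for (r in sort(unique(sub$resid))) {
      pr <- sub[sub$resid == r & sub$elem != "H", ]
      rn <- pr$resname[1]
      cen <- colMeans(cbind(pr$x, pr$y, pr$z))
      if (rn == "B80") {
        th <- atan2(cen[2], cen[1])
        mu <- xcfg$mu_magnitude * c(-sin(th), cos(th), 0)
        rows[[length(rows) + 1L]] <-
          add(sprintf("B800_s%d", s), "B800",
              xcfg$e_b800 + xcfg$b800_shift, cen, mu)
      } else if (rn == "B85") {
        th <- atan2(cen[2], cen[1])
        tv <- c(-sin(th), cos(th), 0)
        if (xcfg$dipole_orientation == "alternating") {
          sgn <- if (b850_k %% 2L == 0L) 1 else -1
          mu <- xcfg$mu_magnitude *
            .unit(cos(tilt) * tv + sgn * sin(tilt) * c(0, 0, 1))
        } else {
          mu <- xcfg$mu_magnitude * tv
        }
        b850_k <- b850_k + 1L
        rows[[length(rows) + 1L]] <-
          add(sprintf("B850_s%d_%d", s, r - 1L), "B850", xcfg$e_b850,
              cen, mu)
      } else if (rn == "RG1" && include_rg1) {
        # the tail segment is the part that couples to B850: dipole
        # centered on the C21-C30 centroid, oriented along the tail
        i21 <- which(pr$atom %in% paste0("C", 21:30))
        i18 <- which(pr$atom %in% paste0("C", 18:22))
        i26 <- which(pr$atom %in% paste0("C", 26:30))
        tail_cen <- colMeans(cbind(pr$x[i21], pr$y[i21], pr$z[i21]))
        dirv <- .unit(colMeans(cbind(pr$x[i26], pr$y[i26], pr$z[i26])) -
                        colMeans(cbind(pr$x[i18], pr$y[i18], pr$z[i18])))
        rows[[length(rows) + 1L]] <-
          add(sprintf("RG1_s%d", s), "RG1", xcfg$e_rg1, tail_cen,
              xcfg$mu_rg1 * dirv)
      }
    }
  }
  if (length(rows) == 0L) {
    stop("labeled-input error: frame carries no labeled pigments")
  }
  as_pigment_table(do.call(rbind, rows))
}

#' Read/write assembly and exciton configs as YAML
#'
#' Field names mirror [assembly_config()] / [exciton_config()].
#'
#' @param path YAML file.
#' @return the corresponding config object.
#' @export
read_assembly_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(assembly_config, y)
}

#' @rdname read_assembly_config
#' @export
read_exciton_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(exciton_config, y)
}

#' @rdname read_assembly_config
#' @param cfg a config object.
#' @export
write_config_yaml <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
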