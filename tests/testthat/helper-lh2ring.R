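# Shared fixtures and independent oracles for the test suite.

# points on an exact circle of given radius/center in the z = z0 plane
circle_points <- function(n = 9, radius = 30, center = c(0, 0), z0 = 0,
                          phase = 0) {
  th <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th), z0)
}

# brute-force grid-search minimizer of the radial-variance circle
# objective: 0.25 A coarse grid, then two refinement stages down to 1e-4 A
grid_circle_oracle <- function(points2d) {
  obj_all <- function(cx, cy) {
    # vectorized objective over the full center grid
    g <- expand.grid(cx = cx, cy = cy)
    r <- sqrt(outer(points2d[, 1], g$cx, "-")^2 +
                outer(points2d[, 2], g$cy, "-")^2)
    colSums(sweep(r, 2, colMeans(r))^2)
  }
  cen <- colMeans(points2d)
  best <- cen
  for (stage in list(c(3, 0.25), c(0.3, 0.01), c(0.012, 1e-4))) {
    cx <- seq(best[1] - stage[1], best[1] + stage[1], by = stage[2])
    cy <- seq(best[2] - stage[1], best[2] + stage[1], by = stage[2])
    v <- obj_all(cx, cy)
    g <- expand.grid(cx = cx, cy = cy)
    best <- as.numeric(g[which.min(v), ])
  }
  r <- sqrt((points2d[, 1] - best[1])^2 + (points2d[, 2] - best[2])^2)
  list(center = best, objective = sum((r - mean(r))^2))
}

circle_objective <- function(points2d, center) {
  r <- sqrt((points2d[, 1] - center[1])^2 + (points2d[, 2] - center[2])^2)
  sum((r - mean(r))^2)
}

# uniform random rotation matrix from a quaternion
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  quat_to_rot(q)
}

quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# apply a rigid transform to every coordinate of a frame
transform_frame <- function(frame, R = diag(3), shift = c(0, 0, 0)) {
  xyz <- frame_coords(frame) %*% t(R)
  xyz <- sweep(xyz, 2, shift, "+")
  set_frame_coords(frame, xyz)
}

zero_noise_cfg <- function(...) {
  assembly_config(positional_noise_sd = 0, ...)
}

# minimal hand-written PDB fixture (3 atoms, 2 residues, chain A)
tiny_pdb_lines <- function() {
  c("ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.500   2.250   3.125  1.00  0.00           C",
    "ATOM      3  N   GLY A   2       4.000  -1.000   0.500  1.00  0.00           N",
    "END")
}

# line-by-line reference PDB parser used as an io oracle (fixed columns)
reference_parse_pdb <- function(path) {
  lines <- readLines(path)
  models <- list()
  cur <- NULL
  for (ln in lines) {
    tag <- substr(ln, 1, 6)
    if (tag %in% c("ATOM  ", "HETATM")) {
      cur <- rbind(cur, data.frame(
        atom = trimws(substr(ln, 13, 16)),
        resname = trimws(substr(ln, 18, 20)),
        chain = substr(ln, 22, 22),
        resno = as.integer(substr(ln, 23, 26)),
        x = as.numeric(substr(ln, 31, 38)),
        y = as.numeric(substr(ln, 39, 46)),
        z = as.numeric(substr(ln, 47, 54)),
        stringsAsFactors = FALSE))
    } else if (trimws(tag) == "ENDMDL") {
      models[[length(models) + 1L]] <- cur
      cur <- NULL
    }
  }
  if (!is.null(cur) && nrow(cur) > 0) models[[length(models) + 1L]] <- cur
  models
}

# crafted toy trajectory for occupancy tests: one pair of atoms per
# subunit whose distance per frame is given by `dists[[subunit]]`
contact_toy_traj <- function(dists) {
  n_frames <- length(dists[[1]])
  n_sub <- length(dists)
  lapply(seq_len(n_frames), function(f) {
    rows <- do.call(rbind, lapply(seq_len(n_sub), function(s) {
      d <- dists[[s]][f]
      data.frame(
        atom = c("O", "N"), elem = c("O", "N"), resname = c("ALA", "ALA"),
        resid = c(4L, 61L),
        chain = c(role_chain("alpha", s - 1L), role_chain("beta", s - 1L)),
        subunit = s - 1L,
        x = c(0, d) + 10 * s, y = 0, z = 0, stringsAsFactors = FALSE)
    }))
    structure_frame(rows, time = f - 1)
  })
}
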