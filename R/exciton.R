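# Point-dipole Frenkel exciton model: orientation factor, dipole-dipole
# couplings, Hamiltonian assembly and diagonalization, Gaussian-broadened
# absorption spectra, ensemble averaging, and two-Gaussian peak fitting.

# Vacuum dipole-dipole prefactor: with mu in Debye (1 D = 1e-18 esu cm)
# and R in Angstrom, V = KAPPA_CM * |mu_i||mu_j| * kappa / R^3 is in cm^-1:
# (1e-18)^2 / (1e-8)^3 erg = 1e-12 erg, divided by hc = 1.9864e-16 erg cm.
.PDA_CM <- 5034.12        # cm^-1 A^3 D^-2
.EV_PER_CM <- 1.239841984e-4
.HC_EV_NM <- 1239.841984  # lambda(nm) = HC / E(eV)

#' Dipole orientation factor kappa
#'
#' \deqn{\kappa = \hat\mu_i \cdot \hat\mu_j
#'   - 3 (\hat\mu_i \cdot \hat R_{ij})(\hat\mu_j \cdot \hat R_{ij})}
#' computed from unit vectors; symmetric in i and j, bounded in \[-2, 2\].
#'
#' @param mu_i,mu_j transition-dipole vectors (any nonzero length).
#' @param r_ij separation vector.
#' @return dimensionless scalar.
#' @export
kappa <- function(mu_i, mu_j, r_ij) {
  ui <- .unit(mu_i)
  uj <- .unit(mu_j)
  rh <- .unit(r_ij)
  sum(ui * uj) - 3 * sum(ui * rh) * sum(uj * rh)
}

#' Point-dipole approximation coupling
#'
#' \deqn{V_{ij} = C \, |\mu_i||\mu_j| \kappa / R_{ij}^3}
#' with mu in Debye, R in Angstrom and the vacuum conversion constant
#' C = 5034.12 cm^-1 A^3 D^-2 (no dielectric screening), converted to eV.
#'
#' @param site_i,site_j rows of a pigment table, or lists with
#'   `pos_x/pos_y/pos_z`, `mu_x/mu_y/mu_z`.
#' @return coupling in eV.
#' @export
pda_coupling <- function(site_i, site_j) {
  pi_ <- c(site_i$pos_x, site_i$pos_y, site_i$pos_z)
  pj <- c(site_j$pos_x, site_j$pos_y, site_j$pos_z)
  mi <- c(site_i$mu_x, site_i$mu_y, site_i$mu_z)
  mj <- c(site_j$mu_x, site_j$mu_y, site_j$mu_z)
  r <- pj - pi_
  R <- sqrt(sum(r^2))
  if (R < 1e-9) stop("degenerate-geometry error: coincident pigments")
  k <- kappa(mi, mj, r)
  v_cm <- .PDA_CM * sqrt(sum(mi^2)) * sqrt(sum(mj^2)) * k / R^3
  v_cm * .EV_PER_CM
}

#' Build the Frenkel exciton Hamiltonian
#'
#' Diagonal: site energies; off-diagonal: `coupling_fn(site_m, site_n)`
#' (default point-dipole coupling), computed once per pair so the matrix
#' is symmetric by construction. Carotenoid (RG1) rows are excluded by
#' default: the Hamiltonian covers the two BChl rings.
#'
#' @param sites a `pigment_table`.
#' @param coupling_fn pair coupling function returning eV.
#' @param rings rings admitted to the Hamiltonian.
#' @return object of class `exciton_hamiltonian` with `matrix` (eV) and
#'   `sites` (the admitted rows, in order).
#' @export
build_hamiltonian <- function(sites, coupling_fn = pda_coupling,
                              rings = c("B800", "B850")) {
  sites <- as_pigment_table(as.data.frame(sites))
  sites <- sites[sites$ring %in% rings, , drop = FALSE]
  n <- nrow(sites)
  if (n < 1L) stop("labeled-input error: no sites in requested rings")
  H <- diag(sites$site_energy_eV, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        v <- coupling_fn(sites[i, ], sites[j, ])
        H[i, j] <- v
        H[j, i] <- v
      }
    }
  }
  dimnames(H) <- list(sites$pigment_id, sites$pigment_id)
  structure(list(matrix = H, sites = sites), class = "exciton_hamiltonian")
}

#' @export
print.exciton_hamiltonian <- function(x, ...) {
  cat(sprintf("exciton_hamiltonian: %d sites, trace %.4f eV\n",
              nrow(x$matrix), sum(diag(x$matrix))))
  invisible(x)
}

#' Diagonalize an exciton Hamiltonian
#'
#' Returns ascending eigenvalues E_i and eigenstate transition-dipole
#' magnitudes M_i = ||sum_n c_in mu_n||. Within a degenerate pair the
#' individual M_i are basis-dependent; only pair sums of M^2 are stable,
#' which is how they should be consumed.
#'
#' @param H an `exciton_hamiltonian` (or symmetric matrix plus `sites`).
#' @param sites pigment table supplying dipoles when `H` is a bare matrix.
#' @return object of class `exciton_result` with `energies` (eV),
#'   `dipole_strengths` M_i (Debye), `coefficients` (columns = states).
#' @export
diagonalize_hamiltonian <- function(H, sites = NULL) {
  if (inherits(H, "exciton_hamiltonian")) {
    sites <- H$sites
    H <- H$matrix
  }
  if (max(abs(H - t(H))) > 1e-9) {
    stop("invariant violation: Hamiltonian not symmetric")
  }
  e <- eigen(H, symmetric = TRUE)
  ord <- order(e$values)
  vals <- e$values[ord]
  C <- e$vectors[, ord, drop = FALSE]
  mu <- as.matrix(sites[, c("mu_x", "mu_y", "mu_z")])
  md <- t(C) %*% mu                       # state dipoles, rows = states
  M <- sqrt(rowSums(md^2))
  structure(list(energies = vals, dipole_strengths = M, coefficients = C,
                 site_ids = sites$pigment_id),
            class = "exciton_result")
}

#' @export
print.exciton_result <- function(x, ...) {
  cat(sprintf("exciton_result: %d states, E in [%.4f, %.4f] eV\n",
              length(x$energies), min(x$energies), max(x$energies)))
  invisible(x)
}

#' Shift the site energies of one ring
#'
#' Pure function adding `delta` (eV) to every site of `ring`; used e.g.
#' for the -0.07 eV B800 calibration shift.
#'
#' @param sites a `pigment_table`.
#' @param ring `"B800"`, `"B850"` or `"RG1"`.
#' @param delta shift in eV.
#' @return the shifted table.
#' @export
apply_ring_shift <- function(sites, ring, delta) {
  if (!ring %in% c("B800", "B850", "RG1")) {
    stop("config error: unknown ring '", ring, "'")
  }
  i <- sites$ring == ring
  sites$site_energy_eV[i] <- sites$site_energy_eV[i] + delta
  sites
}

#' Gaussian-broadened absorption spectrum
#'
#' \deqn{A(v) = \frac{v}{\sqrt{2\pi}\sigma} \sum_i M_i^2
#'   \exp[-(E_i - v)^2 / 2\sigma^2]}
#' evaluated on an energy grid; the frequency prefactor v is the grid
#' energy (not E_i), so a single-state spectrum peaks within ~sigma^2/E of
#' the state energy — below one grid step at the defaults.
#'
#' @param result an `exciton_result`.
#' @param sigma Gaussian sd in eV (default 0.022).
#' @param grid energy grid in eV (uniform).
#' @return object of class `spectrum` with `energy_eV`, `wavelength_nm`,
#'   `absorbance`, `sigma`.
#' @export
exciton_spectrum <- function(result, sigma = 0.022,
                             grid = seq(1.2, 1.9, by = 0.001)) {
  stopifnot(sigma > 0)
  E <- result$energies
  if (min(grid) > min(E) - 5 * sigma || max(grid) < max(E) + 5 * sigma) {
    warning("grid does not cover [min E - 5 sigma, max E + 5 sigma]")
  }
  M2 <- result$dipole_strengths^2
  A <- vapply(grid, function(v) {
    v / (sqrt(2 * pi) * sigma) *
      sum(M2 * exp(-(E - v)^2 / (2 * sigma^2)))
  }, numeric(1))
  structure(list(energy_eV = grid, wavelength_nm = .HC_EV_NM / grid,
                 absorbance = A, sigma = sigma), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  i <- which.max(x$absorbance)
  cat(sprintf("spectrum: %d grid points, max at %.4f eV (%.1f nm)\n",
              length(x$energy_eV), x$energy_eV[i], x$wavelength_nm[i]))
  invisible(x)
}

#' Ensemble (pointwise-mean) spectrum
#'
#' @param spectra list of `spectrum` objects on a common grid.
#' @return a `spectrum`.
#' @export
ensemble_spectrum <- function(spectra) {
  stopifnot(length(spectra) >= 1L)
  g <- spectra[[1]]$energy_eV
  for (s in spectra) {
    if (length(s$energy_eV) != length(g) || any(s$energy_eV != g)) {
      stop("config error: spectra are not on a common grid")
    }
  }
  A <- Reduce("+", lapply(spectra, function(s) s$absorbance)) /
    length(spectra)
  structure(list(energy_eV = g, wavelength_nm = .HC_EV_NM / g,
                 absorbance = A, sigma = spectra[[1]]$sigma),
            class = "spectrum")
}

.local_maxima <- function(y) {
  n <- length(y)
  which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf))
}

#' Two-Gaussian (bimodal) fit of a spectrum
#'
#' Nonlinear least squares of
#' \eqn{a_1 e^{-(E-c_1)^2/2w_1^2} + a_2 e^{-(E-c_2)^2/2w_2^2}} on the
#' energy grid (Levenberg-Marquardt). Initial centers are the two highest
#' local maxima separated by at least 3 grid steps unless `init` is given.
#' A fit where one component carries less than 1% of the total area is
#' flagged degenerate (single-peak input).
#'
#' @param spec a `spectrum`.
#' @param init optional two initial centers (eV).
#' @return object of class `bimodal_fit` with `amplitude`, `center_eV`,
#'   `width_eV`, `peak_nm` (per component, sorted by center), `residual`,
#'   `degenerate`.
#' @export
bimodal_fit <- function(spec, init = NULL) {
  E <- spec$energy_eV
  A <- spec$absorbance
  if (any(A < 0)) stop("invariant violation: negative absorbance")
  step <- E[2] - E[1]
  if (is.null(init)) {
    # smooth lightly before peak picking so shot noise does not split one
    # band into two adjacent "maxima"
    w <- max(3L, 2L * floor(spec$sigma / step / 4) + 1L)
    As <- stats::filter(A, rep(1 / w, w), sides = 2)
    As[is.na(As)] <- A[is.na(As)]
    lm_ <- .local_maxima(as.numeric(As))
    lm_ <- lm_[order(A[lm_], decreasing = TRUE)]
    min_sep <- max(3 * step, 2 * spec$sigma)
    picks <- lm_[1]
    for (i in lm_[-1]) {
      if (all(abs(E[i] - E[picks]) > min_sep)) {
        picks <- c(picks, i)
        break
      }
    }
    if (length(picks) < 2L) {
      # single visible peak: seed the second component on its shoulder
      picks <- c(picks, min(length(E), picks[1] + 10L))
    }
    init <- E[picks]
  }
  d <- data.frame(E = E, A = A)
  a0 <- stats::approx(E, A, xout = init, rule = 2)$y
  a0[a0 <= 0] <- max(A) / 100
  st <- list(a1 = a0[1], c1 = init[1], w1 = spec$sigma,
             a2 = a0[2], c2 = init[2], w2 = spec$sigma)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      A ~ a1 * exp(-(E - c1)^2 / (2 * w1^2)) +
        a2 * exp(-(E - c2)^2 / (2 * w2^2)),
      data = d, start = st,
      lower = c(0, min(E), 1e-4, 0, min(E), 1e-4),
      upper = c(Inf, max(E), diff(range(E)), Inf, max(E), diff(range(E))),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    stop("fit non-convergence: ", conditionMessage(fit),
         " (initial centers ", paste(signif(init, 5), collapse = ", "), ")")
  }
  p <- stats::coef(fit)
  comp <- data.frame(amplitude = c(p["a1"], p["a2"]),
                     center_eV = c(p["c1"], p["c2"]),
                     width_eV = abs(c(p["w1"], p["w2"])))
  comp <- comp[order(comp$center_eV), ]
  rownames(comp) <- NULL
  area <- comp$amplitude * comp$width_eV
  degenerate <- min(area) < 0.01 * sum(area)
  structure(list(amplitude = comp$amplitude, center_eV = comp$center_eV,
                 width_eV = comp$width_eV,
                 peak_nm = .HC_EV_NM / comp$center_eV,
                 residual = sqrt(sum(stats::resid(fit)^2)),
                 degenerate = degenerate),
            class = "bimodal_fit")
}

#' @export
print.bimodal_fit <- function(x, ...) {
  cat("bimodal_fit:\n")
  for (i in 1:2) {
    cat(sprintf("  component %d: center %.4f eV (%.1f nm), width %.4f eV, amplitude %.3g\n",
                i, x$center_eV[i], x$peak_nm[i], x$width_eV[i],
                x$amplitude[i]))
  }
  if (x$degenerate) cat("  [degenerate: one component < 1% of total area]\n")
  invisible(x)
}

#' Pairwise coupling report
#'
#' All couplings between two rings (e.g. the carotenoid-B850 pairs),
#' with separations, orientation factors and couplings in meV, plus the
#' per-donor maximum |V|.
#'
#' @param sites a `pigment_table` containing both rings.
#' @param ring_a,ring_b ring names.
#' @return list with `pairs` (data frame: pair, R_A, kappa, V_meV) and
#'   `max_by_a` (named vector of per-`ring_a`-site max |V| in meV).
#' @export
coupling_report <- function(sites, ring_a = "RG1", ring_b = "B850") {
  a <- sites[sites$ring == ring_a, , drop = FALSE]
  b <- sites[sites$ring == ring_b, , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop("labeled-input error: ring(s) absent from table")
  }
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      r <- c(b$pos_x[j] - a$pos_x[i], b$pos_y[j] - a$pos_y[i],
             b$pos_z[j] - a$pos_z[i])
      out[[length(out) + 1L]] <- data.frame(
        pair = paste(a$pigment_id[i], b$pigment_id[j], sep = "-"),
        a_id = a$pigment_id[i],
        R_A = sqrt(sum(r^2)),
        kappa = kappa(c(a$mu_x[i], a$mu_y[i], a$mu_z[i]),
                      c(b$mu_x[j], b$mu_y[j], b$mu_z[j]), r),
        V_meV = 1000 * pda_coupling(a[i, ], b[j, ]),
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, out)
  max_by_a <- tapply(abs(pairs$V_meV), pairs$a_id, max)
  list(pairs = pairs[, c("pair", "R_A", "kappa", "V_meV")],
       max_by_a = max_by_a)
}
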