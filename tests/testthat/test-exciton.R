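test_that("orientation factor has the textbook closed forms and bounds", {
  # parallel dipoles, both perpendicular to the separation
  expect_equal(kappa(c(0, 0, 2), c(0, 0, 5), c(3, 0, 0)), 1)
  # collinear head-to-tail
  expect_equal(kappa(c(1, 0, 0), c(2, 0, 0), c(4, 0, 0)), -2)
  # mutually perpendicular, one perpendicular to the separation
  expect_equal(kappa(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0)), 0)
  # symmetry in i <-> j
  set.seed(1)
  for (k in 1:25) {
    a <- rnorm(3); b <- rnorm(3); r <- rnorm(3)
    expect_equal(kappa(a, b, r), kappa(b, a, r), tolerance = 1e-12)
  }
  # bounded in [-2, 2] over many random orientations
  set.seed(2)
  n <- 20000
  A <- matrix(rnorm(3 * n), ncol = 3)
  B <- matrix(rnorm(3 * n), ncol = 3)
  R <- matrix(rnorm(3 * n), ncol = 3)
  k <- vapply(seq_len(n), function(i) kappa(A[i, ], B[i, ], R[i, ]),
              numeric(1))
  expect_true(all(abs(k) <= 2 + 1e-12))
  expect_error(kappa(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0)), "zero-length")
})

test_that("point-dipole coupling has the right constant, symmetry and power law", {
  site <- function(pos, mu) {
    list(pos_x = pos[1], pos_y = pos[2], pos_z = pos[3],
         mu_x = mu[1], mu_y = mu[2], mu_z = mu[3])
  }
  # |mu| = 6.3 D each, R = 10 A, kappa = 1:
  # V = 5034.12 * 6.3^2 / 1000 cm^-1 = 199.804... cm^-1 -> eV
  v <- pda_coupling(site(c(0, 0, 0), c(0, 0, 6.3)),
                    site(c(10, 0, 0), c(0, 0, 6.3)))
  expect_equal(v, 5034.12 * 6.3^2 / 1e3 * 1.239841984e-4, tolerance = 1e-12)
  # kappa = 0 -> exactly zero
  expect_equal(pda_coupling(site(c(0, 0, 0), c(0, 0, 1)),
                            site(c(5, 0, 0), c(0, 1, 0))), 0)
  # R -> 2R at fixed orientation: V scales by 1/8
  v2 <- pda_coupling(site(c(0, 0, 0), c(0, 0, 6.3)),
                     site(c(20, 0, 0), c(0, 0, 6.3)))
  expect_equal(v2 / v, 1 / 8, tolerance = 1e-12)
  # log-log slope -3 over a log-spaced grid
  Rg <- 10^seq(0.5, 2, length.out = 12)
  vv <- vapply(Rg, function(r) {
    pda_coupling(site(c(0, 0, 0), c(0, 0, 6.3)),
                 site(c(r, 0, 0), c(0, 0, 6.3)))
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(vv) ~ log(Rg)))[2]
  expect_equal(unname(slope), -3, tolerance = 1e-6)
  # moving one dipole radially outward strictly decreases |V|
  expect_true(all(diff(abs(vv)) < 0))
  expect_error(pda_coupling(site(c(1, 1, 1), c(0, 0, 1)),
                            site(c(1, 1, 1), c(0, 0, 1))), "coincident")
})

test_that("Hamiltonian assembly matches small closed forms", {
  tab <- as_pigment_table(data.frame(
    pigment_id = c("p1", "p2"), ring = "B850",
    site_energy_eV = c(1.5, 1.7),
    pos_x = c(0, 100), pos_y = 0, pos_z = 0,
    mu_x = 0, mu_y = 0, mu_z = 6.3, stringsAsFactors = FALSE))
  # far apart: coupling negligible -> eigenvalues are the site energies
  res <- diagonalize_hamiltonian(build_hamiltonian(tab))
  expect_equal(res$energies, c(1.5, 1.7), tolerance = 1e-6)

  # two identical sites with coupling V: eigenvalues eps +/- V
  cpl <- function(a, b) 0.013
  tab$site_energy_eV <- c(1.6, 1.6)
  res2 <- diagonalize_hamiltonian(build_hamiltonian(tab, coupling_fn = cpl))
  expect_equal(res2$energies, c(1.6 - 0.013, 1.6 + 0.013),
               tolerance = 1e-12)

  # trace conservation on the 27-site synthetic table
  fr <- generate_assembly(zero_noise_cfg())
  t27 <- generate_pigment_table(fr, exciton_config())
  H <- build_hamiltonian(t27)
  expect_equal(max(abs(H$matrix - t(H$matrix))), 0)
  expect_equal(sum(diag(H$matrix)), sum(t27$site_energy_eV),
               tolerance = 1e-12)
  r27 <- diagonalize_hamiltonian(H)
  expect_equal(sum(r27$energies), sum(t27$site_energy_eV),
               tolerance = 1e-9)
  # oscillator strength conservation
  mu2 <- sum(t27$mu_x^2 + t27$mu_y^2 + t27$mu_z^2)
  expect_equal(sum(r27$dipole_strengths^2), mu2, tolerance = 1e-6)
  # orthonormal coefficients
  C <- r27$coefficients
  expect_lt(max(abs(t(C) %*% C - diag(27))), 1e-9)

  dup <- t27
  dup$pigment_id[2] <- dup$pigment_id[1]
  expect_error(build_hamiltonian(dup), "duplicate")
})

test_that("a C9 nearest-neighbour ring reproduces the circulant spectrum", {
  eps <- 1.6
  V <- -0.03
  pos <- circle_points(9, radius = 20)
  tab <- as_pigment_table(data.frame(
    pigment_id = paste0("s", 1:9), ring = "B850", site_energy_eV = eps,
    pos_x = pos[, 1], pos_y = pos[, 2], pos_z = pos[, 3],
    mu_x = 1, mu_y = 0, mu_z = 0, stringsAsFactors = FALSE))
  nn <- function(a, b) {
    # nearest neighbours on the ring couple with V, others 0
    ia <- as.integer(sub("s", "", a$pigment_id))
    ib <- as.integer(sub("s", "", b$pigment_id))
    d <- min(abs(ia - ib), 9 - abs(ia - ib))
    if (d == 1) V else 0
  }
  res <- diagonalize_hamiltonian(build_hamiltonian(tab, coupling_fn = nn))
  analytic <- sort(eps + 2 * V * cos(2 * pi * (0:8) / 9))
  expect_equal(res$energies, analytic, tolerance = 1e-9)
  # degeneracy pattern: 4 pairs + 1 singlet
  rle_deg <- table(round(res$energies, 9))
  expect_equal(sort(as.integer(rle_deg)), c(1L, 2L, 2L, 2L, 2L))

  # all-pairs PDA on a C9 ring is circulant: compare with the closed form
  tabt <- tab
  th <- atan2(pos[, 2], pos[, 1])
  tabt$mu_x <- -sin(th) * 6.3
  tabt$mu_y <- cos(th) * 6.3
  resp <- diagonalize_hamiltonian(build_hamiltonian(tabt))
  c_d <- vapply(1:4, function(d) {
    pda_coupling(tabt[1, ], tabt[1 + d, ])
  }, numeric(1))
  analytic2 <- sort(vapply(0:8, function(k) {
    eps + sum(2 * c_d[1:4] * cos(2 * pi * k * (1:4) / 9))
  }, numeric(1)))
  expect_equal(resp$energies, analytic2, tolerance = 1e-9)
})

test_that("spectra are Gaussian-correct, linear, and properly normalized", {
  one <- list(energies = 1.55, dipole_strengths = 6.3,
              coefficients = matrix(1), site_ids = "x")
  class(one) <- "exciton_result"
  grid <- seq(1.2, 1.9, by = 0.001)
  sp <- exciton_spectrum(one, sigma = 0.022, grid = grid)
  expect_true(all(sp$absorbance >= 0))
  peak <- grid[which.max(sp$absorbance)]
  expect_lt(abs(peak - 1.55), 0.001 + 1e-12)

  # doubling all M^2 doubles A pointwise
  two <- one
  two$dipole_strengths <- sqrt(2) * one$dipole_strengths
  sp2 <- exciton_spectrum(two, sigma = 0.022, grid = grid)
  expect_equal(sp2$absorbance, 2 * sp$absorbance, tolerance = 1e-12)

  # integral of A/v dv recovers sum M^2 (Gaussian normalization)
  integ <- sum(sp$absorbance / sp$energy_eV) * 0.001
  expect_equal(integ, sum(one$dipole_strengths^2), tolerance = 0.01)

  expect_warning(exciton_spectrum(one, sigma = 0.022,
                                  grid = seq(1.5, 1.6, 0.001)), "grid")
})

test_that("ensemble averaging is a pointwise mean on a common grid", {
  g <- seq(1.3, 1.8, 0.001)
  mk <- function(center) {
    r <- list(energies = center, dipole_strengths = 1,
              coefficients = matrix(1), site_ids = "x")
    class(r) <- "exciton_result"
    suppressWarnings(exciton_spectrum(r, sigma = 0.02, grid = g))
  }
  s1 <- mk(1.44); s2 <- mk(1.62); s3 <- mk(1.55)
  same <- ensemble_spectrum(list(s1, s1, s1))
  expect_equal(same$absorbance, s1$absorbance)
  avg <- ensemble_spectrum(list(s1, s2, s3))
  expect_equal(avg$absorbance,
               (s1$absorbance + s2$absorbance + s3$absorbance) / 3,
               tolerance = 1e-12)
  # two well-separated peaks average to half height
  half <- ensemble_spectrum(list(s1, s2))
  i1 <- which.max(s1$absorbance)
  expect_equal(half$absorbance[i1], s1$absorbance[i1] / 2, tolerance = 1e-3)
  sbad <- mk(1.5)
  sbad$energy_eV <- sbad$energy_eV + 1e-3
  expect_error(ensemble_spectrum(list(s1, sbad)), "common grid")
})

test_that("bimodal fitting recovers known Gaussian centers", {
  g <- seq(1.3, 1.7, 0.0005)
  truth <- function(E) {
    1.0 * exp(-(E - 1.44)^2 / (2 * 0.022^2)) +
      0.6 * exp(-(E - 1.55)^2 / (2 * 0.022^2))
  }
  sp <- structure(list(energy_eV = g, wavelength_nm = 1239.841984 / g,
                       absorbance = truth(g), sigma = 0.022),
                  class = "spectrum")
  fit <- bimodal_fit(sp)
  expect_false(fit$degenerate)
  expect_equal(fit$center_eV, c(1.44, 1.55), tolerance = 1e-4)
  expect_equal(fit$peak_nm, 1239.841984 / c(1.44, 1.55), tolerance = 1e-4)

  # 1% noise, seeded: centers within 1e-3 eV
  set.seed(4)
  spn <- sp
  spn$absorbance <- pmax(0, truth(g) + rnorm(length(g), sd = 0.01))
  fitn <- bimodal_fit(spn)
  expect_lt(max(abs(fitn$center_eV - c(1.44, 1.55))), 1e-3)

  # single-peak input flagged degenerate
  sp1 <- sp
  sp1$absorbance <- exp(-(g - 1.5)^2 / (2 * 0.022^2))
  fit1 <- bimodal_fit(sp1)
  expect_true(fit1$degenerate)
})

test_that("ring shifts are additive, targeted, and pure", {
  fr <- generate_assembly(zero_noise_cfg())
  tab <- generate_pigment_table(fr, exciton_config(b800_shift = 0))
  s0 <- apply_ring_shift(tab, "B800", 0)
  expect_equal(s0$site_energy_eV, tab$site_energy_eV)
  s1 <- apply_ring_shift(tab, "B800", -0.07)
  chg <- which(s1$site_energy_eV != tab$site_energy_eV)
  expect_length(chg, 9L)
  expect_true(all(tab$ring[chg] == "B800"))
  expect_equal(s1$site_energy_eV[chg], tab$site_energy_eV[chg] - 0.07)
  s2 <- apply_ring_shift(apply_ring_shift(tab, "B850", -0.01), "B850",
                         -0.01)
  s2b <- apply_ring_shift(tab, "B850", -0.02)
  expect_equal(s2$site_energy_eV, s2b$site_energy_eV)
  expect_error(apply_ring_shift(tab, "B900", 1), "unknown ring")
})

test_that("coupling reports cover all cross-ring pairs with per-donor maxima", {
  fr <- generate_assembly(zero_noise_cfg())
  tab <- generate_pigment_table(fr, exciton_config(), include_rg1 = TRUE)
  rp <- coupling_report(tab, "RG1", "B850")
  expect_equal(nrow(rp$pairs), 9L * 18L)
  expect_length(rp$max_by_a, 9L)
  expect_true(all(rp$pairs$R_A > 0))
  expect_true(all(abs(rp$pairs$kappa) <= 2 + 1e-12))
  one <- rp$pairs[17, ]
  ids <- strsplit(one$pair, "-(?=B850)", perl = TRUE)[[1]]
  a <- tab[tab$pigment_id == ids[1], ]
  b <- tab[tab$pigment_id == ids[2], ]
  expect_equal(one$V_meV, 1000 * pda_coupling(a, b), tolerance = 1e-12)
})
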