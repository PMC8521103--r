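# Per-condition comparison pipeline: geometry descriptors, contact
# occupancies and exciton spectra over labeled ensembles, aggregated as
# mean +/- sd distributions with a cross-condition trend table.
#
# Selections are label-based and atom order is constant across frames of
# one ensemble, so all atom indices are resolved once on the first frame
# and reused; per-frame work is pure arithmetic on coordinate matrices.

#' Pipeline run configuration
#'
#' @param ensembles named list, in comparison order. Each element is
#'   either `list(frames = <list of structure_frame>)` (in-memory) or
#'   `list(topology = <pdb>, coords = <pdb/dcd>, format = "pdb")`.
#' @param stride keep every k-th frame.
#' @param skip_fraction fraction of initial frames discarded before
#'   analysis (the equilibration window), in `[0, 1)`.
#' @param descriptor_cfg see [descriptor_config()].
#' @param hbond_pairs optional list of [contact_pair()]s.
#' @param exciton_cfg an [exciton_config()], or `NULL` to skip spectra.
#' @param n_spectra number of frames evenly extracted for spectra.
#' @param grid spectral energy grid (eV).
#' @param trend_rho minimum |Spearman rho| (pooled values vs condition
#'   rank) for a trend call.
#' @param outdir optional output directory for CSV/JSON artefacts.
#' @param seed seed recorded in the report (the pipeline itself is
#'   deterministic given its inputs).
#' @return object of class `run_config`.
#' @export
run_config <- function(ensembles, stride = 1L, skip_fraction = 0,
                       descriptor_cfg = descriptor_config(),
                       hbond_pairs = NULL,
                       exciton_cfg = exciton_config(),
                       n_spectra = 25L,
                       grid = seq(1.2, 1.9, by = 0.001),
                       trend_rho = 0.5, outdir = NULL, seed = 1L) {
  stopifnot(length(ensembles) >= 1L, !is.null(names(ensembles)),
            skip_fraction >= 0, skip_fraction < 1, stride >= 1L)
  structure(list(ensembles = ensembles, stride = as.integer(stride),
                 skip_fraction = skip_fraction,
                 descriptor_cfg = descriptor_cfg,
                 hbond_pairs = hbond_pairs, exciton_cfg = exciton_cfg,
                 n_spectra = as.integer(n_spectra), grid = grid,
                 trend_rho = trend_rho, outdir = outdir,
                 seed = as.integer(seed)),
            class = "run_config")
}

.dihedrals_vec <- function(xyz, quads) {
  # torsion angle (deg) for each row of the m x 4 index matrix
  p1 <- xyz[quads[, 1], , drop = FALSE]
  p2 <- xyz[quads[, 2], , drop = FALSE]
  p3 <- xyz[quads[, 3], , drop = FALSE]
  p4 <- xyz[quads[, 4], , drop = FALSE]
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  m1 <- cr(n1, b2 / sqrt(rowSums(b2^2)))
  -atan2(rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi
}

.bb_index <- function(frame, chain, resid, atom) {
  i <- which(frame$chain == chain & frame$resid == resid &
               frame$atom == atom)
  if (length(i) != 1L) return(NA_integer_)
  i
}

.descriptor_cache <- function(frame, cfg) {
  subunits <- sort(unique(frame$subunit[!is.na(frame$subunit)]))
  heavy <- frame$elem != "H"
  rng_idx <- function(role, s, lo, hi) {
    ch <- role_chain(role, s)
    which(frame$chain == ch & frame$resid >= lo & frame$resid <= hi & heavy)
  }
  atom_idx <- function(s, resname, atoms) {
    ch <- role_chain("pigment", s)
    which(frame$chain == ch & frame$resname == resname &
            frame$atom %in% atoms)
  }
  cache <- list(subunits = subunits)
  cache$l_angle <- lapply(subunits, function(s) list(
    a = rng_idx("alpha", s, cfg$l_angle$seg_a[1], cfg$l_angle$seg_a[2]),
    b = rng_idx("alpha", s, cfg$l_angle$seg_b[1], cfg$l_angle$seg_b[2]),
    ha = rng_idx("alpha", s, cfg$l_angle$helix_a[1], cfg$l_angle$helix_a[2]),
    hb = rng_idx("alpha", s, cfg$l_angle$helix_b[1], cfg$l_angle$helix_b[2])
  ))
  cache$radii <- list(
    r_up = lapply(subunits, function(s)
      rng_idx("alpha", s, cfg$r_up$residues[1], cfg$r_up$residues[2])),
    r_down = lapply(subunits, function(s)
      rng_idx("alpha", s, cfg$r_down$residues[1], cfg$r_down$residues[2])),
    R_up = lapply(subunits, function(s)
      rng_idx("beta", s, cfg$R_up$residues[1], cfg$R_up$residues[2])),
    R_down = lapply(subunits, function(s)
      rng_idx("beta", s, cfg$R_down$residues[1], cfg$R_down$residues[2])),
    t = lapply(subunits, function(s) atom_idx(s, "RG1", cfg$t_atoms))
  )
  b85 <- which(frame$resname == "B85" & heavy)
  cache$T_groups <- split(b85, paste(frame$chain[b85], frame$resid[b85]))
  cache$omega <- lapply(subunits, function(s) lapply(cfg$omega_groups,
    function(g) atom_idx(s, "RG1", g)))
  cache$contact <- list(
    tails = lapply(subunits, function(s) atom_idx(s, "RG1", cfg$t_atoms)),
    b850 = b85)
  cache$heli <- lapply(subunits, function(s) {
    ch <- role_chain("alpha", s)
    quads <- list(phi = NULL, psi = NULL, resid = integer(0))
    for (r in 1:9) {
      Cm <- .bb_index(frame, ch, r - 1L, "C")
      N <- .bb_index(frame, ch, r, "N")
      CA <- .bb_index(frame, ch, r, "CA")
      CC <- .bb_index(frame, ch, r, "C")
      Np <- .bb_index(frame, ch, r + 1L, "N")
      if (anyNA(c(Cm, N, CA, CC, Np))) next
      quads$phi <- rbind(quads$phi, c(Cm, N, CA, CC))
      quads$psi <- rbind(quads$psi, c(N, CA, CC, Np))
      quads$resid <- c(quads$resid, r)
    }
    quads
  })
  cache
}

.frame_descriptors <- function(xyz, cache, plane_normal = c(0, 0, 1)) {
  cen <- function(i) colMeans(xyz[i, , drop = FALSE])
  ns <- length(cache$subunits)
  la <- nt <- om <- ct <- hc <- numeric(ns)
  for (k in seq_len(ns)) {
    ix <- cache$l_angle[[k]]
    v1 <- cen(ix$b) - cen(ix$a)
    v2 <- cen(ix$hb) - cen(ix$ha)
    la[k] <- .angle_deg(v1, v2)
    nt[k] <- sqrt(sum(v1^2))
    g <- lapply(cache$omega[[k]], cen)
    om[k] <- .angle_deg(g[[1]] - g[[2]], g[[3]] - g[[2]])
    A <- xyz[cache$contact$tails[[k]], , drop = FALSE]
    B <- xyz[cache$contact$b850, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    ct[k] <- sqrt(max(0, min(d2)))
    q <- cache$heli[[k]]
    if (length(q$resid) > 0L) {
      phi <- .dihedrals_vec(xyz, q$phi)
      psi <- .dihedrals_vec(xyz, q$psi)
      hc[k] <- sum(phi >= -100 & phi <= -30 & psi >= -67 & psi <= -7)
    }
  }
  radii <- c(
    vapply(names(cache$radii), function(nm) {
      pts <- t(vapply(cache$radii[[nm]], cen, numeric(3)))
      fit_ring(pts, plane_normal)$r_bar
    }, numeric(1)),
    T = fit_ring(t(vapply(cache$T_groups, cen, numeric(3))),
                 plane_normal)$r_bar
  )
  list(radii = radii, l_angle_deg = la, nterm_length_A = nt,
       omega_deg = om, rg1_b850_contact_A = ct, helical_count = hc)
}

#' Summary statistics of a descriptor sample
#'
#' Sample mean, sd and a Freedman-Diaconis histogram over all pooled
#' (frame, subunit) values. The distribution center is reported as the
#' sample mean.
#'
#' @param values numeric vector, length >= 2.
#' @return list with `mean`, `sd`, `n`, `breaks`, `counts`.
#' @export
descriptor_distribution <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need at least 2 values")
  h <- if (stats::IQR(values) > 0) {
    graphics::hist(values, breaks = "FD", plot = FALSE)
  } else {
    graphics::hist(values, plot = FALSE)
  }
  list(mean = mean(values), sd = stats::sd(values), n = length(values),
       breaks = h$breaks, counts = h$counts)
}

.load_ensemble <- function(ens, stride, skip_fraction) {
  frames <- if (!is.null(ens$frames)) {
    ens$frames
  } else {
    read_trajectory(ens$topology, ens$coords %||% ens$topology, stride = 1L,
                    format = ens$format %||% "pdb")
  }
  n <- length(frames)
  first <- min(n, floor(skip_fraction * n) + 1L)
  frames[seq(first, n, by = stride)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.spearman_trend <- function(values, label_rank, means, rho_min) {
  if (length(unique(label_rank)) < 2L) return("none")
  up <- all(diff(means) > 0)
  down <- all(diff(means) < 0)
  if (!up && !down) return("none")
  rho <- suppressWarnings(
    stats::cor(label_rank, values, method = "spearman"))
  if (is.na(rho) || abs(rho) < rho_min) return("none")
  if (up && rho > 0) "increasing" else if (down && rho < 0) "decreasing"
  else "none"
}

#' Run the per-condition comparison pipeline
#'
#' For each labeled ensemble: per-frame ring radii, per-(frame, subunit)
#' descriptors, optional contact occupancies, spectra from evenly
#' extracted frames (ensemble mean + two-Gaussian peak fit) and coupling
#' statistics. Across ordered labels a trend table marks each descriptor
#' increasing/decreasing when the per-label means are monotone and the
#' pooled Spearman correlation against condition rank exceeds the
#' threshold. Deterministic given the config.
#'
#' @param cfg a [run_config()].
#' @return object of class `comparison_report`.
#' @export
run_comparison <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  labels <- names(cfg$ensembles)
  per_label <- list()
  log_lines <- character(0)
  for (lab in labels) {
    frames <- .load_ensemble(cfg$ensembles[[lab]], cfg$stride,
                             cfg$skip_fraction)
    if (length(frames) < 1L) stop("pipeline error [", lab, "]: no frames")
    cache <- .descriptor_cache(frames[[1]], cfg$descriptor_cfg)
    log_lines <- c(log_lines, sprintf(
      "[%s] %d frames, %d subunits, %d cached selections", lab,
      length(frames), length(cache$subunits),
      length(unlist(cache$radii)) + length(cache$T_groups)))
    res <- tryCatch({
      per_frame <- lapply(frames, function(fr) {
        .frame_descriptors(frame_coords(fr), cache)
      })
      radii_mat <- t(vapply(per_frame, function(d) d$radii, numeric(6)))
      colnames(radii_mat) <- c("r_up", "r_down", "R_up", "R_down", "t", "T")
      desc <- list()
      for (nm in c("l_angle_deg", "nterm_length_A", "omega_deg",
                   "rg1_b850_contact_A", "helical_count")) {
        desc[[nm]] <- as.vector(t(vapply(per_frame, function(d) d[[nm]],
                                         numeric(length(cache$subunits)))))
      }
      for (nm in colnames(radii_mat)) desc[[nm]] <- radii_mat[, nm]
      dist <- lapply(desc, descriptor_distribution)
      occ <- if (!is.null(cfg$hbond_pairs)) {
        hbond_occupancy(frames, cfg$hbond_pairs)
      } else NULL
      spec <- couplings <- fit <- NULL
      if (!is.null(cfg$exciton_cfg)) {
        n <- length(frames)
        pick <- unique(round(seq(1, n, length.out = min(cfg$n_spectra, n))))
        tabs <- lapply(frames[pick], generate_pigment_table,
                       xcfg = cfg$exciton_cfg, include_rg1 = TRUE)
        specs <- lapply(tabs, function(tb) {
          exciton_spectrum(
            diagonalize_hamiltonian(build_hamiltonian(tb)),
            sigma = cfg$exciton_cfg$sigma_broadening, grid = cfg$grid)
        })
        spec <- ensemble_spectrum(specs)
        fit <- tryCatch(bimodal_fit(spec), error = function(e) NULL)
        vnn <- vapply(tabs, function(tb) {
          b <- tb[tb$ring == "B850", ]
          th <- atan2(b$pos_y, b$pos_x)
          b <- b[order(th), ]
          m <- nrow(b)
          mean(vapply(seq_len(m), function(i) {
            abs(1000 * pda_coupling(b[i, ], b[if (i == m) 1L else i + 1L, ]))
          }, numeric(1)))
        }, numeric(1))
        vrg <- vapply(tabs, function(tb) {
          mean(coupling_report(tb, "RG1", "B850")$max_by_a)
        }, numeric(1))
        couplings <- list(
          b850_nn_meV = c(mean = mean(vnn), sd = stats::sd(vnn)),
          rg1_b850_max_meV = c(mean = mean(vrg), sd = stats::sd(vrg)))
      }
      list(n_frames = length(frames), n_subunits = length(cache$subunits),
           values = desc, distributions = dist, occupancy = occ,
           spectrum = spec, bimodal = fit, couplings = couplings)
    }, error = function(e) {
      stop("pipeline error [", lab, ", analysis]: ", conditionMessage(e))
    })
    per_label[[lab]] <- res
  }
  trend <- NULL
  if (length(labels) >= 2L) {
    desc_names <- names(per_label[[1]]$values)
    trend <- data.frame(descriptor = desc_names,
                        direction = vapply(desc_names, function(nm) {
                          vals <- unlist(lapply(per_label,
                                                function(x) x$values[[nm]]))
                          rk <- unlist(lapply(seq_along(labels), function(i) {
                            rep(i, length(per_label[[i]]$values[[nm]]))
                          }))
                          means <- vapply(per_label, function(x) {
                            mean(x$values[[nm]])
                          }, numeric(1))
                          .spearman_trend(vals, rk, means, cfg$trend_rho)
                        }, character(1)),
                        stringsAsFactors = FALSE)
    rownames(trend) <- NULL
  }
  rep_ <- structure(list(labels = labels, per_label = per_label,
                         trend = trend, seed = cfg$seed,
                         log = log_lines),
                    class = "comparison_report")
  if (!is.null(cfg$outdir)) .write_report(rep_, cfg)
  rep_
}

.write_report <- function(rep_, cfg) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  for (lab in rep_$labels) {
    pl <- rep_$per_label[[lab]]
    d <- do.call(rbind, lapply(names(pl$values), function(nm) {
      data.frame(descriptor = nm, value = pl$values[[nm]],
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(d, file.path(cfg$outdir,
                                  paste0("descriptors_", lab, ".csv")),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(pl$spectrum)) {
      utils::write.csv(
        data.frame(energy_eV = pl$spectrum$energy_eV,
                   wavelength_nm = pl$spectrum$wavelength_nm,
                   absorbance = pl$spectrum$absorbance),
        file.path(cfg$outdir, paste0("spectrum_", lab, ".csv")),
        row.names = FALSE, quote = FALSE)
    }
    if (!is.null(pl$occupancy)) {
      utils::write.csv(pl$occupancy,
                       file.path(cfg$outdir,
                                 paste0("occupancy_", lab, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
  }
  summ <- list(
    labels = rep_$labels, seed = rep_$seed,
    distributions = lapply(rep_$per_label, function(pl) {
      lapply(pl$distributions, function(d) d[c("mean", "sd", "n")])
    }),
    couplings = lapply(rep_$per_label, function(pl) pl$couplings),
    peaks_nm = lapply(rep_$per_label, function(pl) {
      if (is.null(pl$bimodal)) NULL else pl$bimodal$peak_nm
    }),
    trend = rep_$trend
  )
  jsonlite::write_json(summ, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(rep_$log, file.path(cfg$outdir, "run.log"))
  invisible(NULL)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report over", length(x$labels), "condition(s):",
      paste(x$labels, collapse = ", "), "\n")
  for (lab in x$labels) {
    pl <- x$per_label[[lab]]
    cat(sprintf("  [%s] %d frames x %d subunits\n", lab, pl$n_frames,
                pl$n_subunits))
    for (nm in names(pl$distributions)) {
      d <- pl$distributions[[nm]]
      cat(sprintf("    %-20s %8.3f +/- %.3f (n=%d)\n", nm, d$mean, d$sd,
                  d$n))
    }
    if (!is.null(pl$bimodal)) {
      cat(sprintf("    peaks: %.1f / %.1f nm\n", pl$bimodal$peak_nm[1],
                  pl$bimodal$peak_nm[2]))
    }
  }
  if (!is.null(x$trend)) {
    cat("  trend:\n")
    for (i in seq_len(nrow(x$trend))) {
      cat(sprintf("    %-20s %s\n", x$trend$descriptor[i],
                  x$trend$direction[i]))
    }
  }
  invisible(x)
}
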