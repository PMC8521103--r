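# Distance-based hydrogen-bond (heavy-atom contact) occupancies over a
# trajectory. The criterion is purely geometric: donor-acceptor heavy-atom
# distance strictly below a cutoff (default 3.5 A); no angle term, which
# matches occupancy tables defined on non-hydrogen distances alone.

#' Define a heavy-atom contact pair
#'
#' Donor and acceptor each resolve to exactly one heavy atom per subunit
#' (e.g. alpha-Gly4 O against beta-Ser61 Ogamma).
#'
#' @param name pair label.
#' @param donor_role,acceptor_role `"alpha"`, `"beta"` or `"pigment"`.
#' @param donor_resid,acceptor_resid residue index (1-based per chain).
#' @param donor_atom,acceptor_atom atom name.
#' @param cutoff contact cutoff in Angstrom (strict `<`).
#' @return object of class `contact_pair`.
#' @export
contact_pair <- function(name, donor_role, donor_resid, donor_atom,
                         acceptor_role, acceptor_resid, acceptor_atom,
                         cutoff = 3.5) {
  stopifnot(cutoff > 0)
  structure(list(name = name,
                 donor = list(role = donor_role, resid = donor_resid,
                              atom = donor_atom),
                 acceptor = list(role = acceptor_role,
                                 resid = acceptor_resid,
                                 atom = acceptor_atom),
                 cutoff = cutoff),
            class = "contact_pair")
}

.resolve_pair_atom <- function(frame, spec, subunit, pair_name) {
  ch <- role_chain(spec$role, subunit)
  i <- which(frame$chain == ch & frame$resid == spec$resid &
               frame$atom == spec$atom & frame$elem != "H")
  if (length(i) != 1L) {
    stop("labeled-input error: pair '", pair_name, "' resolves to ",
         length(i), " atoms (", spec$role, " ", spec$resid, " ",
         spec$atom, ", subunit ", subunit, ")")
  }
  i
}

#' Contact occupancy over a trajectory
#'
#' Occupancy = 100 x (frames with donor-acceptor distance strictly below
#' the cutoff) / (total frames), per subunit, averaged over subunits
#' unless `per_subunit`. Frame order does not matter.
#'
#' @param traj list of [structure_frame()]s sharing one topology.
#' @param pairs list of [contact_pair()]s.
#' @param cutoff optional override of every pair's cutoff (A).
#' @param per_subunit return one row per (pair, subunit) instead of
#'   subunit-averaged values.
#' @param subunits subunit indices to analyse.
#' @return data frame with `pair`, `subunit` (or `"avg"`),
#'   `occupancy_pct`.
#' @export
hbond_occupancy <- function(traj, pairs, cutoff = NULL,
                            per_subunit = FALSE, subunits = 0:8) {
  stopifnot(length(traj) >= 1L)
  if (inherits(pairs, "contact_pair")) pairs <- list(pairs)
  f1 <- traj[[1]]
  subunits <- subunits[vapply(subunits, function(s) {
    role_chain("alpha", s) %in% f1$chain |
      role_chain("beta", s) %in% f1$chain |
      role_chain("pigment", s) %in% f1$chain
  }, logical(1))]
  rows <- list()
  for (p in pairs) {
    cut <- if (is.null(cutoff)) p$cutoff else cutoff
    occ <- vapply(subunits, function(s) {
      id <- .resolve_pair_atom(f1, p$donor, s, p$name)
      ia <- .resolve_pair_atom(f1, p$acceptor, s, p$name)
      d <- vapply(traj, function(fr) {
        sqrt((fr$x[id] - fr$x[ia])^2 + (fr$y[id] - fr$y[ia])^2 +
               (fr$z[id] - fr$z[ia])^2)
      }, numeric(1))
      100 * mean(d < cut)
    }, numeric(1))
    if (per_subunit) {
      rows[[length(rows) + 1L]] <- data.frame(
        pair = p$name, subunit = as.character(subunits),
        occupancy_pct = occ, stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        pair = p$name, subunit = "avg", occupancy_pct = mean(occ),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' The six canonical alpha/beta interface contact pairs
#'
#' The inter-helix hydrogen bonds commonly tabulated for LH2
#' (Cxm1 O..His65 N-epsilon, Trp7 N-epsilon..His65 N-delta, Gly4 O..Ser61
#' O-gamma, Trp7 N..Ser61 O-gamma, Trp7 O..Leu56 N, Asn11 O-delta..Ala54
#' N), mapped to the generic backbone-proxy atom names of the synthetic
#' assemblies: side-chain nitrogens map to N and side-chain oxygens to O.
#'
#' @param cutoff cutoff in Angstrom.
#' @return list of [contact_pair()]s.
#' @export
table_pairs <- function(cutoff = 3.5) {
  list(
    contact_pair("Cxm1.O-His65.Ne", "alpha", 1L, "O", "beta", 65L, "N",
                 cutoff),
    contact_pair("Trp7.Ne-His65.Nd", "alpha", 7L, "N", "beta", 65L, "N",
                 cutoff),
    contact_pair("Gly4.O-Ser61.Og", "alpha", 4L, "O", "beta", 61L, "O",
                 cutoff),
    contact_pair("Trp7.N-Ser61.Og", "alpha", 7L, "N", "beta", 61L, "O",
                 cutoff),
    contact_pair("Trp7.O-Leu56.N", "alpha", 7L, "O", "beta", 56L, "N",
                 cutoff),
    contact_pair("Asn11.Od-Ala54.N", "alpha", 11L, "O", "beta", 54L, "N",
                 cutoff)
  )
}
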