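# Chain-letter convention for C9 assemblies: alpha polypeptides A-I,
# beta polypeptides J-R, pigment chains (B800 + 2x B850 + RG1) a-i,
# one of each per subunit 0..8.
.ALPHA_CHAINS <- LETTERS[1:9]
.BETA_CHAINS <- LETTERS[10:18]
.PIGMENT_CHAINS <- letters[1:9]

#' Map a chain identifier to its subunit index
#'
#' Chains follow the package convention (alpha A-I, beta J-R, pigments a-i).
#' Unknown chains map to `NA`.
#'
#' @param chain character vector of one-letter chain identifiers.
#' @return integer vector of subunit indices in 0..8 (or `NA`).
#' @export
chain_subunit <- function(chain) {
  idx <- rep(NA_integer_, length(chain))
  for (set in list(.ALPHA_CHAINS, .BETA_CHAINS, .PIGMENT_CHAINS)) {
    m <- match(chain, set)
    idx[!is.na(m)] <- m[!is.na(m)] - 1L
  }
  idx
}

#' Chain letter for a molecular role within a subunit
#'
#' @param role one of `"alpha"`, `"beta"`, `"pigment"`.
#' @param subunit integer subunit index 0..8.
#' @return one-letter chain id.
#' @export
role_chain <- function(role, subunit) {
  role <- match.arg(role, c("alpha", "beta", "pigment"))
  stopifnot(all(subunit >= 0L), all(subunit <= 8L))
  switch(role,
    alpha = .ALPHA_CHAINS[subunit + 1L],
    beta = .BETA_CHAINS[subunit + 1L],
    pigment = .PIGMENT_CHAINS[subunit + 1L]
  )
}

#' Construct a structure frame
#'
#' A structure frame is one timestep of a (possibly synthetic) molecular
#' assembly: a data frame with one row per atom carrying `atom` (PDB atom
#' name), `elem` (element symbol), `resname`, `resid` (1-based per chain),
#' `chain`, `subunit` (0-based, `NA` when unknown) and Cartesian `x`, `y`,
#' `z` in Angstrom.
#'
#' @param atoms data frame with the columns above.
#' @param time optional time stamp in ps.
#' @return an object of class `structure_frame` (a data frame).
#' @export
structure_frame <- function(atoms, time = NA_real_) {
  need <- c("atom", "elem", "resname", "resid", "chain", "subunit",
            "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0L) {
    stop("labeled-input error: atom table lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  if (nrow(atoms) < 1L) stop("labeled-input error: frame has no atoms")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("labeled-input error: non-finite coordinates")
  }
  if (any(atoms$resid < 1L, na.rm = TRUE)) {
    stop("labeled-input error: residue indices must be >= 1")
  }
  out <- as.data.frame(atoms[, need], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "time") <- time
  class(out) <- c("structure_frame", "data.frame")
  out
}

#' @export
print.structure_frame <- function(x, ...) {
  cat(sprintf("structure_frame: %d atoms, %d chain(s)%s\n",
              nrow(x), length(unique(x$chain)),
              if (is.finite(attr(x, "time"))) {
                sprintf(", t = %g ps", attr(x, "time"))
              } else ""))
  invisible(x)
}

#' Coordinates of a frame as a matrix
#'
#' @param frame a `structure_frame`.
#' @param idx optional atom indices.
#' @return numeric matrix with columns x, y, z (Angstrom).
#' @export
frame_coords <- function(frame, idx = NULL) {
  m <- cbind(x = frame$x, y = frame$y, z = frame$z)
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  m
}

#' Replace the coordinates of a frame
#'
#' @param frame a `structure_frame`.
#' @param xyz numeric n x 3 matrix.
#' @return the frame with new coordinates.
#' @export
set_frame_coords <- function(frame, xyz) {
  stopifnot(nrow(xyz) == nrow(frame), ncol(xyz) == 3L)
  frame$x <- xyz[, 1]
  frame$y <- xyz[, 2]
  frame$z <- xyz[, 3]
  frame
}

.element_from_name <- function(atom_name) {
  # PDB columns 13-14 hold the element-justified name; for the plain names
  # used here the element is the leading alphabetic character(s) before digits
  a <- toupper(sub("^([0-9]*)", "", atom_name))
  two <- substr(a, 1, 2)
  ifelse(two %in% c("MG", "FE", "ZN", "CL", "BR", "NA"), two, substr(a, 1, 1))
}

.remap_resid <- function(chain, resno) {
  # dense 1-based residue rank per chain, preserving file order
  out <- integer(length(resno))
  for (ch in unique(chain)) {
    i <- which(chain == ch)
    r <- resno[i]
    out[i] <- cumsum(c(TRUE, diff(r) != 0))
  }
  out
}

.frame_from_bio3d <- function(pdb, xyz_row, time = NA_real_) {
  at <- pdb$atom
  if (any(is.na(at$chain)) || any(is.na(at$resno))) {
    stop("labeled-input error: PDB records lack chain or residue labels")
  }
  n <- nrow(at)
  xyz <- matrix(xyz_row, ncol = 3L, byrow = TRUE)
  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  if (any(bad)) elem[bad] <- .element_from_name(at$elety[bad])
  structure_frame(data.frame(
    atom = at$elety,
    elem = elem,
    resname = at$resid,
    resid = .remap_resid(at$chain, at$resno),
    chain = at$chain,
    subunit = chain_subunit(at$chain),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE
  ), time = time)
}

#' Read a (single-frame) structure from PDB
#'
#' Chain and residue labels are required; PDB residue numbers are remapped to
#' a dense 1-based index per chain, so selections count residues from the
#' N-terminus ("1st-3rd residues") regardless of author numbering. Hydrogens
#' are retained and can be recognised through their element symbol.
#'
#' @param path PDB file.
#' @param format currently only `"pdb"`.
#' @return a [structure_frame()] (the first MODEL of a multi-model file).
#' @export
read_structure <- function(path, format = c("pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("I/O error: unreadable PDB: ",
                                           conditionMessage(e)))
  .frame_from_bio3d(pdb, pdb$xyz[1, ])
}

.frames_to_bio3d_args <- function(frames) {
  f1 <- frames[[1]]
  xyz <- do.call(rbind, lapply(frames, function(f) as.numeric(t(frame_coords(f)))))
  list(frame = f1, xyz = xyz)
}

#' Write one frame or a trajectory of frames to (multi-model) PDB
#'
#' @param frames a `structure_frame` or list of frames sharing one topology.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(frames, path) {
  if (inherits(frames, "structure_frame")) frames <- list(frames)
  stopifnot(length(frames) >= 1L)
  f1 <- frames[[1]]
  a <- .frames_to_bio3d_args(frames)
  bio3d::write.pdb(
    file = path,
    xyz = a$xyz,
    type = rep("ATOM", nrow(f1)),
    resno = f1$resid,
    resid = f1$resname,
    eleno = seq_len(nrow(f1)),
    elety = f1$atom,
    chain = f1$chain,
    elesy = f1$elem
  )
  invisible(path)
}

#' Read a trajectory
#'
#' Multi-model PDB is the native format; a DCD adapter (via bio3d) is
#' provided for binary trajectories, keeping the core format-independent.
#' Frames are returned in model order; `stride = k` keeps every k-th frame
#' starting from the first.
#'
#' @param topology PDB file carrying the labels (any model).
#' @param coords coordinate source: multi-model PDB, or DCD when
#'   `format = "dcd"`. Defaults to `topology`.
#' @param stride positive integer.
#' @param format `"pdb"` or `"dcd"`.
#' @return list of [structure_frame()]s.
#' @export
read_trajectory <- function(topology, coords = topology, stride = 1L,
                            format = c("pdb", "dcd")) {
  format <- match.arg(format)
  stopifnot(stride >= 1L)
  top <- tryCatch(bio3d::read.pdb(topology, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("I/O error: unreadable topology: ",
                                           conditionMessage(e)))
  xyz <- if (format == "pdb") {
    p <- bio3d::read.pdb(coords, multi = TRUE, verbose = FALSE)
    if (ncol(p$xyz) != 3L * nrow(top$atom)) {
      stop("topology error: coordinate frames have ", ncol(p$xyz) / 3,
           " atoms but topology has ", nrow(top$atom))
    }
    p$xyz
  } else {
    m <- bio3d::read.dcd(coords, verbose = FALSE)
    if (ncol(m) != 3L * nrow(top$atom)) {
      stop("topology error: DCD atom count does not match topology")
    }
    m
  }
  keep <- seq(1L, nrow(xyz), by = stride)
  lapply(keep, function(i) {
    .frame_from_bio3d(top, xyz[i, ], time = as.numeric(i - 1L))
  })
}

#' Define an atom selection
#'
#' Selections are label-based (chains, an inclusive residue range, optional
#' atom names) and independent of coordinates. `chains` may use role
#' keywords (`"alpha"`, `"beta"`, `"pigment"`), resolved per subunit, or
#' explicit chain letters.
#'
#' @param name label used in error messages and logs.
#' @param chains character vector of chain ids or role keywords.
#' @param residues inclusive integer pair `c(lo, hi)`.
#' @param atoms optional atom-name set; `NULL` selects all heavy atoms.
#' @return an object of class `selection`.
#' @export
selection <- function(name, chains, residues, atoms = NULL) {
  stopifnot(length(residues) == 2L, residues[1] <= residues[2],
            residues[1] >= 1L)
  structure(list(name = name, chains = chains,
                 residues = as.integer(residues), atoms = atoms),
            class = "selection")
}

#' @export
print.selection <- function(x, ...) {
  cat(sprintf("selection '%s': chains {%s}, residues %d-%d%s\n", x$name,
              paste(x$chains, collapse = ","), x$residues[1], x$residues[2],
              if (is.null(x$atoms)) " (heavy atoms)" else
                paste0(", atoms {", paste(x$atoms, collapse = ","), "}")))
  invisible(x)
}

.expand_chains <- function(chains, subunit = NULL) {
  out <- character(0)
  for (ch in chains) {
    if (ch %in% c("alpha", "beta", "pigment")) {
      su <- if (is.null(subunit)) 0:8 else subunit
      out <- c(out, vapply(su, function(s) role_chain(ch, s), character(1)))
    } else {
      out <- c(out, ch)
    }
  }
  unique(out)
}

#' Resolve a selection to atom indices
#'
#' Labels only: the result does not depend on coordinates. When `atoms` is
#' `NULL`, hydrogens are excluded (heavy-atom default, matching
#' distance-between-non-hydrogen-atoms contact criteria).
#'
#' @param frame a [structure_frame()].
#' @param sel a [selection()].
#' @param subunit optional subunit restriction used to expand role keywords.
#' @return sorted integer atom indices (>= 1 entries, else an error).
#' @export
resolve_selection <- function(frame, sel, subunit = NULL) {
  chains <- .expand_chains(sel$chains, subunit)
  hit <- frame$chain %in% chains &
    frame$resid >= sel$residues[1] & frame$resid <= sel$residues[2]
  if (is.null(sel$atoms)) {
    hit <- hit & frame$elem != "H"
  } else {
    hit <- hit & frame$atom %in% sel$atoms
  }
  idx <- which(hit)
  if (length(idx) == 0L) {
    stop("empty-selection error: '", sel$name, "' matched no atoms")
  }
  sort(idx)
}

#' Read a pigment table
#'
#' Plain-text CSV with columns `pigment_id`, `ring` (B800|B850|RG1),
#' `site_energy_eV`, `pos_x`, `pos_y`, `pos_z` (Angstrom), `mu_x`, `mu_y`,
#' `mu_z` (Debye).
#'
#' @param path CSV file.
#' @return data frame of class `pigment_table`.
#' @export
read_pigment_table <- function(path) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_pigment_table(d)
}

#' Validate a pigment table
#'
#' @param d data frame with the columns of [read_pigment_table()].
#' @return `d` with class `pigment_table`.
#' @export
as_pigment_table <- function(d) {
  need <- c("pigment_id", "ring", "site_energy_eV",
            "pos_x", "pos_y", "pos_z", "mu_x", "mu_y", "mu_z")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) {
    stop("labeled-input error: pigment table lacks: ",
         paste(miss, collapse = ", "))
  }
  if (anyDuplicated(d$pigment_id)) {
    stop("labeled-input error: duplicate pigment_id")
  }
  if (!all(d$ring %in% c("B800", "B850", "RG1"))) {
    stop("labeled-input error: ring must be B800, B850 or RG1")
  }
  class(d) <- c("pigment_table", "data.frame")
  d
}

#' Write a pigment table
#'
#' @param d a `pigment_table`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_pigment_table <- function(d, path) {
  utils::write.csv(as.data.frame(d), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
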