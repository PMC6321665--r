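#' Read a protein structure from a PDB file
#'
#' Thin wrapper around \code{bio3d::read.pdb} that normalizes the structure
#' into the package's internal representation: only \code{ATOM} records of
#' the first model are kept, hetero/solvent records are excluded, and when
#' alternate locations are present only the first location per atom is
#' retained. Insertion codes are preserved as part of the residue identity.
#'
#' @param path PDB file.
#' @return An object of class \code{protein_structure}: a list with an
#'   \code{atoms} data frame (chain, resno, insert, resid, elety, elesy,
#'   x, y, z) and the source path.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB ", path, ": ",
                                           conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records in ", path)
  # first alternate location per (chain, resno, insert, atom name)
  alt <- at$alt
  alt[is.na(alt)] <- ""
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  keep <- !duplicated(key)
  at <- at[keep, , drop = FALSE]
  .protein_structure(data.frame(
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    resid = at$resid,
    elety = at$elety,
    elesy = ifelse(is.na(at$elesy) | at$elesy == "",
                   .element_from_name(at$elety), at$elesy),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE), source = path)
}

.protein_structure <- function(atoms, source = NA_character_) {
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)))
  structure(list(atoms = atoms, source = source),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("protein_structure: %d atoms, %d residues, %d chain(s)\n",
              nrow(x$atoms), nrow(rt), length(unique(rt$chain))))
  invisible(x)
}

.element_from_name <- function(name) {
  first <- sub("^[0-9]*", "", name)
  toupper(substr(first, 1, 1))
}

#' Residue list of a structure
#'
#' @param structure A \code{protein_structure}.
#' @return Data frame with one row per residue in file order: \code{chain},
#'   \code{resno}, \code{insert}, \code{resid} (3-letter code) and a unique
#'   \code{res_key}.
#' @export
residue_table <- function(structure) {
  at <- structure$atoms
  key <- paste(at$chain, at$resno, at$insert, sep = "|")
  first <- !duplicated(key)
  data.frame(chain = at$chain[first], resno = at$resno[first],
             insert = at$insert[first], resid = at$resid[first],
             res_key = key[first], stringsAsFactors = FALSE)
}

#' Write a structure to a PDB file
#'
#' Used mainly to materialize generated toy structures; delegates to
#' \code{bio3d::write.pdb} so that coordinates survive a write/read round
#' trip at PDB precision (1e-3 Angstrom).
#'
#' @param structure A \code{protein_structure}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_pdb <- function(structure, path) {
  at <- structure$atoms
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = at$resno,
                   resid = at$resid, chain = at$chain, elety = at$elety,
                   elesy = at$elesy)
  invisible(path)
}

# ---- secondary structure ---------------------------------------------------

#' Assign per-residue 3-state secondary structure
#'
#' Exactly one source must be provided besides the structure:
#' \itemize{
#'   \item \code{dssp}: a DSSP output file; the 8-state annotation is
#'     collapsed to 3 states (H, G, I to H; E, B to E; everything else C);
#'   \item \code{ss}: a plain H/E/C string (or character vector) passed
#'     through after validation;
#'   \item neither: a dihedral-based fallback assignment computed from the
#'     backbone geometry. Runs of at least 4 consecutive residues with
#'     phi in [-80, -40] and psi in [-65, -5] degrees become helix; runs of
#'     at least 2 residues with phi in [-150, -90] and psi in [90, 180]
#'     become strand; all remaining residues are coil.
#' }
#'
#' @param structure A \code{protein_structure}.
#' @param dssp Optional path to a DSSP output file.
#' @param ss Optional plain 3-state string/vector, length = residue count.
#' @return Character vector over \code{c("H", "E", "C")}, one element per
#'   residue of the structure.
#' @export
assign_secondary_structure <- function(structure, dssp = NULL, ss = NULL) {
  n_res <- nrow(residue_table(structure))
  if (!is.null(dssp) && !is.null(ss))
    stop("provide either a DSSP file or a plain secondary-structure string")
  if (!is.null(ss)) {
    states <- if (length(ss) == 1L) strsplit(ss, "")[[1]] else as.character(ss)
    if (length(states) != n_res)
      stop("secondary-structure string length ", length(states),
           " does not match residue count ", n_res)
    bad <- setdiff(unique(states), c("H", "E", "C"))
    if (length(bad)) stop("invalid secondary-structure state(s): ",
                          paste(bad, collapse = ", "))
    return(states)
  }
  if (!is.null(dssp)) {
    states <- .read_dssp_states(dssp)
    if (length(states) != n_res)
      stop("DSSP annotation length ", length(states),
           " does not match residue count ", n_res)
    return(states)
  }
  .dihedral_ss(structure)
}

# Parse the per-residue summary block of a DSSP output file and collapse the
# 8-state code (column 17) to 3 states.
.read_dssp_states <- function(path) {
  lines <- readLines(path, warn = FALSE)
  start <- grep("^  #  RESIDUE", lines)
  if (!length(start)) stop("not a DSSP output file: ", path)
  body <- lines[(start[1] + 1):length(lines)]
  body <- body[nchar(body) >= 17]
  # chain-break records carry '!' as residue code
  aa <- substr(body, 14, 14)
  body <- body[aa != "!"]
  raw <- substr(body, 17, 17)
  .collapse_dssp(raw)
}

.collapse_dssp <- function(raw) {
  out <- rep("C", length(raw))
  out[raw %in% c("H", "G", "I")] <- "H"
  out[raw %in% c("E", "B")] <- "E"
  out
}

# backbone dihedrals per residue (phi, psi in degrees; NA at chain ends)
.backbone_dihedrals <- function(structure) {
  rt <- residue_table(structure)
  at <- structure$atoms
  get_atom <- function(res_key, name) {
    i <- which(paste(at$chain, at$resno, at$insert, sep = "|") == res_key &
                 at$elety == name)
    if (!length(i)) return(NULL)
    c(at$x[i[1]], at$y[i[1]], at$z[i[1]])
  }
  n <- nrow(rt)
  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    Ni <- get_atom(rt$res_key[i], "N")
    CAi <- get_atom(rt$res_key[i], "CA")
    Ci <- get_atom(rt$res_key[i], "C")
    if (i > 1 && rt$chain[i - 1] == rt$chain[i]) {
      Cp <- get_atom(rt$res_key[i - 1], "C")
      if (!is.null(Cp) && !is.null(Ni) && !is.null(CAi) && !is.null(Ci))
        phi[i] <- .dihedral(Cp, Ni, CAi, Ci)
    }
    if (i < n && rt$chain[i + 1] == rt$chain[i]) {
      Nn <- get_atom(rt$res_key[i + 1], "N")
      if (!is.null(Ni) && !is.null(CAi) && !is.null(Ci) && !is.null(Nn))
        psi[i] <- .dihedral(Ni, CAi, Ci, Nn)
    }
  }
  data.frame(phi = phi, psi = psi)
}

.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.dihedral_ss <- function(structure) {
  di <- .backbone_dihedrals(structure)
  h_cand <- !is.na(di$phi) & !is.na(di$psi) &
    di$phi >= -80 & di$phi <= -40 & di$psi >= -65 & di$psi <= -5
  e_cand <- !is.na(di$phi) & !is.na(di$psi) &
    di$phi >= -150 & di$phi <= -90 & di$psi >= 90 & di$psi <= 180
  out <- rep("C", nrow(di))
  out[.runs_at_least(h_cand, 4L)] <- "H"
  out[.runs_at_least(e_cand, 2L) & out == "C"] <- "E"
  out
}

# logical vector marking positions inside candidate runs of length >= k
.runs_at_least <- function(cand, k) {
  r <- rle(cand)
  keep <- r$values & r$lengths >= k
  inverse.rle(list(values = keep, lengths = r$lengths))
}

# ---- secondary-structure derived features ---------------------------------

#' Secondary-structure element size and loop fraction
#'
#' \code{SecSize} is the length of the maximal contiguous run of the
#' residue's own state containing it (the residue itself included).
#' \code{LF} is the fraction of coil states within the 9-residue window
#' centered on the residue; at chain termini the window is truncated and the
#' count normalized by the positions actually present, so LF stays in
#' [0, 1]. Both are computed per chain.
#'
#' @param ss Character vector of 3-state assignments.
#' @param chain Optional chain identifier per residue; runs and windows never
#'   cross chain boundaries.
#' @param window Odd window size for the loop fraction (default 9).
#' @return Data frame with columns \code{SecSize} and \code{LF}.
#' @export
sec_size_and_lf <- function(ss, chain = NULL, window = 9L) {
  stopifnot(window %% 2L == 1L)
  if (is.null(chain)) chain <- rep("A", length(ss))
  half <- (window - 1L) %/% 2L
  out_size <- integer(length(ss)); out_lf <- numeric(length(ss))
  for (ch in unique(chain)) {
    idx <- which(chain == ch)
    s <- ss[idx]
    r <- rle(s)
    out_size[idx] <- rep(r$lengths, r$lengths)
    is_c <- s == "C"
    n <- length(s)
    for (i in seq_len(n)) {
      w <- max(1L, i - half):min(n, i + half)
      out_lf[idx[i]] <- mean(is_c[w])
    }
  }
  data.frame(SecSize = out_size, LF = out_lf)
}

# ---- Shrake-Rupley accessible surface area --------------------------------

# van der Waals radii (Angstrom) by element; unlisted elements fall back to
# carbon's radius with a warning.
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

# Maximum accessible surface area per amino acid (Angstrom^2), theoretical
# values for extended Gly-X-Gly tripeptides (Tien et al. 2013), used to turn
# absolute residue ASA into relative ASA.
.MAX_ASA <- c(ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0,
              CYS = 167.0, GLN = 225.0, GLU = 223.0, GLY = 104.0,
              HIS = 224.0, ILE = 197.0, LEU = 201.0, LYS = 236.0,
              MET = 224.0, PHE = 240.0, PRO = 159.0, SER = 155.0,
              THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)

# deterministic quasi-uniform points on the unit sphere (golden spiral)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Per-atom accessible surface area (Shrake-Rupley)
#'
#' Classic sphere-sampling algorithm: each atom is surrounded by a
#' deterministic golden-spiral point set on the sphere of radius
#' \code{vdW + probe}; points falling inside any neighbor's probe-expanded
#' sphere are occluded, and the unoccluded fraction times the sphere area
#' gives the atom's ASA. Hydrogens are ignored if present (heavy-atom
#' convention).
#'
#' @param structure A \code{protein_structure}.
#' @param n_points Number of sphere sample points per atom (default 960).
#' @param probe Solvent probe radius in Angstrom (default 1.4, water).
#' @return Numeric vector of per-atom ASA values (Angstrom^2), zero for
#'   hydrogen atoms.
#' @export
shrake_rupley <- function(structure, n_points = 960L, probe = 1.4) {
  at <- structure$atoms
  elem <- toupper(at$elesy)
  unknown <- setdiff(unique(elem), names(.VDW_RADII))
  if (length(unknown))
    warning("unknown element(s) ", paste(unknown, collapse = ", "),
            "; using carbon vdW radius")
  radii <- .VDW_RADII[elem]
  radii[is.na(radii)] <- .VDW_RADII[["C"]]
  heavy <- elem != "H"
  pts <- .sphere_points(n_points)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  n_at <- nrow(at)
  asa <- numeric(n_at)
  hv <- which(heavy)
  for (i in hv) {
    ri <- radii[i] + probe
    # neighbors whose expanded sphere can occlude points of atom i
    d2 <- (xyz[hv, 1] - xyz[i, 1])^2 + (xyz[hv, 2] - xyz[i, 2])^2 +
      (xyz[hv, 3] - xyz[i, 3])^2
    nb <- hv[d2 > 0 & d2 < (ri + radii[hv] + probe)^2]
    p <- sweep(pts * ri, 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      rj <- radii[j] + probe
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      free <- free & dj2 >= rj^2
      if (!any(free)) break
    }
    asa[i] <- 4 * pi * ri^2 * sum(free) / n_points
  }
  asa
}

#' Per-residue relative accessible surface area
#'
#' Sums \code{\link{shrake_rupley}} atom areas per residue and divides by the
#' amino-acid specific maximum ASA (theoretical extended tripeptide values).
#' Values slightly above 1 can occur for exposed termini; values above 1.2
#' are reported in a warning.
#'
#' @inheritParams shrake_rupley
#' @param max_asa Named vector of reference maxima (Angstrom^2) per 3-letter
#'   residue code; defaults to the bundled table.
#' @return Data frame with per-residue \code{asa} and \code{rasa}, aligned to
#'   \code{\link{residue_table}}.
#' @export
shrake_rupley_rasa <- function(structure, n_points = 960L, probe = 1.4,
                               max_asa = NULL) {
  if (is.null(max_asa)) max_asa <- .MAX_ASA
  asa_atom <- shrake_rupley(structure, n_points = n_points, probe = probe)
  at <- structure$atoms
  key <- paste(at$chain, at$resno, at$insert, sep = "|")
  rt <- residue_table(structure)
  asa <- rowsum(asa_atom, group = factor(key, levels = rt$res_key))
  ref <- max_asa[rt$resid]
  if (anyNA(ref)) {
    warning("no reference maximum ASA for residue type(s) ",
            paste(unique(rt$resid[is.na(ref)]), collapse = ", "),
            "; using the table mean")
    ref[is.na(ref)] <- mean(max_asa)
  }
  rasa <- as.numeric(asa) / as.numeric(ref)
  high <- sum(rasa > 1.2)
  if (high > 0)
    warning(high, " residue(s) with relative ASA above 1.2")
  data.frame(asa = as.numeric(asa), rasa = rasa)
}
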