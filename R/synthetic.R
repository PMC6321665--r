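#' Specification of a synthetic labeled dataset
#'
#' Describes a two-class Gaussian dataset emulating the scale and class
#' balance of the early-folding-residue problem: by default 27 features and
#' a 14.8\% positive (EARLY) fraction. A small subset of informative
#' features separates the classes by a mean shift, optional feature pairs
#' carry a within-class correlation, and everything else is noise.
#'
#' @param n Number of rows.
#' @param d Number of features (default 27, named like the residue feature
#'   table when \code{d <= 27}).
#' @param positive_fraction Fraction of EARLY rows in (0, 1); the positive
#'   count is \code{round(n * positive_fraction)}.
#' @param informative Integer indices of informative features.
#' @param delta Per-class mean shift of the informative features (EARLY at
#'   +delta/2, LATE at -delta/2); scalar or one value per informative index.
#' @param correlated_pairs Optional data frame (or list of triples) with
#'   columns \code{i}, \code{j}, \code{rho}: within-class correlation
#'   between features i and j.
#' @param noise_sd Within-class standard deviation of every feature.
#' @param seed Integer seed; generation is deterministic per seed.
#' @return Object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n, d = 27L, positive_fraction = 0.148,
                           informative = integer(0), delta = 1,
                           correlated_pairs = NULL, noise_sd = 1,
                           seed = 42L) {
  stopifnot(n >= 2, d >= 1, positive_fraction > 0, positive_fraction < 1,
            noise_sd > 0)
  informative <- as.integer(informative)
  if (anyDuplicated(informative)) stop("informative indices must be distinct")
  if (length(informative) && (min(informative) < 1 || max(informative) > d))
    stop("informative indices out of range")
  if (!is.null(correlated_pairs) && !is.data.frame(correlated_pairs))
    correlated_pairs <- as.data.frame(do.call(rbind, correlated_pairs)) |>
      setNames(c("i", "j", "rho"))
  structure(list(n = as.integer(n), d = as.integer(d),
                 positive_fraction = positive_fraction,
                 informative = informative,
                 delta = rep_len(delta, max(1L, length(informative))),
                 correlated_pairs = correlated_pairs,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a labeled Gaussian dataset
#'
#' Draws class-conditional multivariate Gaussians according to a
#' \code{\link{synthetic_spec}}: informative features are shifted by
#' +/- delta/2 between the classes, correlated pairs share the specified
#' within-class correlation, and all features have standard deviation
#' \code{noise_sd}. Row identifiers mimic the residue table (a synthetic
#' protein id, chain A, sequence index, a non-proline amino acid).
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @return Feature table with id columns, \code{d} feature columns and a
#'   \code{label} column over EARLY/LATE.
#' @export
gaussian_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  d <- spec$d; n <- spec$n
  R <- diag(d)
  cp <- spec$correlated_pairs
  if (!is.null(cp) && nrow(cp)) {
    for (r in seq_len(nrow(cp)))
      R[cp$i[r], cp$j[r]] <- R[cp$j[r], cp$i[r]] <- cp$rho[r]
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("requested correlations produce a non-positive-semidefinite ",
         "covariance (min eigenvalue ", format(min(ev)), ")")
  L <- chol(R + diag(1e-12, d))
  n_pos <- round(n * spec$positive_fraction)
  if (n_pos < 1 || n_pos > n - 1)
    stop("positive_fraction leaves a class empty at this n")
  .with_seed(spec$seed, {
    lab <- rep("LATE", n)
    lab[sample.int(n, n_pos)] <- "EARLY"
    Z <- matrix(rnorm(n * d), n, d) %*% L * spec$noise_sd
    if (length(spec$informative)) {
      shift <- ifelse(lab == "EARLY", 0.5, -0.5)
      for (k in seq_along(spec$informative))
        Z[, spec$informative[k]] <- Z[, spec$informative[k]] +
          shift * spec$delta[k]
    }
    cn <- if (d <= length(.FEATURE_NAMES)) .FEATURE_NAMES[seq_len(d)] else
      c(.FEATURE_NAMES, paste0("feat", seq_len(d -
        length(.FEATURE_NAMES))))[seq_len(d)]
    colnames(Z) <- cn
    out <- data.frame(protein_id = "SYNTH", chain_id = "A",
                      seq_index = seq_len(n), amino_acid = "ALA",
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(Z))
    out$label <- lab
    out
  })
}

# ---- toy structures --------------------------------------------------------

# Natural-extension-reference-frame placement: position of atom D given the
# three preceding atoms and internal coordinates (bond length to C, bond
# angle B-C-D in degrees, torsion A-B-C-D in degrees).
.place_atom <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- .cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# ideal backbone internal coordinates (Angstrom / degrees)
.BB <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
            ca_cb = 1.53, ang_n_ca_c = 111.2, ang_ca_c_n = 116.2,
            ang_c_n_ca = 121.7, ang_ca_c_o = 120.8, ang_c_ca_cb = 110.1,
            tor_n_c_ca_cb = 122.55, omega = 180)

# full-backbone chain with constant phi/psi; ALA residues (N, CA, C, O, CB)
.ideal_chain <- function(n_res, phi, psi, jitter = 0, resid = "ALA") {
  bb <- .BB
  atoms <- list()
  # seed residue in the xy-plane
  N <- c(0, 0, 0)
  CA <- c(bb$n_ca, 0, 0)
  ang <- bb$ang_n_ca_c * pi / 180
  C <- CA + bb$ca_c * c(cos(pi - ang), sin(pi - ang), 0)
  pos <- list()
  for (i in seq_len(n_res)) {
    pos[[i]] <- list(N = N, CA = CA, C = C)
    if (i < n_res) {
      N2 <- .place_atom(N, CA, C, bb$c_n, bb$ang_ca_c_n, psi)
      CA2 <- .place_atom(CA, C, N2, bb$n_ca, bb$ang_c_n_ca, bb$omega)
      C2 <- .place_atom(C, N2, CA2, bb$ca_c, bb$ang_n_ca_c, phi)
      N <- N2; CA <- CA2; C <- C2
    }
  }
  rows <- list()
  for (i in seq_len(n_res)) {
    p <- pos[[i]]
    O <- .place_atom(p$N, p$CA, p$C, bb$c_o, bb$ang_ca_c_o, psi + 180)
    CB <- .place_atom(p$N, p$C, p$CA, bb$ca_cb, bb$ang_c_ca_cb,
                      bb$tor_n_c_ca_cb)
    nm <- c("N", "CA", "C", "O", if (resid != "GLY") "CB")
    el <- c("N", "C", "C", "O", if (resid != "GLY") "C")
    xyz <- rbind(p$N, p$CA, p$C, O, if (resid != "GLY") CB)
    rows[[i]] <- data.frame(chain = "A", resno = i, insert = "",
                            resid = resid, elety = nm, elesy = el,
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            stringsAsFactors = FALSE)
  }
  at <- do.call(rbind, rows)
  if (jitter > 0) {
    at$x <- at$x + rnorm(nrow(at), sd = jitter)
    at$y <- at$y + rnorm(nrow(at), sd = jitter)
    at$z <- at$z + rnorm(nrow(at), sd = jitter)
  }
  at
}

# C-alpha grid blob: points on a cubic lattice (spacing 5 A) in a sequence
# order that keeps consecutive residues adjacent
.blob_coords <- function(m, origin, spacing = 5) {
  side <- ceiling(m^(1 / 3))
  coords <- matrix(0, m, 3)
  k <- 1L
  for (iz in seq_len(side)) {
    for (iy in seq_len(side)) {
      xs <- seq_len(side)
      if (iy %% 2 == 0) xs <- rev(xs)   # serpentine path
      for (ix in xs) {
        if (k > m) break
        coords[k, ] <- origin + spacing * c(ix - 1, iy - 1, iz - 1)
        k <- k + 1L
      }
    }
  }
  coords
}

#' Generate a toy protein structure
#'
#' Three deterministic structure generators used to exercise the feature
#' pipeline without downloads: an ideal alpha-helix (phi = -57, psi = -47),
#' an extended beta-strand (phi = -120, psi = 130), both with full backbone
#' plus C-beta atoms built from standard internal coordinates, and
#' \code{two_blob}: two compact C-alpha clusters joined by an extended
#' linker, which guarantees long-range distance contacts (nonzero distinct
#' neighborhood counts).
#'
#' @param kind One of \code{"helix"}, \code{"strand"}, \code{"two_blob"}.
#' @param n_res Number of residues (at least 4; at least 20 for
#'   \code{two_blob}).
#' @param seed Integer seed for the small coordinate jitter.
#' @param jitter Coordinate noise sd in Angstrom (default 0, ideal
#'   geometry).
#' @return A \code{protein_structure}.
#' @export
toy_structure <- function(kind = c("helix", "strand", "two_blob"),
                          n_res = 20L, seed = 42L, jitter = 0) {
  kind <- match.arg(kind)
  if (n_res < 4L) stop("n_res must be at least 4")
  .with_seed(seed, {
    if (kind == "helix") {
      at <- .ideal_chain(n_res, phi = -57, psi = -47, jitter = jitter)
    } else if (kind == "strand") {
      at <- .ideal_chain(n_res, phi = -120, psi = 130, jitter = jitter)
    } else {
      if (n_res < 20L) stop("two_blob needs at least 20 residues")
      n_link <- 4L
      m1 <- (n_res - n_link) %/% 2L
      m2 <- n_res - n_link - m1
      b1 <- .blob_coords(m1, origin = c(0, 0, 0))
      b2_origin <- c(max(b1[, 1]) + n_link * 7 + 14, 0, 0)
      b2 <- .blob_coords(m2, origin = b2_origin)
      start <- b1[m1, ]; end <- b2[1, ]
      frac <- seq_len(n_link) / (n_link + 1)
      link <- t(vapply(frac, function(f) start + f * (end - start),
                       numeric(3)))
      xyz <- rbind(b1, link, b2)
      if (jitter > 0) xyz <- xyz + rnorm(length(xyz), sd = jitter)
      at <- data.frame(chain = "A", resno = seq_len(n_res), insert = "",
                       resid = "GLY", elety = "CA", elesy = "C",
                       x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                       stringsAsFactors = FALSE)
    }
    .protein_structure(at, source = paste0("toy:", kind))
  })
}
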