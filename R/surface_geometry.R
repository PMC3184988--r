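# Solvent accessibility and surface-shape descriptors.
#
# ASA: Shrake-Rupley quadrature on a deterministic golden-spiral point set
# (probe 1.4 A, NACCESS-like heavy-atom radii). RASA divides residue ASA by
# the residue type's maximum in a Gly-X-Gly tri-peptide. DPX is the distance
# of a buried atom to the nearest solvent-accessible atom; CX is the ratio
# of empty to occupied volume in a 10 A sphere around each atom.

#' Maximum residue ASA in a Gly-X-Gly tri-peptide (A^2)
#'
#' Tri-peptide maximum accessible surface areas per residue type
#' (Rost & Sander values), used as RASA denominators.
#' @keywords internal
MAX_ASA_TRIPEPTIDE <- c(
  ALA = 106, ARG = 248, ASN = 157, ASP = 163, CYS = 135,
  GLN = 198, GLU = 194, GLY = 84,  HIS = 184, ILE = 169,
  LEU = 164, LYS = 205, MET = 188, PHE = 197, PRO = 136,
  SER = 130, THR = 142, TRP = 227, TYR = 222, VAL = 142
)

ELEMENT_RADII <- c(C = 1.87, N = 1.65, O = 1.40, S = 1.85)
DEFAULT_RADIUS <- 1.80
BACKBONE_ATOMS <- c("N", "CA", "C", "O")

element_radii <- function(elements) {
  r <- unname(ELEMENT_RADII[elements])
  unknown <- is.na(r)
  if (any(unknown)) {
    warning(sprintf("unknown element(s) %s: using fallback radius %.2f A",
                    paste(unique(elements[unknown]), collapse = ","),
                    DEFAULT_RADIUS))
    r[unknown] <- DEFAULT_RADIUS
  }
  r
}

# Deterministic near-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom's solvent-accessible sphere (van der Waals radius + probe) is
#' sampled with a deterministic golden-spiral point set; a point is
#' accessible when no neighboring atom's probe-expanded sphere covers it.
#'
#' @param atoms Data frame of heavy atoms with columns x, y, z, element.
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param n_points Quadrature points per atom (default 960).
#' @return List of class `hemenet_sasa`: `asa` (per-atom, A^2), `probe`,
#'   `n_points`, `radii`.
#' @export
shrake_rupley_asa <- function(atoms, probe = 1.4, n_points = 960) {
  stopifnot(probe > 0, n_points >= 100)
  n <- nrow(atoms)
  coords <- cbind(atoms$x, atoms$y, atoms$z)
  r <- element_radii(atoms$element)
  pts <- sphere_points(n_points)
  asa <- numeric(n)
  R <- r + probe
  if (n > 1L) {
    d2 <- outer(rowSums(coords^2), rowSums(coords^2), "+") -
      2 * tcrossprod(coords)
  }
  for (i in seq_len(n)) {
    p <- sweep(pts * R[i], 2, coords[i, ], "+")
    free <- rep(TRUE, n_points)
    if (n > 1L) {
      # only neighbors whose expanded sphere can reach atom i's test sphere
      nb <- setdiff(which(sqrt(pmax(d2[i, ], 0)) < R[i] + R), i)
      for (j in nb) {
        if (!any(free)) break
        dj2 <- (p[, 1] - coords[j, 1])^2 + (p[, 2] - coords[j, 2])^2 +
          (p[, 3] - coords[j, 3])^2
        free <- free & dj2 >= R[j]^2
      }
    }
    asa[i] <- 4 * pi * R[i]^2 * mean(free)
  }
  structure(list(asa = asa, probe = probe, n_points = n_points, radii = r),
            class = "hemenet_sasa")
}

#' Per-residue ASA and relative ASA
#'
#' Residue ASA is the sum of its heavy-atom ASA values; RASA divides by the
#' tri-peptide maximum for the residue type and is clamped to `[0, 1]`.
#'
#' @param sasa A `hemenet_sasa` computed on `atom_tbl`.
#' @param residues Residue list the SASA was computed over (heavy atoms,
#'   concatenated in residue order).
#' @return Data frame: id, res_type, asa, rasa.
#' @export
residue_rasa <- function(sasa, residues) {
  tbl <- atom_table(residues)
  stopifnot(length(sasa$asa) == nrow(tbl))
  asa_res <- vapply(seq_along(residues), function(i) {
    sum(sasa$asa[tbl$res_index == i])
  }, numeric(1))
  types <- vapply(residues, function(r) r$res_type %||% NA_character_, "")
  mx <- MAX_ASA_TRIPEPTIDE[types]
  rasa <- pmin(1, asa_res / mx)
  data.frame(id = vapply(residues, residue_id, ""),
             res_type = types, asa = asa_res, rasa = unname(rasa),
             stringsAsFactors = FALSE)
}

#' Per-atom depth index (DPX)
#'
#' Depth of a buried atom is its Euclidean distance to the nearest
#' solvent-accessible atom (ASA > 0); solvent-accessible atoms have depth 0.
#'
#' @param atoms Data frame of heavy atoms with x, y, z.
#' @param sasa A `hemenet_sasa` for the same atoms.
#' @return Numeric vector of depths in Angstrom.
#' @export
dpx_per_atom <- function(atoms, sasa) {
  stopifnot(nrow(atoms) == length(sasa$asa))
  exposed <- sasa$asa > 0
  if (!any(exposed)) {
    stop("no solvent-accessible atom in structure: DPX undefined",
         call. = FALSE)
  }
  coords <- cbind(atoms$x, atoms$y, atoms$z)
  ex <- coords[exposed, , drop = FALSE]
  dpx <- numeric(nrow(atoms))
  buried <- which(!exposed)
  for (i in buried) {
    dpx[i] <- min(dist_to_point(ex, coords[i, ]))
  }
  dpx
}

#' Per-atom protrusion index (CX)
#'
#' Ratio of empty to occupied volume in a sphere of radius `radius` around
#' each atom: `CX = (V_sphere - V_int) / V_int`, with the internal volume
#' estimated as the atom count inside the sphere (the atom itself included)
#' times a mean atom volume.
#'
#' @param atoms Data frame of heavy atoms with x, y, z.
#' @param radius Sphere radius in Angstrom (default 10).
#' @param v_atom Mean heavy-atom volume in A^3 (default 20.1).
#' @return Numeric vector of protrusion values.
#' @export
cx_per_atom <- function(atoms, radius = 10.0, v_atom = 20.1) {
  stopifnot(radius > 0, v_atom > 0)
  coords <- cbind(atoms$x, atoms$y, atoms$z)
  v_sphere <- 4 / 3 * pi * radius^3
  vapply(seq_len(nrow(coords)), function(i) {
    n_in <- sum(dist_to_point(coords, coords[i, ]) <= radius)
    v_int <- v_atom * n_in
    (v_sphere - v_int) / v_int
  }, numeric(1))
}

six_stats <- function(v) {
  c(mean_all = mean(v), sd_all = pop_sd(v),
    mean_sc = NA_real_, sd_sc = NA_real_,
    min_all = min(v), max_all = max(v))
}

#' Six-statistic per-residue profile of a per-atom value
#'
#' For each residue: mean and (population) SD over all heavy atoms, mean and
#' SD over side-chain heavy atoms (non-backbone; glycine and other residues
#' without side-chain heavy atoms fall back to the all-atom statistics), and
#' the minimum and maximum atom values.
#'
#' @param values Per-atom numeric vector aligned with `atom_table(residues)`.
#' @param residues Residue list.
#' @param prefix Column-name prefix (e.g. "dpx").
#' @return Data frame with columns `<prefix>_{mean_all, sd_all, mean_sc,
#'   sd_sc, min_all, max_all}` plus an id column.
#' @export
residue_geometry_profile <- function(values, residues, prefix = "v") {
  tbl <- atom_table(residues)
  stopifnot(length(values) == nrow(tbl))
  rows <- lapply(seq_along(residues), function(i) {
    sel <- tbl$res_index == i
    v <- values[sel]
    st <- six_stats(v)
    sc <- !(tbl$name[sel] %in% BACKBONE_ATOMS)
    if (any(sc)) {
      st["mean_sc"] <- mean(v[sc])
      st["sd_sc"] <- pop_sd(v[sc])
    } else {
      st["mean_sc"] <- st["mean_all"]
      st["sd_sc"] <- st["sd_all"]
    }
    st
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- paste0(prefix, "_", names(out))
  cbind(data.frame(id = vapply(residues, residue_id, ""),
                   stringsAsFactors = FALSE), out)
}

#' Full per-residue surface profile
#'
#' Runs the ASA quadrature, RASA, DPX and CX computations for a residue list
#' and returns one row per residue with ASA, RASA and the six-statistic DPX
#' and CX profiles.
#'
#' @param residues Residue list (heavy atoms are used).
#' @param config A [hemenet_config()] (probe radius, quadrature points, CX
#'   sphere radius and atom volume are taken from it).
#' @return Data frame keyed by residue id.
#' @export
surface_profile <- function(residues, config = hemenet_config()) {
  tbl <- atom_table(residues)
  sasa <- shrake_rupley_asa(tbl, probe = config$probe_radius,
                            n_points = config$sasa_points)
  ra <- residue_rasa(sasa, residues)
  dpx <- dpx_per_atom(tbl, sasa)
  cx <- cx_per_atom(tbl, radius = config$cx_radius,
                    v_atom = config$cx_atom_volume)
  dpx_prof <- residue_geometry_profile(dpx, residues, prefix = "dpx")
  cx_prof <- residue_geometry_profile(cx, residues, prefix = "cx")
  cbind(ra, dpx_prof[, -1, drop = FALSE], cx_prof[, -1, drop = FALSE])
}
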