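# Run configuration: every tunable cutoff and model parameter in one place.

#' Pipeline configuration
#'
#' Collects all tunable parameters with their defaults: 5 A heavy-atom
#' contact cutoff for the residue network, 4.5 A ligand-contact cutoff for
#' binding labels, HEM/HEC heme codes, 14 spatial window neighbors, a 1.4 A
#' solvent probe with 960 quadrature points, a 10 A / 20.1 A^3 protrusion
#' sphere, and the RBF-SVM penalty C = 2 with kernel width gamma = 0.03125.
#'
#' @param contact_cutoff Heavy-atom contact cutoff in Angstrom for network
#'   edges (strictly-less-than rule).
#' @param ligand_cutoff Heavy-atom distance in Angstrom within which a
#'   surface residue is labeled heme-binding.
#' @param heme_codes Hetero residue names treated as heme groups.
#' @param window_neighbors Number of spatially nearest residues added to the
#'   target residue's structural window.
#' @param probe_radius Solvent probe radius in Angstrom.
#' @param sasa_points Quadrature points per atom for the ASA computation.
#' @param cx_radius Protrusion sphere radius in Angstrom.
#' @param cx_atom_volume Mean heavy-atom volume in A^3 for protrusion.
#' @param asa_epsilon Residues with ASA less than or equal to this are
#'   excluded as buried (exact zero by default).
#' @param svm_cost SVM penalty parameter C.
#' @param svm_gamma RBF kernel width gamma.
#' @param seed Seed for balanced sampling and fold assignment.
#' @param mask Feature subsets to assemble: any combination of "N" (network),
#'   "G" (geometry), "C" (conservation).
#' @param decision_threshold Decision-value threshold for calling a residue
#'   binding.
#' @return Named list of class `hemenet_config`.
#' @export
hemenet_config <- function(contact_cutoff = 5.0,
                           ligand_cutoff = 4.5,
                           heme_codes = c("HEM", "HEC"),
                           window_neighbors = 14L,
                           probe_radius = 1.4,
                           sasa_points = 960L,
                           cx_radius = 10.0,
                           cx_atom_volume = 20.1,
                           asa_epsilon = 0.0,
                           svm_cost = 2.0,
                           svm_gamma = 0.03125,
                           seed = 1L,
                           mask = c("N", "G", "C"),
                           decision_threshold = 0.0) {
  stopifnot(contact_cutoff > 0, ligand_cutoff > 0, window_neighbors >= 0,
            probe_radius > 0, sasa_points >= 100, cx_radius > 0,
            cx_atom_volume > 0, svm_cost > 0, svm_gamma > 0,
            asa_epsilon >= 0)
  mask <- match.arg(mask, c("N", "G", "C"), several.ok = TRUE)
  structure(list(contact_cutoff = contact_cutoff,
                 ligand_cutoff = ligand_cutoff,
                 heme_codes = heme_codes,
                 window_neighbors = as.integer(window_neighbors),
                 probe_radius = probe_radius,
                 sasa_points = as.integer(sasa_points),
                 cx_radius = cx_radius,
                 cx_atom_volume = cx_atom_volume,
                 asa_epsilon = asa_epsilon,
                 svm_cost = svm_cost,
                 svm_gamma = svm_gamma,
                 seed = as.integer(seed),
                 mask = mask,
                 decision_threshold = decision_threshold),
            class = "hemenet_config")
}

#' Write a configuration to a YAML file
#' @param config A `hemenet_config`.
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a configuration from a YAML file
#'
#' Unset keys fall back to the defaults of [hemenet_config()]; unknown keys
#' are an error.
#' @param path YAML file path.
#' @return A `hemenet_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(hemenet_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(hemenet_config, vals)
}
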