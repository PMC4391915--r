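#' Specification for a synthetic concentration-response experiment
#'
#' Describes a dual-luciferase transactivation experiment whose
#' firefly/renilla fold response follows a four-parameter logistic (4PL)
#' curve with variable slope. [simulate_dose_response()] turns a spec into a
#' per-well plate table.
#'
#' @param ec50 Half-maximal effective concentration, nM (> 0).
#' @param emax Top plateau in fold-activation units (> `bottom`).
#' @param bottom Bottom plateau, fold-activation; vehicle wells sit here.
#' @param hill Hill slope (dimensionless).
#' @param doses Numeric vector of ligand concentrations in nM; may include 0
#'   (vehicle wells).
#' @param replicates Wells per dose (>= 1).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise applied to each firefly reading (>= 0).
#' @param renilla_mean,renilla_cv Level and relative variability of the
#'   renilla internal-control readings (RLU).
#' @param construct Label for the receptor construct.
#' @param coregulators Character vector of coregulator labels co-transfected
#'   in this experiment (empty for receptor alone).
#' @param seed Integer seed; generation is deterministic given the spec.
#'
#' @return An object of class `dr_sim_spec`.
#' @seealso [simulate_dose_response()]
#' @export
dr_sim_spec <- function(ec50, emax, bottom = 1, hill = 1,
                        doses = c(0, 0.12 * 10^(4 * (0:7) / 7)),
                        replicates = 4, noise_cv = 0.1,
                        renilla_mean = 1e4, renilla_cv = 0.05,
                        construct = "VDR", coregulators = character(),
                        seed = 1L) {
  stopifnot_scalar_pos(ec50, "ec50")
  stopifnot_scalar_pos(emax - bottom, "emax - bottom")
  stopifnot_scalar_pos(replicates, "replicates")
  if (replicates != round(replicates) || replicates < 1) {
    stop("'replicates' must be an integer >= 1", call. = FALSE)
  }
  stopifnot_scalar_pos(noise_cv, "noise_cv", strict = FALSE)
  stopifnot_scalar_pos(renilla_mean, "renilla_mean")
  stopifnot_scalar_pos(renilla_cv, "renilla_cv", strict = FALSE)
  if (!is.numeric(doses) || length(doses) == 0 || any(doses < 0)) {
    stop("'doses' must be non-negative concentrations (nM)", call. = FALSE)
  }
  structure(list(ec50 = ec50, emax = emax, bottom = bottom, hill = hill,
                 doses = doses, replicates = as.integer(replicates),
                 noise_cv = noise_cv, renilla_mean = renilla_mean,
                 renilla_cv = renilla_cv, construct = construct,
                 coregulators = coregulators, seed = as.integer(seed)),
            class = "dr_sim_spec")
}

#' Simulate a dual-luciferase concentration-response plate
#'
#' Generates one row per well. The renilla internal-control reading is drawn
#' around `renilla_mean`; the firefly reading is
#' `renilla * fold(dose) * noise`, where `fold(dose)` is the 4PL curve of the
#' spec and the noise is multiplicative lognormal with unit mean. Vehicle
#' wells (dose 0) are generated at the bottom plateau; they exercise the
#' ethanol-control normalization, not the fit.
#'
#' @param spec A [dr_sim_spec()].
#' @return A `data.frame` plate table with columns `construct`,
#'   `coregulators` (comma-joined labels, `""` if none), `dose_nM`,
#'   `replicate`, `firefly_rlu`, `renilla_rlu`.
#' @examples
#' plate <- simulate_dose_response(dr_sim_spec(ec50 = 5, emax = 51, seed = 1))
#' head(plate)
#' @export
simulate_dose_response <- function(spec) {
  if (!inherits(spec, "dr_sim_spec")) {
    stop("'spec' must be a dr_sim_spec", call. = FALSE)
  }
  n_well <- length(spec$doses) * spec$replicates
  dose <- rep(spec$doses, each = spec$replicates)
  with_seed(spec$seed, {
    renilla <- spec$renilla_mean * rlnorm_cv(n_well, spec$renilla_cv)
    fold <- fourpl_response(dose, spec$bottom, spec$emax, spec$hill, spec$ec50)
    firefly <- renilla * fold * rlnorm_cv(n_well, spec$noise_cv)
    data.frame(
      construct = spec$construct,
      coregulators = paste(spec$coregulators, collapse = ","),
      dose_nM = dose,
      replicate = rep(seq_len(spec$replicates), times = length(spec$doses)),
      firefly_rlu = firefly,
      renilla_rlu = renilla,
      stringsAsFactors = FALSE
    )
  })
}

#' Specification for a synthetic saturation-binding experiment
#'
#' One-site radioligand binding: specific counts follow the hyperbola
#' `bmax * x / (kd + x)` and nonspecific counts grow linearly with free
#' ligand concentration.
#'
#' @param kd Equilibrium dissociation constant, nM (> 0).
#' @param bmax Specific binding at saturation, counts (> 0).
#' @param ns_slope Nonspecific counts per nM of ligand (>= 0).
#' @param concentrations Ligand concentrations in nM (default 0-1.6 nM in
#'   nine steps, the range used for tritiated 1,25D3).
#' @param replicates Tubes per concentration (default 2, duplicate tubes).
#' @param noise_cv Multiplicative lognormal noise CV on each count.
#' @param seed Integer seed.
#' @return An object of class `binding_sim_spec`.
#' @seealso [simulate_binding()]
#' @export
binding_sim_spec <- function(kd, bmax, ns_slope = 0,
                             concentrations = seq(0, 1.6, by = 0.2),
                             replicates = 2, noise_cv = 0.1, seed = 1L) {
  stopifnot_scalar_pos(kd, "kd")
  stopifnot_scalar_pos(bmax, "bmax")
  stopifnot_scalar_pos(ns_slope, "ns_slope", strict = FALSE)
  stopifnot_scalar_pos(noise_cv, "noise_cv", strict = FALSE)
  if (!is.numeric(concentrations) || length(concentrations) == 0) {
    stop("'concentrations' must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(concentrations < 0)) {
    stop("'concentrations' must be >= 0", call. = FALSE)
  }
  if (replicates != round(replicates) || replicates < 1) {
    stop("'replicates' must be an integer >= 1", call. = FALSE)
  }
  structure(list(kd = kd, bmax = bmax, ns_slope = ns_slope,
                 concentrations = concentrations,
                 replicates = as.integer(replicates),
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "binding_sim_spec")
}

#' Simulate a saturation-binding table
#'
#' Per tube: `total_counts = (bmax*x/(kd+x) + ns_slope*x) * noise` and
#' `nonspecific_counts = ns_slope*x * noise` with independent multiplicative
#' lognormal noise draws (unit mean, CV `noise_cv`).
#'
#' @param spec A [binding_sim_spec()].
#' @return A `data.frame` with columns `conc_nM`, `replicate`,
#'   `total_counts`, `nonspecific_counts`.
#' @examples
#' simulate_binding(binding_sim_spec(kd = 0.5, bmax = 1e4, seed = 3))
#' @export
simulate_binding <- function(spec) {
  if (!inherits(spec, "binding_sim_spec")) {
    stop("'spec' must be a binding_sim_spec", call. = FALSE)
  }
  x <- rep(spec$concentrations, each = spec$replicates)
  n <- length(x)
  with_seed(spec$seed, {
    specific <- spec$bmax * x / (spec$kd + x)
    ns <- spec$ns_slope * x
    data.frame(
      conc_nM = x,
      replicate = rep(seq_len(spec$replicates),
                      times = length(spec$concentrations)),
      total_counts = (specific + ns) * rlnorm_cv(n, spec$noise_cv),
      nonspecific_counts = ns * rlnorm_cv(n, spec$noise_cv),
      stringsAsFactors = FALSE
    )
  })
}

#' Specification for a synthetic assay-by-species response matrix
#'
#' Emulates a functional-assay summary matrix (transactivation and mammalian
#' 2-hybrid readouts across VDR species) with a planted species partition:
#' assays flagged with a "driver" coregulator carry cluster-specific means
#' separated by `effect_size`; all other assays share a common mean. Gaussian
#' noise is added on top (the matrix is z-scored downstream, so the additive
#' scale is natural here).
#'
#' @param species_labels Character vector of species/receptor labels.
#' @param assay_ids Character vector of assay row identifiers.
#' @param coregulator_groups Named list mapping each assay id to a character
#'   vector of coregulator labels present in that assay (may be empty).
#' @param planted_partition Named integer/character vector mapping each
#'   species to a cluster id.
#' @param effect_size Separation (response units) between cluster means in
#'   driver assays.
#' @param driver_groups Coregulator labels whose assays carry the planted
#'   signal.
#' @param assay_types Optional character vector (`"TT"` or `"M2H"`) per
#'   assay; defaults to `"TT"`.
#' @param noise_sd Additive Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return An object of class `matrix_sim_spec`.
#' @seealso [simulate_assay_matrix()]
#' @export
matrix_sim_spec <- function(species_labels, assay_ids, coregulator_groups,
                            planted_partition, effect_size, driver_groups,
                            assay_types = NULL, noise_sd = 1, seed = 1L) {
  species_labels <- as.character(species_labels)
  assay_ids <- as.character(assay_ids)
  if (anyDuplicated(species_labels) || anyDuplicated(assay_ids)) {
    stop("species and assay labels must be unique", call. = FALSE)
  }
  if (!setequal(names(coregulator_groups), assay_ids)) {
    stop("every assay_id must be annotated in 'coregulator_groups'",
         call. = FALSE)
  }
  if (!setequal(names(planted_partition), species_labels)) {
    stop("every species must be assigned a cluster in 'planted_partition'",
         call. = FALSE)
  }
  stopifnot_scalar_pos(noise_sd, "noise_sd", strict = FALSE)
  all_labels <- unique(unlist(coregulator_groups, use.names = FALSE))
  unknown <- setdiff(driver_groups, all_labels)
  if (length(unknown)) {
    stop("driver_groups reference unknown coregulator labels: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(assay_types)) assay_types <- rep("TT", length(assay_ids))
  if (!all(assay_types %in% c("TT", "M2H")) ||
      length(assay_types) != length(assay_ids)) {
    stop("'assay_types' must be TT or M2H, one per assay", call. = FALSE)
  }
  structure(list(species_labels = species_labels, assay_ids = assay_ids,
                 coregulator_groups = coregulator_groups[assay_ids],
                 planted_partition = planted_partition[species_labels],
                 effect_size = effect_size, driver_groups = driver_groups,
                 assay_types = assay_types, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "matrix_sim_spec")
}

#' Simulate an assay-by-species matrix with planted cluster structure
#'
#' @param spec A [matrix_sim_spec()].
#' @return An [assay_matrix()] with `length(assay_ids)` rows and
#'   `length(species_labels)` columns; coregulator annotations are copied
#'   through.
#' @export
simulate_assay_matrix <- function(spec) {
  if (!inherits(spec, "matrix_sim_spec")) {
    stop("'spec' must be a matrix_sim_spec", call. = FALSE)
  }
  n_assay <- length(spec$assay_ids)
  n_sp <- length(spec$species_labels)
  is_driver <- vapply(spec$coregulator_groups,
                      function(g) length(intersect(g, spec$driver_groups)) > 0,
                      logical(1))
  cluster_code <- as.integer(factor(spec$planted_partition))
  with_seed(spec$seed, {
    vals <- matrix(rnorm(n_assay * n_sp, sd = spec$noise_sd),
                   nrow = n_assay, ncol = n_sp)
    # driver assays: cluster-specific means spaced effect_size apart
    if (any(is_driver)) {
      mu <- spec$effect_size * (cluster_code - mean(cluster_code))
      vals[is_driver, ] <- vals[is_driver, , drop = FALSE] +
        rep(mu, each = sum(is_driver))
    }
    dimnames(vals) <- list(spec$assay_ids, spec$species_labels)
    assay_matrix(vals, assay_type = spec$assay_types,
                 coregulators = spec$coregulator_groups)
  })
}

#' Simulate a coding nucleotide sequence for a protein of given length
#'
#' Builds `ATG` + (`protein_length` - 1) random non-stop codons + a random
#' stop codon, optionally embedded in random untranslated flanks. The flanks
#' are resampled until the intended reading frame is the longest
#' ATG-initiated ORF, so translation of the longest ORF always yields
#' `protein_length` residues.
#'
#' @param protein_length Number of residues in the encoded protein (>= 1).
#' @param seed Integer seed.
#' @param utr5,utr3 Lengths (nt) of random flanks around the ORF.
#' @return A single uppercase DNA string.
#' @examples
#' simulate_orf(3, seed = 1)
#' @export
simulate_orf <- function(protein_length, seed = 1L, utr5 = 0, utr3 = 0) {
  if (protein_length != round(protein_length) || protein_length < 1) {
    stop("'protein_length' must be an integer >= 1", call. = FALSE)
  }
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste0, collapse = "")
  sense <- setdiff(codons, stops)
  with_seed(seed, {
    body <- if (protein_length > 1) {
      sample(sense, protein_length - 1, replace = TRUE)
    } else character()
    orf <- paste0("ATG", paste(body, collapse = ""),
                  sample(stops, 1))
    for (attempt in seq_len(100L)) {
      seq <- paste0(
        paste(sample(c("A", "C", "G", "T"), utr5, replace = TRUE),
              collapse = ""),
        orf,
        paste(sample(c("A", "C", "G", "T"), utr3, replace = TRUE),
              collapse = "")
      )
      hit <- find_longest_orf(seq)
      if (!is.null(hit) && hit$n_res == protein_length) return(seq)
    }
    stop("could not embed ORF in random flanks", call. = FALSE)
  })
}
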