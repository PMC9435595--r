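#' Ideal poly-alanine helix model
#'
#' Builds an idealized alpha-helix (rise 1.5 angstroms, 100 degrees per
#' residue, canonical backbone radii) of `n_res` alanine residues with
#' N, CA, C, O and CB atoms, centered in the cell with a seeded random
#' rotation about the helix axis.
#'
#' @param n_res Number of residues (at least 3).
#' @param cell A [unit_cell()] (default 20 x 20 x 30 angstrom P1 box).
#' @param spacegroup Space-group symbol or [space_group()].
#' @param seed Integer seed; identical seeds give identical coordinates.
#' @param chain Chain id (default "A").
#' @return An [structure_model()].
#' @export
make_helix_model <- function(n_res, cell = unit_cell(20, 20, 30),
                             spacegroup = "P 1", seed = 1, chain = "A") {
  if (n_res < 3) stop("a helix needs at least 3 residues")
  twist <- 100 * pi / 180
  rise <- 1.5
  phi0 <- with_seed(seed, stats::runif(1, 0, 2 * pi))
  cyl <- function(r, dphi, dz, i) {
    th <- phi0 + twist * i + dphi
    c(r * cos(th), r * sin(th), rise * i + dz)
  }
  rows <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    ca <- cyl(2.30, 0, 0, i)
    n_ <- cyl(1.60, -28 * pi / 180, -0.95, i)
    c_ <- cyl(1.66, +28 * pi / 180, +0.95, i)
    th_c <- phi0 + twist * i + 28 * pi / 180
    o_ <- c_ + 1.23 * c(cos(th_c) * 0.55, sin(th_c) * 0.55, 0.84)
    th <- phi0 + twist * i
    cb <- ca + 1.53 * c(cos(th) * 0.90, sin(th) * 0.90, -0.44)
    rows[[i]] <- data.frame(
      chain = chain, seqnum = i, icode = "", resname = "ALA",
      atom = c("N", "CA", "C", "O", "CB"), element = c("N", "C", "C", "O", "C"),
      x = c(n_[1], ca[1], c_[1], o_[1], cb[1]),
      y = c(n_[2], ca[2], c_[2], o_[2], cb[2]),
      z = c(n_[3], ca[3], c_[3], o_[3], cb[3]),
      occ = 1, b = 20, stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  # center the helix in the cell
  ctr_frac <- c(0.5, 0.5, 0.5)
  ctr <- orthogonalize(cell, ctr_frac)
  mid <- c(mean(range(atoms$x)), mean(range(atoms$y)), mean(range(atoms$z)))
  atoms$x <- atoms$x + ctr[1] - mid[1]
  atoms$y <- atoms$y + ctr[2] - mid[2]
  atoms$z <- atoms$z + ctr[3] - mid[3]
  model <- structure_model(cell, spacegroup, atoms)
  fr <- fractionalize(cell, atom_coords(model))
  if (any(fr < 0.02) || any(fr > 0.98))
    stop("helix of ", n_res, " residues does not fit this cell; ",
         "use a larger cell")
  model
}

#' Randomly perturb a model to a target RMSD
#'
#' Adds zero-mean Gaussian displacements rescaled so the all-atom RMSD
#' to the input equals `rmsd_target` exactly.
#'
#' @param model An [structure_model()].
#' @param rmsd_target Target all-atom RMSD in angstroms (0 = identity).
#' @param seed Integer seed.
#' @return The perturbed model.
#' @export
perturb_model <- function(model, rmsd_target, seed = 1) {
  if (rmsd_target < 0) stop("rmsd_target must be non-negative")
  if (rmsd_target == 0 || !nrow(model$atoms)) return(model)
  n <- nrow(model$atoms)
  D <- with_seed(seed, matrix(stats::rnorm(3 * n), n, 3))
  D <- D * rmsd_target / sqrt(mean(rowSums(D^2)))
  a <- model$atoms
  a$x <- a$x + D[, 1]; a$y <- a$y + D[, 2]; a$z <- a$z + D[, 3]
  structure_model(model$cell, model$spacegroup, a)
}

#' Delete a random residue subset
#'
#' @param model An [structure_model()].
#' @param fraction Fraction of residues to delete, in `[0, 1]`;
#'   `round(fraction * n)` residues are removed.
#' @param seed Integer seed.
#' @return The reduced model.
#' @export
delete_residues <- function(model, fraction, seed = 1) {
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  rt <- residue_table(model)
  ndel <- round(fraction * nrow(rt))
  if (ndel == 0) return(model)
  victims <- with_seed(seed, sample(rt$key, ndel))
  subset_residues(model, victims, drop = TRUE)
}

#' Generate synthetic per-residue scores
#'
#' Residues named in `correct_ids` draw main-chain / side-chain
#' correctness from a high band (0.7 to 0.95) and LLK values around +5;
#' all others draw from a low band (0.01 to 0.2) with LLK around -5.
#' A deterministic stand-in for an external scoring engine.
#'
#' @param model An [structure_model()].
#' @param correct_ids Residue keys considered correct (default: all).
#' @param seed Integer seed.
#' @return A [residue_scores()].
#' @export
make_scores <- function(model, correct_ids = NULL, seed = 1) {
  rt <- residue_table(model)
  rt <- rt[rt$category == "protein", , drop = FALSE]
  if (is.null(correct_ids)) correct_ids <- rt$key
  good <- rt$key %in% correct_ids
  n <- nrow(rt)
  vals <- with_seed(seed, {
    list(mc = stats::runif(n, 0.7, 0.95), mc_bad = stats::runif(n, 0.01, 0.2),
         sc = stats::runif(n, 0.7, 0.95), sc_bad = stats::runif(n, 0.01, 0.2),
         llk = stats::rnorm(n, 5, 1), llk_bad = stats::rnorm(n, -5, 1))
  })
  residue_scores(data.frame(
    chain = rt$chain, seqnum = rt$seqnum, icode = rt$icode,
    main_chain = ifelse(good, vals$mc, vals$mc_bad),
    side_chain = ifelse(good, vals$sc, vals$sc_bad),
    llk = ifelse(good, vals$llk, vals$llk_bad),
    stringsAsFactors = FALSE))
}

#' Scenario specification for scripted pipeline runs
#'
#' Bundles everything the scripted backend suite needs: the reference
#' structure, a per-cycle R_free trajectory and the builder's
#' deletion / perturbation schedule.
#'
#' @param reference Reference [structure_model()].
#' @param trajectory Per-cycle R_free values in (0, 1); the run errors
#'   if the pipeline outlives the trajectory.
#' @param rwork_offset R_work is the cycle's R_free minus this offset
#'   (default 0.03).
#' @param deletion_fraction Initial builder deletion fraction (default
#'   0; 0 is the "perfect builder").
#' @param perturbation_rmsd Initial builder coordinate noise (default 0).
#' @param improve_cycles Cycles over which deletion/noise decay to zero
#'   (default 3).
#' @param dummy_delta,water_delta Shift applied to the scripted R
#'   factors for refinements of models containing dummy atoms / waters
#'   (positive = worse, so the step is rejected; defaults +0.01).
#' @param make_maps Whether density modification returns a real map
#'   (default TRUE); `FALSE` skips all density-based steps, which is
#'   convenient for pure control-flow scenarios.
#' @param bad_chains Chain ids scored in the low band (default none).
#' @param seed Integer seed for all stochastic pieces.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(reference, trajectory, rwork_offset = 0.03,
                          deletion_fraction = 0, perturbation_rmsd = 0,
                          improve_cycles = 3, dummy_delta = 0.01,
                          water_delta = 0.01, make_maps = TRUE,
                          bad_chains = character(0), seed = 1) {
  if (!length(trajectory)) stop("trajectory must be non-empty")
  if (any(trajectory <= 0 | trajectory >= 1))
    stop("trajectory values must lie in (0, 1)")
  structure(list(reference = reference, trajectory = trajectory,
                 rwork_offset = rwork_offset,
                 deletion_fraction = deletion_fraction,
                 perturbation_rmsd = perturbation_rmsd,
                 improve_cycles = improve_cycles,
                 dummy_delta = dummy_delta, water_delta = water_delta,
                 make_maps = make_maps, bad_chains = bad_chains, seed = seed),
            class = "scenario_spec")
}

#' Scripted backend suite
#'
#' Mock engines driven by a [scenario_spec()]: `refine` returns the
#' scripted (R_work, R_free) for the current cycle (shifted by
#' `dummy_delta` / `water_delta` when the refined model carries dummy
#' atoms or waters, so acceptance behaviour can be scripted);
#' `build_protein` returns the reference with the scenario's deletion
#' and noise applied, improving per cycle; `density_modify` returns a
#' synthetic map of the current model; scores come from [make_scores()].
#'
#' @param spec A [scenario_spec()].
#' @return A [backend_suite()].
#' @export
scripted_backends <- function(spec) {
  env <- new.env(parent = emptyenv())
  env$cycle <- 0L
  cycle_value <- function() {
    idx <- max(1L, env$cycle)
    if (idx > length(spec$trajectory))
      stop("scripted trajectory exhausted at cycle ", idx)
    spec$trajectory[idx]
  }
  refine <- function(model, reflections, n_cycles, use_phases) {
    rf <- cycle_value()
    if (any(model$atoms$category == "dummy")) rf <- rf + spec$dummy_delta
    else if (any(model$atoms$category == "water")) rf <- rf + spec$water_delta
    list(model = model, r_work = max(0.001, rf - spec$rwork_offset),
         r_free = rf)
  }
  build_protein <- function(map, reflections, sequence, model, seeds, n_cycles) {
    decay <- max(0, 1 - (max(1L, env$cycle) - 1) / spec$improve_cycles)
    m <- spec$reference
    if (spec$deletion_fraction * decay > 0)
      m <- delete_residues(m, spec$deletion_fraction * decay,
                           seed = spec$seed + env$cycle)
    if (spec$perturbation_rmsd * decay > 0)
      m <- perturb_model(m, spec$perturbation_rmsd * decay,
                         seed = spec$seed + env$cycle)
    m
  }
  backend_suite(
    refine = refine,
    shift_field_refine = function(model, reflections, n_cycles, schedule) model,
    density_modify = function(reflections, model) {
      if (!spec$make_maps) return(NULL)
      src <- if (!is.null(model) && nrow(model$atoms)) model else spec$reference
      map_from_model(src, grid_spacing = 1.0, atom_width_B = 10)
    },
    build_protein = build_protein,
    build_nucleic = function(map, reflections, sequence, model, n_cycles) model,
    rebuild_side_chain = function(model, residue_key) model,
    score_residues = function(model, map) {
      rt <- residue_table(model)
      good <- rt$key[!(rt$chain %in% spec$bad_chains)]
      make_scores(model, correct_ids = good, seed = spec$seed)
    },
    on_cycle_start = function(i) env$cycle <- as.integer(i))
}

#' Toy-physics backend suite
#'
#' A minimal self-contained stand-in for the refinement engine: refine
#' leaves coordinates untouched and computes real R factors from the
#' observed amplitudes by direct-summation structure factors with a
#' least-squares scale; the builder returns the reference structure
#' (optionally noised). Useful for end-to-end runs where the R factors
#' must respond to the model.
#'
#' @param reference Reference [structure_model()].
#' @param rs_obs Observed [reflection_set()] with free flags, typically
#'   amplitudes computed from `reference`.
#' @param builder_rmsd Coordinate noise applied by the builder (default
#'   0: perfect builder).
#' @param seed Integer seed.
#' @return A [backend_suite()].
#' @export
toy_backends <- function(reference, rs_obs, builder_rmsd = 0, seed = 1) {
  env <- new.env(parent = emptyenv())
  env$cycle <- 0L
  refine <- function(model, reflections, n_cycles, use_phases) {
    if (!nrow(model$atoms))
      return(list(model = model, r_work = 0.99, r_free = 0.99))
    rr <- r_factor(rs_obs, model)
    list(model = model, r_work = rr$r_work,
         r_free = if (is.na(rr$r_free)) rr$r_work else rr$r_free)
  }
  backend_suite(
    refine = refine,
    shift_field_refine = function(model, reflections, n_cycles, schedule) model,
    density_modify = function(reflections, model) {
      src <- if (!is.null(model) && nrow(model$atoms)) model else reference
      map_from_model(src, grid_spacing = 1.0, atom_width_B = 10)
    },
    build_protein = function(map, reflections, sequence, model, seeds, n_cycles) {
      if (builder_rmsd > 0)
        perturb_model(reference, builder_rmsd, seed = seed + env$cycle)
      else reference
    },
    build_nucleic = function(map, reflections, sequence, model, n_cycles) model,
    rebuild_side_chain = function(model, residue_key) model,
    score_residues = function(model, map) make_scores(model, seed = seed),
    on_cycle_start = function(i) env$cycle <- as.integer(i))
}

#' Write a complete synthetic fixture set
#'
#' Generates a reference model, a perturbed/depleted starting model, a
#' synthetic map, calculated amplitudes with free flags and per-residue
#' scores, and writes them to a directory in the standard formats.
#'
#' @param dir Output directory (created if needed).
#' @param preset `"helix"`, `"two-chain"`, `"decoy"` or `"trajectory"`.
#' @param seed Integer seed.
#' @return Invisibly, the list of written paths.
#' @export
write_scenario <- function(dir, preset = c("helix", "two-chain", "decoy",
                                           "trajectory"), seed = 1) {
  preset <- match.arg(preset)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cell <- unit_cell(24, 24, 30)
  ref <- make_helix_model(12, cell, seed = seed)
  if (preset == "two-chain") {
    second <- make_helix_model(8, cell, seed = seed + 1, chain = "B")
    shift <- orthogonalize(cell, c(0.3, 0.3, 0)) - orthogonalize(cell, c(0, 0, 0))
    ref <- append_residues(ref, translate_model(second, shift)$atoms)
  }
  start <- switch(preset,
    helix = perturb_model(ref, 0.3, seed = seed),
    `two-chain` = perturb_model(delete_residues(ref, 0.25, seed), 0.3, seed),
    decoy = perturb_model(ref, 2.5, seed = seed),
    trajectory = ref)
  rs <- structure_factors(ref, 2.0)
  rs$data$sigf <- 0.05 * rs$data$fobs
  rs <- generate_free_flags(rs, 0.05, seed)
  scores <- make_scores(ref, seed = seed)
  paths <- list(
    reference = file.path(dir, "reference.cif"),
    model = file.path(dir, "model.cif"),
    reflections = file.path(dir, "reflections.cif"),
    map = file.path(dir, "map.ccp4"),
    scores = file.path(dir, "scores.json"),
    config = file.path(dir, "config.json"))
  write_structure(ref, paths$reference)
  write_structure(start, paths$model)
  write_reflections(rs, paths$reflections)
  write_map(map_from_model(ref, grid_spacing = 0.8, atom_width_B = 10),
            paths$map)
  write_scores(scores, paths$scores)
  jsonlite::write_json(unclass(pipeline_config()), paths$config,
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
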