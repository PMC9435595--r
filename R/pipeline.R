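#' Pipeline configuration
#'
#' Defaults encode the published schedule of the automated building
#' pipeline: up to 25 cycles with an automatic stop after 4 cycles
#' without an R_free improvement; 3 building-engine cycles in the first
#' iteration then 2; 3 nucleic-acid building cycles; 10 refinement
#' cycles after building / dummy atoms / waters and 5 after pruning and
#' the final side-chain rebuild; 12 shift-field cycles with the
#' resolution schedule running linearly from 6 to 3 angstroms; a 2
#' angstrom resolution cap on the building map; experimental phases
#' dropped once R_work reaches 0.35; waters attempted once R_work is
#' below 0.40; the final rebuild gated at d_min better than 2.5
#' angstroms and R_work better than 0.30; residue/side-chain pruning
#' skipped when the data do not extend beyond 2.3 angstroms.
#'
#' @param ... Named overrides of the defaults listed above.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    max_cycles = 25L,
    stop_after_no_improvement = 4L,
    buccaneer_cycles_first = 3L,
    buccaneer_cycles_later = 2L,
    nautilus_cycles = 3L,
    refmac_cycles_building = 10L,
    refmac_cycles_pruning = 5L,
    sheetbend_cycles = 12L,
    sheetbend_resolution_from = 6.0,
    sheetbend_resolution_to = 3.0,
    build_map_dmin_cap = 2.0,
    phases_off_rwork = 0.35,
    water_rwork_threshold = 0.40,
    rebuild_dmin = 2.5,
    rebuild_rwork = 0.30,
    prune_skip_dmin = 2.3,
    prune_chain_len = 20L,
    prune_chain_factor = 0.2,
    prune_residue_factor = 0.5,
    prune_cap = 0.2,
    rebuild_sc_factor = 0.25,
    rebuild_mc_factor = 0.25,
    dummy_threshold_sigma = 2.0,
    water_threshold_sigma = 2.0)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$max_cycles >= 1, cfg$stop_after_no_improvement >= 1)
  structure(cfg, class = "pipeline_config")
}

#' Backend suite contract
#'
#' The cycle engine orchestrates external building and refinement
#' programs through this contract; the engine never inspects backend
#' internals. Bundled implementations are scripted mocks and a toy
#' suite (see [scripted_backends()] and [toy_backends()]); adapters for
#' real programs can implement the same contract.
#'
#' @param refine `function(model, reflections, n_cycles, use_phases)`
#'   returning `list(model, r_work, r_free)` (optionally `map`).
#' @param shift_field_refine `function(model, reflections, n_cycles,
#'   schedule)` returning a model.
#' @param density_modify `function(reflections, model)` returning a
#'   [density_grid()] (or `NULL` to skip density-based steps).
#' @param build_protein `function(map, reflections, sequence, model,
#'   seeds, n_cycles)` returning a model.
#' @param build_nucleic `function(map, reflections, sequence, model,
#'   n_cycles)` returning a model.
#' @param rebuild_side_chain `function(model, residue_key)` returning a
#'   model.
#' @param score_residues `function(model, map)` returning a
#'   [residue_scores()].
#' @param on_cycle_start Optional `function(cycle_index)` notification.
#' @return Object of class `backend_suite`.
#' @export
backend_suite <- function(refine, shift_field_refine, density_modify,
                          build_protein, build_nucleic, rebuild_side_chain,
                          score_residues, on_cycle_start = NULL) {
  suite <- list(refine = refine, shift_field_refine = shift_field_refine,
                density_modify = density_modify, build_protein = build_protein,
                build_nucleic = build_nucleic,
                rebuild_side_chain = rebuild_side_chain,
                score_residues = score_residues,
                on_cycle_start = on_cycle_start)
  for (nm in setdiff(names(suite), "on_cycle_start"))
    if (!is.function(suite[[nm]])) stop("backend '", nm, "' must be a function")
  structure(suite, class = "backend_suite")
}

step_call <- function(backends, name, ...) {
  tryCatch(backends[[name]](...),
           error = function(e) stop("backend step '", name, "' failed: ",
                                    conditionMessage(e), call. = FALSE))
}

#' Initialize a pipeline run
#'
#' When a starting model is given it is first refined with shift-field
#' refinement (12 cycles, resolution schedule 6 to 3 angstroms) followed
#' by 10 cycles of conventional refinement, and the baseline R factors
#' are recorded. Seed residues for the building engine's finding step
#' are selected from the starting model once, here.
#'
#' @param starting_model An [structure_model()] or `NULL`.
#' @param reflections Observed [reflection_set()] with valid free flags.
#' @param config A [pipeline_config()].
#' @param backends A [backend_suite()].
#' @param sequence Named character vector of input sequences (one-letter
#'   codes); nucleic building runs only when a nucleic sequence is
#'   present.
#' @param phases_provided Whether experimental phases accompany the data.
#' @return Object of class `pipeline_state`.
#' @export
initialize_pipeline <- function(starting_model, reflections, config, backends,
                                sequence = character(0), phases_provided = FALSE) {
  if (!validate_free_flags(reflections))
    stop("reflections do not carry a valid free-R flag set")
  state <- structure(list(
    model = starting_model, map = NULL, reflections = reflections,
    sequence = sequence, config = config,
    phases_provided = phases_provided, min_rwork_seen = Inf,
    last_r_work = NA_real_, last_r_free = Inf,
    best = list(r_free = Inf, cycle = NA_integer_, model = NULL,
                r_work = NA_real_),
    no_improve = 0L, cycle = 0L, history = list(),
    seeds = character(0), start_model = starting_model),
    class = "pipeline_state")
  if (!is.null(starting_model) && nrow(starting_model$atoms)) {
    schedule <- seq(config$sheetbend_resolution_from,
                    config$sheetbend_resolution_to,
                    length.out = config$sheetbend_cycles)
    m <- step_call(backends, "shift_field_refine", starting_model, reflections,
                   config$sheetbend_cycles, schedule)
    res <- step_call(backends, "refine", m, reflections,
                     config$refmac_cycles_building,
                     use_experimental_phases(state))
    state$model <- res$model
    state$last_r_work <- res$r_work
    state$last_r_free <- res$r_free
    state$min_rwork_seen <- min(state$min_rwork_seen, res$r_work)
    state$start_model <- res$model
    sc <- tryCatch(step_call(backends, "score_residues", res$model, NULL),
                   error = function(e) NULL)
    if (!is.null(sc) && any(!is.na(sc$llk)))
      state$seeds <- select_seed_residues(res$model, sc)
  } else {
    state$model <- structure_model(reflections$cell, "P 1")
  }
  state
}

#' Should the pipeline stop?
#'
#' True when R_free has not improved over its previous best for
#' `stop_after_no_improvement` cycles, or the cycle cap is reached.
#'
#' @param state A `pipeline_state`.
#' @param config A [pipeline_config()] (defaults to the state's own).
#' @export
should_stop <- function(state, config = state$config) {
  state$no_improve >= config$stop_after_no_improvement ||
    state$cycle >= config$max_cycles
}

#' Strict R_free acceptance test
#'
#' @param candidate_r_free,reference_r_free Finite R_free values.
#' @return `TRUE` iff the candidate is strictly better (smaller).
#' @export
accept_if_improved <- function(candidate_r_free, reference_r_free) {
  is.finite(candidate_r_free) && candidate_r_free < reference_r_free
}

#' Latching experimental-phase switch
#'
#' Experimental phases are used in refinement until R_work first
#' reaches the configured threshold (default 0.35); from then on they
#' stay off even if R_work rises again.
#'
#' @param state A `pipeline_state`.
#' @param config A [pipeline_config()].
#' @return `TRUE` while phases should be used.
#' @export
use_experimental_phases <- function(state, config = state$config) {
  state$phases_provided && state$min_rwork_seen > config$phases_off_rwork
}

record_refine <- function(state, res) {
  state$last_r_work <- res$r_work
  state$last_r_free <- res$r_free
  state$min_rwork_seen <- min(state$min_rwork_seen, res$r_work)
  state
}

#' Run one pipeline cycle
#'
#' Executes the seven steps in order: (i) protein chain, residue and
#' side-chain pruning; (ii) density modification; (iii) dummy-atom
#' addition with R_free-gated acceptance; (iv) protein building;
#' (v) protein-chain pruning; (vi) nucleic-acid building; (vii) water
#' addition with R_free-gated acceptance. Appends a cycle record and
#' updates the best-model bookkeeping and the stop counter.
#'
#' @param state A `pipeline_state` from [initialize_pipeline()].
#' @param backends A [backend_suite()].
#' @param config A [pipeline_config()] (defaults to the state's own).
#' @return The updated state.
#' @export
run_cycle <- function(state, backends, config = state$config) {
  state$cycle <- state$cycle + 1L
  cyc <- state$cycle
  if (is.function(backends$on_cycle_start)) backends$on_cycle_start(cyc)
  steps <- list()
  log_step <- function(name, ...) {
    steps[[length(steps) + 1]] <<- c(list(step = name), list(...))
  }
  d_min <- state$reflections$d_min

  # (i) pruning at the start of the cycle
  if (!is.null(state$model) && any(state$model$atoms$category == "protein")) {
    scores <- step_call(backends, "score_residues", state$model, state$map)
    pc <- prune_chains(state$model, scores, config$prune_chain_len,
                       config$prune_chain_factor)
    pr <- prune_residues_and_sidechains(pc$model, scores, cyc, d_min,
                                        config$prune_residue_factor,
                                        config$prune_cap)
    n_removed <- length(pc$removed) + length(pr$removed_residues) +
      length(pr$removed_sidechains)
    state$model <- pr$model
    if (n_removed > 0) {
      res <- step_call(backends, "refine", state$model, state$reflections,
                       config$refmac_cycles_pruning,
                       use_experimental_phases(state, config))
      state$model <- res$model
      state <- record_refine(state, res)
    }
    log_step("prune", removed_chains = length(pc$removed),
             removed_residues = length(pr$removed_residues),
             removed_sidechains = length(pr$removed_sidechains),
             refined = n_removed > 0)
  }

  # (ii) density modification
  state$map <- step_call(backends, "density_modify", state$reflections,
                         state$model)
  log_step("density_modification", produced_map = !is.null(state$map))
  build_map <- state$map

  # (iii) dummy-atom addition, accepted only on R_free improvement
  if (!is.null(state$map) && inherits(state$map, "density_grid") &&
      nrow(state$model$atoms) > 0) {
    dummies <- flood_dummy_atoms(state$map, state$model,
                                 threshold_sigma = config$dummy_threshold_sigma)
    if (nrow(dummies) > 0) {
      hybrid <- append_residues(state$model, data.frame(
        chain = "Z", seqnum = seq_len(nrow(dummies)), icode = "",
        resname = "DUM", atom = "O", element = "O",
        x = dummies[, 1], y = dummies[, 2], z = dummies[, 3], occ = 1, b = 30))
      res <- step_call(backends, "refine", hybrid, state$reflections,
                       config$refmac_cycles_building,
                       use_experimental_phases(state, config))
      accepted <- accept_if_improved(res$r_free, state$last_r_free)
      if (accepted) {
        state$model <- strip_categories(res$model, c("dummy", "water"))
        state <- record_refine(state, res)
        if (!is.null(res$map)) build_map <- res$map
      }
      log_step("dummy_atoms", added = nrow(dummies), accepted = accepted)
    } else {
      log_step("dummy_atoms", added = 0L, accepted = FALSE)
    }
  }
  # dummies and waters are only used for phase improvement; never let
  # them leak into the building model
  state$model <- strip_categories(state$model, c("dummy", "water"))

  # (iv) protein building
  n_bucc <- if (cyc == 1) config$buccaneer_cycles_first else config$buccaneer_cycles_later
  build_refl <- filter_reflections_for_building(state$reflections,
                                                config$build_map_dmin_cap)
  m <- step_call(backends, "build_protein", build_map, build_refl,
                 state$sequence, state$model, state$seeds, n_bucc)
  res <- step_call(backends, "refine", m, state$reflections,
                   config$refmac_cycles_building,
                   use_experimental_phases(state, config))
  state$model <- res$model
  state <- record_refine(state, res)
  log_step("build_protein", n_cycles = n_bucc,
           residues = n_residues(state$model))

  # (v) protein-chain pruning after building
  if (any(state$model$atoms$category == "protein")) {
    scores <- step_call(backends, "score_residues", state$model, build_map)
    pc <- prune_chains(state$model, scores, config$prune_chain_len,
                       config$prune_chain_factor)
    state$model <- pc$model
    if (length(pc$removed)) {
      res <- step_call(backends, "refine", state$model, state$reflections,
                       config$refmac_cycles_pruning,
                       use_experimental_phases(state, config))
      state$model <- res$model
      state <- record_refine(state, res)
    }
    log_step("prune_chains", removed_chains = length(pc$removed),
             refined = length(pc$removed) > 0)
  }

  # (vi) nucleic-acid building (skipped when no nucleic sequence)
  if (has_nucleic_sequence(state$sequence)) {
    m <- step_call(backends, "build_nucleic", build_map, build_refl,
                   state$sequence, state$model, config$nautilus_cycles)
    res <- step_call(backends, "refine", m, state$reflections,
                     config$refmac_cycles_building,
                     use_experimental_phases(state, config))
    state$model <- res$model
    state <- record_refine(state, res)
    log_step("build_nucleic", n_cycles = config$nautilus_cycles)
  }

  # (vii) water addition, accepted only on R_free improvement
  if (isTRUE(state$last_r_work < config$water_rwork_threshold) &&
      inherits(state$map, "density_grid") && nrow(state$model$atoms) > 0) {
    waters <- pick_waters(state$map, state$model,
                          threshold_sigma = config$water_threshold_sigma)
    if (nrow(waters) > 0) {
      withw <- append_residues(state$model, data.frame(
        chain = "S", seqnum = seq_len(nrow(waters)), icode = "",
        resname = "HOH", atom = "O", element = "O",
        x = waters[, 1], y = waters[, 2], z = waters[, 3], occ = 1, b = 30))
      res <- step_call(backends, "refine", withw, state$reflections,
                       config$refmac_cycles_building,
                       use_experimental_phases(state, config))
      accepted <- accept_if_improved(res$r_free, state$last_r_free)
      if (accepted) {
        state$model <- res$model
        state <- record_refine(state, res)
      }
      log_step("waters", added = nrow(waters), accepted = accepted)
    } else {
      log_step("waters", added = 0L, accepted = FALSE)
    }
  }

  # close the cycle record; the end-of-cycle R_free is the last accepted
  # refinement of the cycle
  rec <- list(cycle = cyc, r_work = state$last_r_work,
              r_free = state$last_r_free,
              n_residues = n_residues(state$model), steps = steps)
  state$history[[cyc]] <- rec
  if (accept_if_improved(state$last_r_free, state$best$r_free)) {
    state$best <- list(r_free = state$last_r_free, cycle = cyc,
                       model = state$model, r_work = state$last_r_work)
    state$no_improve <- 0L
  } else {
    state$no_improve <- state$no_improve + 1L
  }
  state
}

has_nucleic_sequence <- function(sequence) {
  if (!length(sequence)) return(FALSE)
  any(vapply(sequence, function(s) {
    letters <- unique(strsplit(toupper(s), "")[[1]])
    length(letters) > 0 && all(letters %in% c("A", "C", "G", "T", "U"))
  }, logical(1)))
}

#' Finalize a pipeline run
#'
#' Selects the model from the cycle with the lowest R_free (earliest on
#' ties). If the resolution is better than 2.5 angstroms and that
#' model's R_work is better than 0.30, side chains that are missing or
#' predicted incorrect are rebuilt and re-refined, accepted only on an
#' R_free improvement.
#'
#' @param state A `pipeline_state` with at least one completed cycle.
#' @param backends A [backend_suite()].
#' @param config A [pipeline_config()] (defaults to the state's own).
#' @return List with `model`, `r_work`, `r_free`, `best_cycle`,
#'   `rebuild` (attempted / accepted) and the full `report`.
#' @export
finalize_pipeline <- function(state, backends, config = state$config) {
  if (!length(state$history)) stop("no completed cycles to finalize")
  rfrees <- vapply(state$history, `[[`, numeric(1), "r_free")
  best_cycle <- which.min(rfrees)   # earliest minimum
  model <- state$best$model
  r_work <- state$history[[best_cycle]]$r_work
  r_free <- state$history[[best_cycle]]$r_free
  d_min <- state$reflections$d_min
  rebuild <- list(attempted = FALSE, accepted = FALSE, n_selected = 0L)
  if (d_min < config$rebuild_dmin && isTRUE(r_work < config$rebuild_rwork) &&
      !is.null(model) && any(model$atoms$category == "protein")) {
    scores <- step_call(backends, "score_residues", model, state$map)
    keys <- select_sidechain_rebuilds(model, scores, config$rebuild_sc_factor,
                                      config$rebuild_mc_factor)
    rebuild$attempted <- TRUE
    rebuild$n_selected <- length(keys)
    if (length(keys)) {
      m2 <- model
      for (k in keys) m2 <- step_call(backends, "rebuild_side_chain", m2, k)
      res <- step_call(backends, "refine", m2, state$reflections,
                       config$refmac_cycles_pruning,
                       use_experimental_phases(state, config))
      if (accept_if_improved(res$r_free, r_free)) {
        model <- res$model
        r_work <- res$r_work
        r_free <- res$r_free
        rebuild$accepted <- TRUE
      }
    }
  }
  report <- list(
    n_cycles = state$cycle,
    best_cycle = best_cycle,
    final_r_work = r_work,
    final_r_free = r_free,
    rebuild = rebuild,
    cycles = state$history)
  list(model = model, r_work = r_work, r_free = r_free,
       best_cycle = best_cycle, rebuild = rebuild, report = report)
}

#' Run the full pipeline
#'
#' Convenience driver: [initialize_pipeline()], then [run_cycle()] until
#' [should_stop()], then [finalize_pipeline()]. Optionally writes
#' `report.json` and the final model (`final.cif`) to a directory.
#'
#' @inheritParams initialize_pipeline
#' @param out_dir Output directory for `report.json` / `final.cif`
#'   (created if needed), or `NULL` to skip writing.
#' @return The [finalize_pipeline()] result.
#' @export
run_pipeline <- function(reflections, backends, config = pipeline_config(),
                         starting_model = NULL, sequence = character(0),
                         phases_provided = FALSE, out_dir = NULL) {
  state <- initialize_pipeline(starting_model, reflections, config, backends,
                               sequence, phases_provided)
  repeat {
    state <- run_cycle(state, backends, config)
    if (should_stop(state, config)) break
  }
  out <- finalize_pipeline(state, backends, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pipeline_report(out$report, file.path(out_dir, "report.json"))
    if (!is.null(out$model))
      write_structure(out$model, file.path(out_dir, "final.cif"))
  }
  out
}

#' Write a pipeline report as JSON
#'
#' @param report Report list from [finalize_pipeline()].
#' @param path Output path.
#' @export
write_pipeline_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA headers in ", path)
  ends <- c(hdr[-1] - 1, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    paste(lines[(hdr[i] + 1):ends[i]], collapse = "")
  }, "")
  names(seqs) <- sub("^>\\s*", "", lines[hdr])
  gsub("[[:space:]]", "", seqs)
}
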