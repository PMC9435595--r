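#' Per-residue correctness and likelihood scores
#'
#' Scores are inputs to the pruning and rebuild-selection rules: a
#' main-chain correctness in `[0, 1]` for every scored protein residue,
#' an optional side-chain correctness in `[0, 1]` and an optional
#' log-likelihood (LLK) density-fit value. The networks / engines that
#' produce them are external; this container only keys them to residues.
#'
#' @param df Data frame with columns `chain`, `seqnum`, `icode`
#'   (optional), `main_chain` and optionally `side_chain`, `llk`.
#' @return Object of class `residue_scores` (a data frame with a `key`
#'   column `"chain|seqnum|icode"`).
#' @export
residue_scores <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(df$icode)) df$icode <- ""
  df$icode[is.na(df$icode)] <- ""
  if (is.null(df$side_chain)) df$side_chain <- NA_real_
  if (is.null(df$llk)) df$llk <- NA_real_
  if (any(df$main_chain < 0 | df$main_chain > 1, na.rm = TRUE))
    stop("main-chain correctness must lie in [0, 1]")
  if (any(df$side_chain < 0 | df$side_chain > 1, na.rm = TRUE))
    stop("side-chain correctness must lie in [0, 1]")
  df$seqnum <- as.integer(df$seqnum)
  df$key <- paste(df$chain, df$seqnum, df$icode, sep = "|")
  if (anyDuplicated(df$key)) stop("duplicate residue in scores")
  class(df) <- c("residue_scores", "data.frame")
  df
}

#' Read residue scores from JSON
#'
#' Expects an array of records such as
#' `{"chain": "A", "seqnum": 17, "icode": "", "main_chain": 0.83,
#' "side_chain": 0.41, "llk": 12.7}`.
#'
#' @param path JSON file path.
#' @return A [residue_scores()].
#' @export
read_scores <- function(path) {
  residue_scores(jsonlite::fromJSON(path))
}

#' Write residue scores to JSON
#'
#' @param scores A [residue_scores()].
#' @param path Output path.
#' @export
write_scores <- function(scores, path) {
  df <- as.data.frame(scores)[, c("chain", "seqnum", "icode", "main_chain",
                                  "side_chain", "llk")]
  jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Median of a score field over the whole structure
#'
#' @param scores A [residue_scores()].
#' @param field `"main_chain"`, `"side_chain"` or `"llk"`.
#' @return The median over scored residues (mean of the two middle
#'   values for an even count).
#' @export
median_score <- function(scores, field = "main_chain") {
  v <- scores[[field]]
  v <- v[!is.na(v)]
  if (!length(v)) stop("no scored residues carry the field '", field, "'")
  stats::median(v)
}

scores_for_model <- function(model, scores, category = "protein") {
  rt <- residue_table(model)
  rt <- rt[rt$category == category, , drop = FALSE]
  m <- match(rt$key, scores$key)
  cbind(rt, scores[m, c("main_chain", "side_chain", "llk"), drop = FALSE])
}

#' Prune low-confidence short protein chains
#'
#' Protein chains of up to `max_chain_len` residues are removed when the
#' mean main-chain correctness of the chain is less than `factor` times
#' the median main-chain correctness of the whole structure.
#'
#' @param model An [structure_model()].
#' @param scores A [residue_scores()] covering the model's protein
#'   residues.
#' @param max_chain_len Longest chain length eligible for removal
#'   (default 20).
#' @param factor Threshold factor applied to the structure median
#'   (default 0.2).
#' @return List with the pruned `model` and `removed` chain ids.
#' @export
prune_chains <- function(model, scores, max_chain_len = 20, factor = 0.2) {
  sc <- scores_for_model(model, scores)
  if (!nrow(sc)) return(list(model = model, removed = character(0)))
  med <- stats::median(sc$main_chain[!is.na(sc$main_chain)])
  removed <- character(0)
  for (ch in unique(sc$chain)) {
    rows <- sc[sc$chain == ch, ]
    if (nrow(rows) <= max_chain_len &&
        mean(rows$main_chain, na.rm = TRUE) < factor * med)
      removed <- c(removed, ch)
  }
  if (length(removed)) {
    keep <- !(model$atoms$chain %in% removed & model$atoms$category == "protein")
    model <- structure_model(model$cell, model$spacegroup,
                             model$atoms[keep, , drop = FALSE])
  }
  list(model = model, removed = removed)
}

#' Prune low-confidence residues and side chains
#'
#' Residues whose main-chain correctness is below `factor` times the
#' structure median are removed, and side chains (atoms beyond C-beta)
#' whose side-chain correctness is below `factor` times the side-chain
#' median are truncated. Each removal class is capped at `cap` times its
#' eligible population (all scored residues, respectively all residues
#' with side chains), removing the lowest scores first with ties broken
#' by (chain, seqnum) order. The step is skipped entirely in the first
#' cycle and when the data do not extend beyond 2.3 angstrom resolution.
#'
#' @param model An [structure_model()].
#' @param scores A [residue_scores()].
#' @param cycle_index 1-based pipeline cycle number.
#' @param d_min Data resolution in angstroms.
#' @param factor Threshold factor on the medians (default 0.5).
#' @param cap Maximum fraction pruned per class per stage (default 0.2).
#' @return List with `model`, `removed_residues` (keys) and
#'   `removed_sidechains` (keys).
#' @export
prune_residues_and_sidechains <- function(model, scores, cycle_index, d_min,
                                          factor = 0.5, cap = 0.2) {
  noop <- list(model = model, removed_residues = character(0),
               removed_sidechains = character(0))
  if (cycle_index == 1 || d_min > 2.3) return(noop)
  sc <- scores_for_model(model, scores)
  if (!nrow(sc)) return(noop)

  ord <- order(sc$chain, sc$seqnum, sc$icode)

  pick_victims <- function(values, keys) {
    have <- !is.na(values)
    if (!any(have)) return(character(0))
    med <- stats::median(values[have])
    eligible_pop <- sum(have)
    below <- have & values < factor * med
    max_n <- floor(cap * eligible_pop)
    idx <- which(below)
    if (!length(idx) || max_n == 0) return(character(0))
    idx <- idx[order(values[idx], match(idx, ord))]
    keys[idx[seq_len(min(length(idx), max_n))]]
  }

  rm_res <- pick_victims(sc$main_chain, sc$key)
  has_sc <- !sc$resname %in% c("GLY", "ALA")
  sc_vals <- ifelse(has_sc, sc$side_chain, NA_real_)
  rm_side <- pick_victims(sc_vals, sc$key)

  model2 <- subset_residues(model, rm_res, drop = TRUE)
  if (length(rm_side)) {
    a <- model2$atoms
    key <- residue_key(a)
    beyond_cb <- key %in% rm_side &
      !a$atom %in% c("N", "CA", "C", "O", "CB", "OXT")
    model2 <- structure_model(model2$cell, model2$spacegroup,
                              a[!beyond_cb, , drop = FALSE])
  }
  list(model = model2, removed_residues = rm_res,
       removed_sidechains = setdiff(rm_side, rm_res))
}

#' Select side chains to rebuild
#'
#' Chooses protein residues whose side chain is either predicted to be
#' incorrect (side-chain correctness below `sc_factor` times the
#' side-chain median while the main-chain correctness exceeds
#' `mc_factor` times the main-chain median) or missing atoms relative to
#' the canonical residue dictionary. GLY and ALA have no side chain
#' beyond C-beta and are never selected.
#'
#' @param model An [structure_model()].
#' @param scores A [residue_scores()].
#' @param sc_factor,mc_factor Threshold factors (default 0.25 each).
#' @return Character vector of residue keys.
#' @export
select_sidechain_rebuilds <- function(model, scores, sc_factor = 0.25,
                                      mc_factor = 0.25) {
  sc <- scores_for_model(model, scores)
  sc <- sc[!sc$resname %in% c("GLY", "ALA"), , drop = FALSE]
  if (!nrow(sc)) return(character(0))
  med_sc <- if (any(!is.na(sc$side_chain)))
    stats::median(sc$side_chain[!is.na(sc$side_chain)]) else NA_real_
  med_mc <- stats::median(sc$main_chain[!is.na(sc$main_chain)])
  predicted_bad <- !is.na(sc$side_chain) & !is.na(sc$main_chain) &
    sc$side_chain < sc_factor * med_sc & sc$main_chain > mc_factor * med_mc
  a <- model$atoms
  key <- residue_key(a)
  missing <- vapply(seq_len(nrow(sc)), function(i) {
    expect <- .sidechain_atoms[[sc$resname[i]]]
    if (is.null(expect) || !length(expect)) return(FALSE)
    have <- a$atom[key == sc$key[i]]
    !all(expect %in% have)
  }, logical(1))
  sc$key[predicted_bad | missing]
}

#' Select seed residues for the building engine's finding step
#'
#' Residues with LLK scores lower than two standard deviations below the
#' mean are dropped; of the survivors, in model order, every third
#' residue starting at the first is kept.
#'
#' @param model An [structure_model()].
#' @param scores A [residue_scores()] with `llk` present.
#' @return Character vector of residue keys.
#' @export
select_seed_residues <- function(model, scores) {
  sc <- scores_for_model(model, scores)
  sc <- sc[!is.na(sc$llk), , drop = FALSE]
  if (!nrow(sc)) return(character(0))
  mu <- mean(sc$llk)
  sdv <- stats::sd(sc$llk)   # sample (n-1) standard deviation
  if (is.na(sdv)) sdv <- 0
  surv <- sc[sc$llk >= mu - 2 * sdv, , drop = FALSE]
  surv$key[seq(1, nrow(surv), by = 3)]
}
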