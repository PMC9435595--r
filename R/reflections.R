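#' Reflection set
#'
#' Miller-indexed structure-factor amplitudes with uncertainties, free-R
#' flags (CCP4 convention: flag value 0 marks the free / cross-validation
#' set) and optional phases (degrees) with figures of merit. `d_min` is
#' always recomputed from the cell and the indices present.
#'
#' @param cell A [unit_cell()].
#' @param data Data frame with columns `h`, `k`, `l`, `fobs` and
#'   optionally `sigf`, `free`, `phi`, `fom`.
#' @return Object of class `reflection_set` with elements `cell`, `data`
#'   (with a computed `d` column) and `d_min`.
#' @export
reflection_set <- function(cell, data) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  for (colname in c("h", "k", "l")) data[[colname]] <- as.integer(data[[colname]])
  key <- paste(data$h, data$k, data$l)
  if (anyDuplicated(key))
    stop("duplicate Miller index: (", key[duplicated(key)][1], ")")
  if (any(data$fobs < 0, na.rm = TRUE))
    stop("negative structure-factor amplitude")
  if (is.null(data$sigf)) data$sigf <- NA_real_
  if (is.null(data$free)) data$free <- NA_integer_
  if (is.null(data$phi)) data$phi <- NA_real_
  if (is.null(data$fom)) data$fom <- NA_real_
  data$d <- d_spacing(cell, as.matrix(data[, c("h", "k", "l")]))
  structure(list(cell = cell, data = data,
                 d_min = if (nrow(data)) min(data$d) else Inf),
            class = "reflection_set")
}

#' @export
print.reflection_set <- function(x, ...) {
  nfree <- sum(x$data$free == 0, na.rm = TRUE)
  cat(sprintf("<reflection_set> %d reflections, d_min %.3f A, %d free\n",
              nrow(x$data), x$d_min, nfree))
  invisible(x)
}

#' Read reflections from a structure-factor mmCIF subset
#'
#' Expects a `_refln` loop with `index_h/k/l` and `F_meas_au` columns;
#' `F_meas_sigma_au`, `pdbx_r_free_flag` (integer; 0 = free),
#' `phase_calc` and `fom` are carried when present. The unit cell is
#' taken from the `_cell` items.
#'
#' @param path File path.
#' @return A [reflection_set()].
#' @export
read_reflections <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  p <- cif_parse(path)
  need <- c("_cell.length_a", "_cell.length_b", "_cell.length_c",
            "_cell.angle_alpha", "_cell.angle_beta", "_cell.angle_gamma")
  vals <- suppressWarnings(as.numeric(vapply(need, function(t) cif_item(p, t), "")))
  if (any(is.na(vals))) stop("missing unit cell (_cell.*) in ", path)
  cell <- unit_cell(vals[1], vals[2], vals[3], vals[4], vals[5], vals[6])
  rf <- p$loops[["_refln"]]
  if (is.null(rf)) stop("missing _refln loop in ", path)
  col <- function(tag) {
    full <- paste0("_refln.", tag)
    if (full %in% names(rf)) rf[[full]] else NULL
  }
  if (is.null(col("index_h")) || is.null(col("F_meas_au")))
    stop("reflection file must contain _refln.index_h/k/l and _refln.F_meas_au")
  numcol <- function(tag) {
    v <- col(tag)
    if (is.null(v)) return(NULL)
    suppressWarnings(as.numeric(ifelse(v %in% c("?", "."), NA, v)))
  }
  data <- data.frame(h = as.integer(col("index_h")),
                     k = as.integer(col("index_k")),
                     l = as.integer(col("index_l")),
                     fobs = numcol("F_meas_au"))
  if (!is.null(numcol("F_meas_sigma_au"))) data$sigf <- numcol("F_meas_sigma_au")
  if (!is.null(numcol("pdbx_r_free_flag"))) data$free <- as.integer(numcol("pdbx_r_free_flag"))
  if (!is.null(numcol("phase_calc"))) data$phi <- numcol("phase_calc")
  if (!is.null(numcol("fom"))) data$fom <- numcol("fom")
  reflection_set(cell, data)
}

#' Write reflections as a structure-factor mmCIF subset
#'
#' @param rs A [reflection_set()].
#' @param path Output path.
#' @export
write_reflections <- function(rs, path) {
  c_ <- rs$cell
  fmt <- function(v) ifelse(is.na(v), "?", sprintf("%.6f", v))
  lines <- c(
    "data_reflections",
    sprintf("_cell.length_a    %.6f", c_$a),
    sprintf("_cell.length_b    %.6f", c_$b),
    sprintf("_cell.length_c    %.6f", c_$c),
    sprintf("_cell.angle_alpha %.6f", c_$alpha),
    sprintf("_cell.angle_beta  %.6f", c_$beta),
    sprintf("_cell.angle_gamma %.6f", c_$gamma),
    "loop_",
    "_refln.index_h", "_refln.index_k", "_refln.index_l",
    "_refln.F_meas_au", "_refln.F_meas_sigma_au", "_refln.pdbx_r_free_flag",
    "_refln.phase_calc", "_refln.fom",
    sprintf("%d %d %d %s %s %s %s %s",
            rs$data$h, rs$data$k, rs$data$l, fmt(rs$data$fobs), fmt(rs$data$sigf),
            ifelse(is.na(rs$data$free), "?", as.character(rs$data$free)),
            fmt(rs$data$phi), fmt(rs$data$fom)))
  writeLines(lines, path)
  invisible(path)
}

#' Validate a free-R flag set
#'
#' A flag set is usable for cross-validation when some but at most half
#' of the reflections carry the free flag (value 0): the fraction f of
#' zero-valued flags must satisfy 0 < f <= 0.5.
#'
#' @param rs A [reflection_set()].
#' @return `TRUE` or `FALSE`.
#' @export
validate_free_flags <- function(rs) {
  flags <- rs$data$free
  if (!length(flags) || all(is.na(flags))) return(FALSE)
  f <- mean(flags == 0, na.rm = TRUE)
  f > 0 && f <= 0.5
}

#' Generate a fresh free-R flag set
#'
#' Assigns flag 0 (free) to a reproducible random subset of
#' `round(fraction * N)` reflections and flag 1 to the rest.
#'
#' @param rs A [reflection_set()].
#' @param fraction Free-set fraction, in (0, 0.5).
#' @param seed Integer seed; the same seed always yields the same flags.
#' @return The reflection set with its `free` column replaced.
#' @export
generate_free_flags <- function(rs, fraction = 0.05, seed = 1) {
  if (!(fraction > 0 && fraction < 0.5))
    stop("free fraction must lie in (0, 0.5)")
  n <- nrow(rs$data)
  nfree <- round(fraction * n)
  idx <- with_seed(seed, sample.int(n, nfree))
  rs$data$free <- rep(1L, n)
  rs$data$free[idx] <- 0L
  rs
}

#' Filter reflections for map calculation during building
#'
#' The map used for model building is computed without the free
#' (cross-validation) reflections and truncated to a 2 angstrom
#' resolution limit; data not extending that far are left untouched
#' apart from the free-set removal.
#'
#' @param rs A [reflection_set()] with free flags present.
#' @param d_cap Resolution cap in angstroms (default 2.0).
#' @return The filtered [reflection_set()].
#' @export
filter_reflections_for_building <- function(rs, d_cap = 2.0) {
  keep <- !(rs$data$free %in% 0L) & rs$data$d >= d_cap
  if (!any(keep))
    warning("no reflections remain after free-set and resolution filtering")
  reflection_set(rs$cell, rs$data[keep, setdiff(names(rs$data), "d"), drop = FALSE])
}

# RNG-isolated evaluation: runs expr under a temporary seed without
# disturbing the caller's random state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
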