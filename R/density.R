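# Single-Gaussian atomic form factors: one (a, b) pair per element,
# with a close to the electron count. Metrics in scope are correlations
# and ratios, which are insensitive to form-factor fidelity; a bundled
# 4-Gaussian table would add precision the use cases do not need.
.form_factors <- list(
  "H" = c(1, 20), "C" = c(6, 18), "N" = c(7, 15), "O" = c(8, 13),
  "P" = c(15, 12), "S" = c(16, 12), "SE" = c(34, 11), "FE" = c(26, 10),
  "ZN" = c(30, 10), "MG" = c(12, 12), "MN" = c(25, 10), "CA" = c(20, 11),
  "NA" = c(11, 12), "K" = c(19, 11), "CL" = c(17, 12), "X" = c(6, 15))

form_factor_ab <- function(element) {
  el <- toupper(element)
  out <- matrix(0, length(el), 2)
  for (i in seq_along(el)) {
    ab <- .form_factors[[el[i]]]
    if (is.null(ab)) ab <- .form_factors$X
    out[i, ] <- ab
  }
  out
}

#' Find density peaks
#'
#' A peak is a voxel strictly greater than all 26 neighbors (with
#' periodic wrap) whose height is at least `threshold_sigma` standard
#' deviations above the map mean. Positions are refined by per-axis
#' quadratic interpolation; the peak volume is the size of the
#' 6-connected voxel region above the threshold containing the peak,
#' times the voxel volume.
#'
#' @param grid A [density_grid()].
#' @param threshold_sigma Height cutoff in sigma units (default 2).
#' @return Data frame sorted by descending height with columns `x`,
#'   `y`, `z` (orthogonal angstroms), `value`, `height_sigma`,
#'   `volume` (cubic angstroms) and the voxel indices `i`, `j`, `k`.
#' @export
find_peaks <- function(grid, threshold_sigma = 2.0) {
  st <- grid_stats(grid)
  if (st$degenerate) stop("cannot search for peaks in a constant (sigma = 0) map")
  v <- grid$values
  d <- dim(v)
  thr <- st$mu + threshold_sigma * st$sigma
  shift_idx <- function(n, s) ((seq_len(n) - 1 + s) %% n) + 1
  localmax <- array(TRUE, d)
  for (du in -1:1) for (dv in -1:1) for (dw in -1:1) {
    if (du == 0 && dv == 0 && dw == 0) next
    nb <- v[shift_idx(d[1], du), shift_idx(d[2], dv), shift_idx(d[3], dw)]
    localmax <- localmax & (v > nb)
  }
  cand <- which(localmax & v >= thr, arr.ind = TRUE)
  if (!nrow(cand)) {
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      value = numeric(0), height_sigma = numeric(0),
                      volume = numeric(0), i = integer(0), j = integer(0),
                      k = integer(0)))
  }
  mask <- v >= thr
  comp_size <- flood_component_sizes(mask, cand)
  vv <- voxel_volume(grid)
  # quadratic interpolation along each axis
  interp <- function(fm, f0, fp) {
    den <- fm - 2 * f0 + fp
    off <- ifelse(abs(den) < 1e-12, 0, 0.5 * (fm - fp) / den)
    pmin(pmax(off, -0.5), 0.5)
  }
  pos_frac <- matrix(0, nrow(cand), 3)
  for (r in seq_len(nrow(cand))) {
    ijk <- cand[r, ]
    off <- numeric(3)
    for (ax in 1:3) {
      im <- ijk; ip <- ijk
      im[ax] <- ((ijk[ax] - 2) %% d[ax]) + 1
      ip[ax] <- (ijk[ax] %% d[ax]) + 1
      off[ax] <- interp(v[im[1], im[2], im[3]], v[ijk[1], ijk[2], ijk[3]],
                        v[ip[1], ip[2], ip[3]])
    }
    pos_frac[r, ] <- (ijk - 1 + off) / d
  }
  xyz <- orthogonalize(grid$cell, pos_frac)
  vals <- v[cand]
  out <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    value = vals, height_sigma = (vals - st$mu) / st$sigma,
                    volume = comp_size * vv,
                    i = cand[, 1], j = cand[, 2], k = cand[, 3])
  out <- out[order(-out$value, out$i, out$j, out$k), ]
  rownames(out) <- NULL
  out
}

# Size of the 6-connected TRUE region containing each seed voxel.
# Periodic neighbors; regions are labelled once and shared between
# seeds falling in the same component.
flood_component_sizes <- function(mask, seeds) {
  d <- dim(mask)
  lab <- array(0L, d)
  sizes <- integer(0)
  nextlab <- 0L
  nb_offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                      c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  out <- integer(nrow(seeds))
  for (r in seq_len(nrow(seeds))) {
    s <- seeds[r, ]
    if (lab[s[1], s[2], s[3]] > 0) {
      out[r] <- sizes[lab[s[1], s[2], s[3]]]
      next
    }
    nextlab <- nextlab + 1L
    queue <- matrix(s, ncol = 3)
    lab[s[1], s[2], s[3]] <- nextlab
    count <- 1L
    while (nrow(queue)) {
      cur <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      for (q in 1:6) {
        nbv <- cur + nb_offsets[q, ]
        nbv <- ((nbv - 1) %% d) + 1
        if (mask[nbv[1], nbv[2], nbv[3]] && lab[nbv[1], nbv[2], nbv[3]] == 0L) {
          lab[nbv[1], nbv[2], nbv[3]] <- nextlab
          count <- count + 1L
          queue <- rbind(queue, nbv)
        }
      }
    }
    sizes[nextlab] <- count
    out[r] <- count
  }
  out
}

#' Flood dummy atoms into a density map
#'
#' Dummy O atoms are placed into map peaks above `threshold_sigma` that
#' lie within `min_model_dist` to `max_model_dist` of the model
#' (symmetry-aware), accepting peaks greedily in descending height
#' order subject to a minimum pairwise separation between accepted
#' dummies. The atoms are used purely for phase improvement.
#'
#' @param grid A [density_grid()].
#' @param model A non-empty [structure_model()].
#' @param threshold_sigma Peak height cutoff in sigma units.
#' @param min_model_dist,max_model_dist Allowed distance band to the
#'   model in angstroms (default 1.9 to 10).
#' @param min_pair_dist Minimum separation between accepted dummy atoms
#'   in angstroms (default 1.4).
#' @param expand_symmetry Use symmetry-expanded distances (default).
#' @return Matrix of accepted positions (orthogonal angstroms), ordered
#'   by descending peak height.
#' @export
flood_dummy_atoms <- function(grid, model, threshold_sigma = 2.0,
                              min_model_dist = 1.9, max_model_dist = 10.0,
                              min_pair_dist = 1.4, expand_symmetry = TRUE) {
  if (!nrow(model$atoms)) stop("model has no atoms")
  peaks <- find_peaks(grid, threshold_sigma)
  if (!nrow(peaks)) return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("x", "y", "z"))))
  imgs <- symmetry_images(model, expand = expand_symmetry)
  pts <- as.matrix(peaks[, c("x", "y", "z")])
  dmodel <- min_dist_to_images(pts, imgs)
  ok <- dmodel >= min_model_dist & dmodel <= max_model_dist
  accepted <- matrix(numeric(0), 0, 3)
  for (r in which(ok)) {
    p <- pts[r, ]
    if (nrow(accepted)) {
      dmin <- min(sqrt(rowSums(sweep(accepted, 2, p)^2)))
      if (dmin < min_pair_dist) next
    }
    accepted <- rbind(accepted, p)
  }
  dimnames(accepted) <- list(NULL, c("x", "y", "z"))
  accepted
}

#' Pick water molecules from a density map
#'
#' Waters are built into peaks above `threshold_sigma` with connected
#' volumes below `max_volume`, provided the peak is further than
#' `min_any_dist` from all current atoms and within `max_hbond_dist` of
#' an N or O atom (waters count as O). The search runs `passes` times;
#' waters accepted in one pass join the model for the next, so
#' outer-shell waters hydrogen-bonded to earlier waters can be added.
#'
#' @param grid A [density_grid()].
#' @param model A non-empty [structure_model()].
#' @param threshold_sigma Peak height cutoff in sigma units (default 2).
#' @param max_volume Maximum connected peak volume in cubic angstroms
#'   (default 15).
#' @param min_any_dist Exclusion distance to any atom in angstroms
#'   (default 2.4).
#' @param max_hbond_dist Maximum distance to an N/O hydrogen-bond
#'   partner in angstroms (default 3.2).
#' @param passes Number of picking passes (default 3).
#' @param expand_symmetry Use symmetry-expanded distances (default).
#' @return Matrix of accepted water positions with a `pass` attribute
#'   recording the pass each water was accepted in.
#' @export
pick_waters <- function(grid, model, threshold_sigma = 2.0, max_volume = 15.0,
                        min_any_dist = 2.4, max_hbond_dist = 3.2, passes = 3,
                        expand_symmetry = TRUE) {
  if (!nrow(model$atoms)) stop("model has no atoms")
  peaks <- find_peaks(grid, threshold_sigma)
  peaks <- peaks[peaks$volume < max_volume, , drop = FALSE]
  accepted <- matrix(numeric(0), 0, 3, dimnames = list(NULL, c("x", "y", "z")))
  pass_of <- integer(0)
  work <- model
  for (pass in seq_len(passes)) {
    if (!nrow(peaks)) break
    all_imgs <- symmetry_images(work, expand = expand_symmetry)
    no_sel <- toupper(work$atoms$element) %in% c("N", "O")
    no_imgs <- symmetry_images(work, sel = no_sel, expand = expand_symmetry)
    pts <- as.matrix(peaks[, c("x", "y", "z")])
    d_any_start <- min_dist_to_images(pts, all_imgs)
    d_hb <- min_dist_to_images(pts, no_imgs)
    new_rows <- integer(0)
    for (r in seq_len(nrow(peaks))) {
      if (d_hb[r] > max_hbond_dist) next
      p <- pts[r, ]
      d_any <- d_any_start[r]
      if (nrow(accepted))
        d_any <- min(d_any, sqrt(rowSums(sweep(accepted, 2, p)^2)))
      if (d_any <= min_any_dist) next
      accepted <- rbind(accepted, p)
      pass_of <- c(pass_of, pass)
      new_rows <- c(new_rows, r)
    }
    if (length(new_rows)) {
      newpos <- as.matrix(peaks[new_rows, c("x", "y", "z"), drop = FALSE])
      work <- append_residues(work, data.frame(
        chain = "W", seqnum = n_residues(work) + seq_len(nrow(newpos)),
        icode = "", resname = "HOH", atom = "O", element = "O",
        x = newpos[, 1], y = newpos[, 2], z = newpos[, 3], occ = 1, b = 30))
      peaks <- peaks[-new_rows, , drop = FALSE]
    }
  }
  dimnames(accepted) <- list(NULL, c("x", "y", "z"))
  attr(accepted, "pass") <- pass_of
  accepted
}

#' Synthesize a density map from a model
#'
#' Each atom contributes an occupancy-weighted 3-D Gaussian whose width
#' is set by the atom's B factor plus `atom_width_B`, matching the
#' single-Gaussian form factors used by [structure_factors()] (so an
#' FFT of this map reproduces the direct-summation amplitudes). The map
#' is periodic over the unit cell.
#'
#' @param model A [structure_model()].
#' @param grid_spacing Approximate voxel spacing in angstroms.
#' @param atom_width_B Extra Gaussian width in square angstroms added to
#'   each atom's B factor (default 0).
#' @return A [density_grid()].
#' @export
map_from_model <- function(model, grid_spacing = 0.7, atom_width_B = 0) {
  if (grid_spacing <= 0) stop("grid spacing must be positive")
  cell <- model$cell
  d <- pmax(4L, as.integer(ceiling(c(cell$a, cell$b, cell$c) / grid_spacing)))
  vals <- array(0, d)
  a <- model$atoms
  if (!nrow(a)) return(density_grid(cell, vals))
  ab <- form_factor_ab(a$element)
  frac_rows <- sqrt(rowSums(cell$frac^2))  # fractional extent of 1 A per axis
  fr_all <- fractionalize(cell, as.matrix(a[, c("x", "y", "z")])) %% 1
  for (ia in seq_len(nrow(a))) {
    Btot <- ab[ia, 2] + a$b[ia] + atom_width_B
    amp <- a$occ[ia] * ab[ia, 1] * (4 * pi / Btot)^1.5
    rcut <- sqrt(Btot * log(1e8)) / (2 * pi)
    ctr <- fr_all[ia, ]
    span <- lapply(1:3, function(ax) {
      ext <- ceiling(rcut * frac_rows[ax] * d[ax])
      ctr_vox <- round(ctr[ax] * d[ax])
      (ctr_vox - ext):(ctr_vox + ext)
    })
    box <- as.matrix(expand.grid(i = span[[1]], j = span[[2]], k = span[[3]]))
    fr_box <- sweep(box, 2, d, "/")
    delta <- orthogonalize(cell, sweep(fr_box, 2, ctr))
    r2 <- rowSums(delta^2)
    keep <- r2 <= rcut^2
    if (!any(keep)) next
    idx <- (box[keep, , drop = FALSE] %% matrix(d, sum(keep), 3, byrow = TRUE)) + 1
    contrib <- amp * exp(-4 * pi^2 * r2[keep] / Btot)
    lin <- idx[, 1] + d[1] * (idx[, 2] - 1) + d[1] * d[2] * (idx[, 3] - 1)
    agg <- rowsum(contrib, lin)
    vals[as.integer(rownames(agg))] <- vals[as.integer(rownames(agg))] + agg[, 1]
  }
  density_grid(cell, vals)
}

#' Structure factors by direct summation
#'
#' Computes `F(h) = sum_atoms occ * f(s) * exp(-B s^2 / 4) *
#' exp(2 pi i h . x)` over all unique reflections (one Friedel
#' hemisphere) with d-spacing of at least `d_min`, with atoms expanded
#' over the space-group operators. `f(s)` is a bundled single-Gaussian
#' form factor per element. F(000) is excluded.
#'
#' @param model A non-empty [structure_model()].
#' @param d_min Resolution limit in angstroms.
#' @return A [reflection_set()] with calculated amplitudes in `fobs` and
#'   phases (degrees) in `phi`.
#' @export
structure_factors <- function(model, d_min) {
  if (!nrow(model$atoms)) stop("model has no atoms")
  if (d_min <= 0) stop("d_min must be positive")
  cell <- model$cell
  hmax <- ceiling(c(cell$a, cell$b, cell$c) / d_min) + 1
  H <- as.matrix(expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                             l = -hmax[3]:hmax[3]))
  dsp <- d_spacing(cell, H)
  hemi <- (H[, 3] > 0) | (H[, 3] == 0 & H[, 2] > 0) |
    (H[, 3] == 0 & H[, 2] == 0 & H[, 1] > 0)
  keep <- hemi & dsp >= d_min
  H <- H[keep, , drop = FALSE]
  dsp <- dsp[keep]
  a <- model$atoms
  fr <- fractionalize(cell, as.matrix(a[, c("x", "y", "z")])) %% 1
  ops <- model$spacegroup$ops
  fr_exp <- do.call(rbind, lapply(ops, function(op) apply_symop(op, fr, wrap = TRUE)))
  occ <- rep(a$occ, length(ops))
  Bf <- rep(a$b, length(ops))
  ab <- form_factor_ab(rep(a$element, length(ops)))
  s2 <- (1 / dsp)^2
  # weight matrix: nref x natom_images
  w <- exp(-outer(s2 / 4, ab[, 2] + Bf)) *
    matrix(occ * ab[, 1], nrow(H), length(occ), byrow = TRUE)
  phase <- 2 * pi * (H %*% t(fr_exp))
  Freal <- rowSums(w * cos(phase))
  Fimag <- rowSums(w * sin(phase))
  amp <- sqrt(Freal^2 + Fimag^2)
  phi <- atan2(Fimag, Freal) * 180 / pi
  reflection_set(cell, data.frame(h = H[, 1], k = H[, 2], l = H[, 3],
                                  fobs = amp, phi = phi))
}
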