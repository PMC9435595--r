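# Symmetry-expanded coordinate images. Returns the orthogonal
# coordinates of every atom image under all space-group operations and
# the 27 neighboring lattice translations (or just the identity when
# expand is FALSE). Used by the distance rules for dummy atoms, waters
# and crystal contacts.
symmetry_images <- function(model, sel = TRUE, expand = TRUE) {
  xyz <- atom_coords(model, sel)
  if (!nrow(xyz)) return(xyz)
  if (!expand) return(xyz)
  fr <- fractionalize(model$cell, xyz) %% 1
  ops <- model$spacegroup$ops
  imgs <- do.call(rbind, lapply(ops, function(op) apply_symop(op, fr, wrap = TRUE)))
  shifts <- as.matrix(expand.grid(u = -1:1, v = -1:1, w = -1:1))
  all_fr <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(i) {
    sweep(imgs, 2, shifts[i, ], "+")
  }))
  orthogonalize(model$cell, all_fr)
}

#' Distance from a point to the nearest atom of a model
#'
#' With `expand_symmetry = TRUE` (the default) all space-group images
#' and neighboring lattice translations of the model are considered, so
#' crystal contacts count as real contacts.
#'
#' @param point Orthogonal position in angstroms (length 3).
#' @param model An [structure_model()] with at least one atom.
#' @param expand_symmetry Include symmetry mates and lattice images.
#' @return Minimum distance in angstroms.
#' @export
nearest_model_distance <- function(point, model, expand_symmetry = TRUE) {
  if (!nrow(model$atoms)) stop("model has no atoms")
  imgs <- symmetry_images(model, expand = expand_symmetry)
  min(sqrt(rowSums(sweep(imgs, 2, point)^2)))
}

# Vectorized variant: minimum distance from each row of `points` to a
# precomputed image set.
min_dist_to_images <- function(points, imgs) {
  if (!nrow(imgs)) return(rep(Inf, nrow(points)))
  apply(points, 1, function(p) min(sqrt(rowSums(sweep(imgs, 2, p)^2))))
}
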