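#' Symmetry- and origin-aware model completeness
#'
#' The fraction of protein residues in a reference model that have a
#' matching residue in a built model, with each built chain first moved
#' onto the reference by the space-group operation and allowed origin
#' shift that maximize the number of matched residues. A reference
#' residue matches when its N, C-alpha and C atoms are each within
#' `cutoff` of the corresponding atoms of some built residue (distances
#' are lattice-minimum-image); each reference residue is matched at
#' most once.
#'
#' Continuous (polar) origin components are seeded from C-alpha pair
#' differences between the rotated built chain and the reference, then
#' refined by a coarse-then-fine 1-D scan minimizing the mean matched
#' C-alpha distance, which keeps the match deterministic.
#'
#' @param built,reference [structure_model()]s sharing cell and space
#'   group (within tolerance).
#' @param cutoff Per-atom match distance in angstroms (default 1.0).
#' @return Object of class `match_result`: list with `completeness`
#'   (percent), `matched` / `total` residue counts and a per-chain list
#'   of chosen transforms.
#' @export
completeness <- function(built, reference, cutoff = 1.0) {
  if (!cells_compatible(built$cell, reference$cell))
    stop("built and reference models have incompatible unit cells")
  ref_res <- protein_backbone_frac(reference)
  if (!length(ref_res$keys)) stop("reference model has no protein residues")
  shifts <- candidate_origin_shifts(built$spacegroup)
  ops <- built$spacegroup$ops
  cell <- reference$cell
  matched_keys <- character(0)
  chain_info <- list()
  for (ch in unique(built$atoms$chain[built$atoms$category == "protein"])) {
    blt <- protein_backbone_frac(built, chain = ch)
    if (!length(blt$keys)) next
    best <- list(count = -1L, op = NULL, shift = NULL, keys = character(0))
    for (io in seq_along(ops)) {
      rot_ca <- apply_symop(ops[[io]], blt$ca)
      rot_n <- apply_symop(ops[[io]], blt$n)
      rot_c <- apply_symop(ops[[io]], blt$c)
      for (sh in shifts) {
        cands <- candidate_translations(rot_ca, ref_res$ca, sh)
        for (tv in cands) {
          res <- match_residues(rot_n, rot_ca, rot_c, ref_res, tv, cell, cutoff,
                                exclude = matched_keys)
          if (res$count > best$count ||
              (res$count == best$count && res$mean_dist < best$mean_dist %||% Inf)) {
            best <- list(count = res$count, op = ops[[io]],
                         shift = tv, keys = res$keys, pairs = res$pairs,
                         mean_dist = res$mean_dist,
                         rot = list(n = rot_n, ca = rot_ca, c = rot_c))
          }
        }
      }
    }
    # refine continuous origin components on the matched pairs: shift by
    # the mean wrapped fractional residual, keep only if not worse
    cont <- if (length(shifts)) shifts[[1]]$continuous else rep(FALSE, 3)
    if (best$count > 0 && any(cont) && nrow(best$pairs) > 0) {
      resid <- ref_res$ca[best$pairs[, 1], , drop = FALSE] -
        (best$rot$ca[best$pairs[, 2], , drop = FALSE] +
           matrix(best$shift, nrow(best$pairs), 3, byrow = TRUE))
      resid <- (resid + 0.5) %% 1 - 0.5
      tv2 <- best$shift
      tv2[cont] <- tv2[cont] + colMeans(resid)[cont]
      res2 <- match_residues(best$rot$n, best$rot$ca, best$rot$c, ref_res, tv2,
                             cell, cutoff, exclude = matched_keys)
      if (res2$count > best$count ||
          (res2$count == best$count && res2$mean_dist <= best$mean_dist)) {
        best$shift <- tv2; best$keys <- res2$keys; best$count <- res2$count
      }
    }
    if (best$count > 0) {
      matched_keys <- c(matched_keys, best$keys)
      chain_info[[ch]] <- list(op = symop_triplet(best$op),
                               shift = round(best$shift, 6),
                               matched = best$count)
    } else {
      chain_info[[ch]] <- list(op = NA_character_, shift = c(0, 0, 0), matched = 0L)
    }
  }
  total <- length(ref_res$keys)
  structure(list(completeness = 100 * length(matched_keys) / total,
                 matched = length(matched_keys), total = total,
                 chains = chain_info),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> completeness %.1f%% (%d / %d reference residues)\n",
              x$completeness, x$matched, x$total))
  for (ch in names(x$chains)) {
    ci <- x$chains[[ch]]
    cat(sprintf("  chain %s: %d matched, op %s, shift (%.3f %.3f %.3f)\n",
                ch, ci$matched, ci$op, ci$shift[1], ci$shift[2], ci$shift[3]))
  }
  invisible(x)
}

# Fractional N / CA / C coordinates per complete protein residue.
protein_backbone_frac <- function(model, chain = NULL) {
  a <- model$atoms
  sel <- a$category == "protein"
  if (!is.null(chain)) sel <- sel & a$chain == chain
  a <- a[sel, , drop = FALSE]
  key <- residue_key(a)
  grab <- function(atom) {
    rows <- a[a$atom == atom, , drop = FALSE]
    m <- fractionalize(model$cell, as.matrix(rows[, c("x", "y", "z")]))
    rownames(m) <- residue_key(rows)
    m
  }
  n <- grab("N"); ca <- grab("CA"); c_ <- grab("C")
  keys <- intersect(intersect(rownames(n), rownames(ca)), rownames(c_))
  list(keys = keys, n = n[keys, , drop = FALSE], ca = ca[keys, , drop = FALSE],
       c = c_[keys, , drop = FALSE])
}

# Candidate whole-chain translations compatible with an origin shift
# pattern: discrete components come from the shift itself; continuous
# components are seeded from wrapped CA pair differences.
candidate_translations <- function(rot_ca, ref_ca, sh, max_pairs = 6) {
  if (!any(sh$continuous)) return(list(sh$shift))
  nb <- min(max_pairs, nrow(rot_ca))
  cands <- list()
  for (j in seq_len(nb)) {
    diffs <- sweep(ref_ca, 2, rot_ca[j, ])
    for (r in seq_len(nrow(diffs))) {
      tv <- sh$shift
      dv <- diffs[r, ]
      ok <- TRUE
      for (ax in 1:3) {
        if (sh$continuous[ax]) {
          tv[ax] <- dv[ax]
        } else {
          # discrete axis: pair difference must agree with the shift
          # component modulo 1 (within noise) or the pairing is wrong
          delta <- (dv[ax] - sh$shift[ax]) %% 1
          if (min(delta, 1 - delta) > 0.08) { ok <- FALSE; break }
        }
      }
      if (ok) cands[[length(cands) + 1]] <- tv
    }
  }
  if (!length(cands)) cands <- list(sh$shift)
  cands
}

match_residues <- function(rot_n, rot_ca, rot_c, ref, tv, cell, cutoff, exclude) {
  shift_m <- matrix(tv, nrow(rot_ca), 3, byrow = TRUE)
  b_ca <- rot_ca + shift_m; b_n <- rot_n + shift_m; b_c <- rot_c + shift_m
  avail <- !(ref$keys %in% exclude)
  used_built <- rep(FALSE, nrow(b_ca))
  keys <- character(0)
  dists <- numeric(0)
  pairs <- matrix(integer(0), 0, 2)
  mi_dist <- function(p, q) {
    dfr <- (p - q + 0.5) %% 1 - 0.5
    sqrt(sum(orthogonalize(cell, dfr)^2))
  }
  for (ir in seq_along(ref$keys)) {
    if (!avail[ir]) next
    bestd <- Inf; bestb <- 0L
    for (ib in seq_len(nrow(b_ca))) {
      if (used_built[ib]) next
      dca <- mi_dist(b_ca[ib, ], ref$ca[ir, ])
      if (dca > cutoff) next
      dn <- mi_dist(b_n[ib, ], ref$n[ir, ])
      if (dn > cutoff) next
      dc <- mi_dist(b_c[ib, ], ref$c[ir, ])
      if (dc > cutoff) next
      if (dca < bestd) { bestd <- dca; bestb <- ib }
    }
    if (bestb > 0) {
      used_built[bestb] <- TRUE
      keys <- c(keys, ref$keys[ir])
      dists <- c(dists, bestd)
      pairs <- rbind(pairs, c(ir, bestb))
    }
  }
  list(count = length(keys), keys = keys, pairs = pairs,
       mean_dist = if (length(dists)) mean(dists) else Inf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' F-map correlation between two models
#'
#' The correlation coefficient between the structure-factor amplitudes
#' of the two models' maps, weighted by the cosine of the phase
#' difference: `sum(Fa Fb cos(phi_a - phi_b)) / sqrt(sum(Fa^2)
#' sum(Fb^2))` over all reflections to `d_min`, F(000) excluded. This
#' equals the real-space correlation of the two zero-mean maps computed
#' from the same coefficients.
#'
#' @param model_a,model_b [structure_model()]s sharing a cell, or
#'   [reflection_set()]s carrying amplitudes and phases.
#' @param d_min Resolution limit in angstroms (ignored when reflection
#'   sets are supplied).
#' @return Correlation in `[-1, 1]`.
#' @export
fmap_correlation <- function(model_a, model_b, d_min = 2.5) {
  if (inherits(model_a, "xtal_model")) {
    if (!cells_compatible(model_a$cell, model_b$cell))
      stop("models have incompatible unit cells")
    rs_a <- structure_factors(model_a, d_min)
    rs_b <- structure_factors(model_b, d_min)
  } else {
    rs_a <- model_a; rs_b <- model_b
  }
  key_a <- paste(rs_a$data$h, rs_a$data$k, rs_a$data$l)
  key_b <- paste(rs_b$data$h, rs_b$data$k, rs_b$data$l)
  common <- intersect(key_a, key_b)
  if (!length(common)) stop("no common reflections")
  ia <- match(common, key_a); ib <- match(common, key_b)
  fa <- rs_a$data$fobs[ia]; fb <- rs_b$data$fobs[ib]
  dphi <- (rs_a$data$phi[ia] - rs_b$data$phi[ib]) * pi / 180
  sum(fa * fb * cos(dphi)) / sqrt(sum(fa^2) * sum(fb^2))
}

#' Crystallographic R factors
#'
#' `R = sum(| |Fobs| - k |Fcalc| |) / sum(|Fobs|)` with `k` the
#' least-squares scale over the working set, partitioned by the free-R
#' flag (0 = free).
#'
#' @param rs_obs Observed [reflection_set()] with free flags.
#' @param model An [structure_model()] (calculated amplitudes are
#'   computed to the observed resolution limit) or a precomputed
#'   [reflection_set()] of calculated amplitudes.
#' @return List with `r_all`, `r_work`, `r_free` and the scale `k`.
#' @export
r_factor <- function(rs_obs, model) {
  rs_calc <- if (inherits(model, "xtal_model"))
    structure_factors(model, rs_obs$d_min) else model
  key_o <- paste(rs_obs$data$h, rs_obs$data$k, rs_obs$data$l)
  key_c <- paste(rs_calc$data$h, rs_calc$data$k, rs_calc$data$l)
  common <- intersect(key_o, key_c)
  if (!length(common)) stop("no overlap between observed and calculated reflections")
  fo <- rs_obs$data$fobs[match(common, key_o)]
  fc <- rs_calc$data$fobs[match(common, key_c)]
  free <- rs_obs$data$free[match(common, key_o)]
  work <- is.na(free) | free != 0
  k <- sum(fo[work] * fc[work]) / sum(fc[work]^2)
  rf <- function(sel) if (any(sel)) sum(abs(fo[sel] - k * fc[sel])) / sum(fo[sel]) else NA_real_
  list(r_all = rf(rep(TRUE, length(fo))), r_work = rf(work),
       r_free = rf(!work), k = k)
}

#' Data / model quality gate
#'
#' A case fails the gate when R_free exceeds `0.06 * d_min + 0.17`, the
#' data completeness is below 90 percent, or the F-map correlation is
#' below 0.2. All failed clauses are reported.
#'
#' @param d_min Resolution in angstroms.
#' @param r_free Cross-validation R factor.
#' @param data_completeness Percentage of theoretically observable
#'   reflections present.
#' @param fmap_corr F-map correlation.
#' @return List with logical `pass` and character `reasons`.
#' @export
quality_gate <- function(d_min, r_free, data_completeness, fmap_corr) {
  reasons <- character(0)
  if (r_free > 0.06 * d_min + 0.17) reasons <- c(reasons, "r_free")
  if (data_completeness < 90) reasons <- c(reasons, "completeness")
  if (fmap_corr < 0.2) reasons <- c(reasons, "fmap_correlation")
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Data completeness against the full reciprocal sphere
#'
#' Fraction (in percent) of symmetry-unique reflections theoretically
#' observable to the set's resolution limit that are actually present.
#'
#' @param rs A [reflection_set()].
#' @param spacegroup A [space_group()] (default P1, Friedel pairs
#'   merged).
#' @return Percentage in `[0, 100]`.
#' @export
data_completeness <- function(rs, spacegroup = space_group("P 1")) {
  cell <- rs$cell
  d_min <- rs$d_min
  hmax <- ceiling(c(cell$a, cell$b, cell$c) / d_min) + 1
  H <- as.matrix(expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                             l = -hmax[3]:hmax[3]))
  dsp <- d_spacing(cell, H)
  H <- H[is.finite(dsp) & dsp >= d_min - 1e-9, , drop = FALSE]
  canon <- canonical_hkl(H, spacegroup)
  theo <- unique(canon)
  obs <- unique(canonical_hkl(as.matrix(rs$data[, c("h", "k", "l")]), spacegroup))
  100 * sum(obs %in% theo) / length(theo)
}

# Canonical representative of each index under the group's reciprocal
# symmetry plus Friedel inversion: lexicographic maximum over images.
canonical_hkl <- function(H, spacegroup) {
  imgs <- lapply(spacegroup$ops, function(op) H %*% op$R)
  imgs <- c(imgs, lapply(imgs, function(m) -m))
  enc <- function(m) m[, 1] * 4e6 + m[, 2] * 2e3 + m[, 3]
  codes <- do.call(cbind, lapply(imgs, enc))
  best <- max.col(codes, ties.method = "first")
  vapply(seq_len(nrow(H)), function(i) {
    m <- imgs[[best[i]]]
    paste(m[i, 1], m[i, 2], m[i, 3])
  }, "")
}

#' Truncate a predicted model by pLDDT
#'
#' Removes residues whose per-residue confidence (pLDDT, stored in the
#' B-factor field by convention) falls below `cutoff`.
#'
#' @param model An [structure_model()] carrying pLDDT in `b`.
#' @param cutoff pLDDT cutoff (0 disables truncation).
#' @return The truncated model.
#' @export
truncate_by_plddt <- function(model, cutoff) {
  rt <- residue_table(model)
  a <- model$atoms
  key <- residue_key(a)
  plddt <- vapply(rt$key, function(k) mean(a$b[key == k]), numeric(1))
  drop <- rt$key[plddt < cutoff]
  out <- subset_residues(model, drop, drop = TRUE)
  if (!nrow(out$atoms)) warning("pLDDT cutoff removed every residue")
  out
}

#' Molecular-replacement score
#'
#' The product of the correlation coefficient and the packing function
#' (1 when no molecules overlap, -1 when they overlap completely).
#'
#' @param correlation Correlation coefficient.
#' @param packing Packing function value in `[-1, 1]`.
#' @return The product.
#' @export
mr_score <- function(correlation, packing) {
  if (abs(packing) > 1) stop("packing function must lie in [-1, 1]")
  correlation * packing
}

#' Superposed C-alpha similarity
#'
#' Truncates the predicted model to residues present in the reference
#' chain (matched by residue numbering), superposes the common C-alpha
#' atoms by least squares (Kabsch) and returns the percentage of the
#' chain's C-alpha atoms that end up within `cutoff` of any predicted
#' C-alpha.
#'
#' @param predicted An [structure_model()].
#' @param reference An [structure_model()] providing the chain.
#' @param chain Chain id in `reference`; when `NULL` the chain
#'   maximizing the similarity is used (ties broken by chain id).
#' @param cutoff Match distance in angstroms (default 1.0).
#' @return Percentage in `[0, 100]`.
#' @export
superposed_similarity <- function(predicted, reference, chain = NULL, cutoff = 1.0) {
  chains <- sort(unique(reference$atoms$chain[reference$atoms$category == "protein"]))
  if (!is.null(chain)) chains <- chain
  best <- -Inf
  for (ch in chains) {
    ref_ca <- named_atom_coords(reference, "CA", chain = ch)
    prd_ca <- named_atom_coords(predicted, "CA")
    # residue numbering must agree: strip chain id from the predicted keys
    ref_num <- sub("^[^|]*\\|", "", rownames(ref_ca))
    prd_num <- sub("^[^|]*\\|", "", rownames(prd_ca))
    common <- intersect(ref_num, prd_num)
    if (length(common) < 3) {
      if (is.null(chain)) next
      stop("fewer than 3 common C-alpha atoms between models")
    }
    P <- prd_ca[match(common, prd_num), , drop = FALSE]
    Q <- ref_ca[match(common, ref_num), , drop = FALSE]
    fit <- kabsch(P, Q)
    all_prd <- sweep(prd_ca[prd_num %in% common, , drop = FALSE], 2, fit$cp) %*%
      fit$U
    all_prd <- sweep(all_prd, 2, fit$cq, "+")
    n_hit <- sum(apply(ref_ca, 1, function(p)
      min(sqrt(rowSums(sweep(all_prd, 2, p)^2))) <= cutoff))
    val <- 100 * n_hit / nrow(ref_ca)
    if (val > best) best <- val
  }
  if (!is.finite(best)) stop("fewer than 3 common C-alpha atoms between models")
  best
}

# Least-squares superposition (Kabsch): rotation U and centroids such
# that (P - cp) U + cq approximates Q.
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  S <- t(Pc) %*% Qc
  sv <- svd(S)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  U <- sv$u %*% D %*% t(sv$v)
  list(U = U, cp = cp, cq = cq)
}
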