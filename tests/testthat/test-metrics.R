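test_that("completeness is exact for identity, deletion and displacement", {
  ref <- helix10("P21")
  expect_equal(completeness(ref, ref)$completeness, 100)
  # deletion: equals the retained fraction
  b <- delete_residues(ref, 0.4, seed = 5)
  expect_equal(completeness(b, ref)$completeness, 60)
  # rigid 2 A displacement with no symmetry relation: nothing matches
  b2 <- translate_model(ref, c(2, 0, 0))
  expect_equal(completeness(b2, ref)$completeness, 0)
  # reference without protein residues errors
  cell <- ref$cell
  waters <- structure_model(cell, "P21", data.frame(
    chain = "W", seqnum = 1:3, icode = "", resname = "HOH", atom = "O",
    element = "O", x = 1:3, y = 1:3, z = 1:3, occ = 1, b = 20))
  expect_error(completeness(ref, waters), "no protein")
})

test_that("completeness undoes every operator and allowed origin shift", {
  cases <- list(
    list(sym = "P1",      cell = unit_cell(24, 24, 30)),
    list(sym = "P21",     cell = unit_cell(24, 24, 30, 90, 105, 90)),
    list(sym = "C2",      cell = unit_cell(34, 26, 30, 90, 105, 90)),
    list(sym = "P212121", cell = unit_cell(24, 26, 34)),
    list(sym = "P43212",  cell = unit_cell(26, 26, 34)))
  for (cs in cases) {
    ref <- make_helix_model(10, cs$cell, spacegroup = cs$sym, seed = 4)
    sg <- ref$spacegroup
    shifts <- candidate_origin_shifts(sg)
    for (op in sg$ops) {
      for (sh in shifts) {
        extra <- ifelse(sh$continuous, 0.137, 0)   # polar axes are free
        built <- transform_model(ref, op, shift = sh$shift + extra)
        res <- completeness(built, ref)
        expect_equal(res$completeness, 100,
                     label = paste(cs$sym, mxbuild:::symop_triplet(op),
                                   paste(sh$shift, collapse = ",")))
      }
    }
  }
})

test_that("completeness is monotone under deletion and matches retained fractions", {
  ref <- helix10("P212121", cell = unit_cell(24, 26, 34))
  last <- 100
  for (fr in c(0.1, 0.3, 0.5, 0.8)) {
    b <- delete_residues(ref, fr, seed = 3)
    val <- completeness(b, ref)$completeness
    expect_equal(val, 100 * (10 - round(fr * 10)) / 10)
    expect_lte(val, last)
    last <- val
  }
})

test_that("F-map correlation hits its analytic anchors", {
  m <- helix10()
  expect_equal(fmap_correlation(m, m, 2.5), 1.0, tolerance = 1e-12)
  # 180 degree phase flip at the reflection level
  rs <- structure_factors(m, 2.5)
  rs_flip <- rs
  rs_flip$data$phi <- rs$data$phi + 180
  expect_equal(fmap_correlation(rs, rs_flip), -1.0, tolerance = 1e-12)
  # symmetry of arguments
  m2 <- perturb_model(m, 0.8, seed = 4)
  expect_equal(fmap_correlation(m, m2, 2.5), fmap_correlation(m2, m, 2.5),
               tolerance = 1e-12)
  # invariance under joint rigid translation
  shift <- c(1.7, -2.3, 0.9)
  expect_equal(fmap_correlation(translate_model(m, shift),
                                translate_model(m2, shift), 2.5),
               fmap_correlation(m, m2, 2.5), tolerance = 1e-9)
})

test_that("F-map correlation agrees with an FFT real-space oracle", {
  set.seed(6)
  for (rep in 1:3) {
    cell <- unit_cell(18, 18, 18)
    mk <- function() structure_model(cell, "P 1", data.frame(
      chain = "A", seqnum = 1:10, icode = "", resname = "ALA", atom = "CA",
      element = "C", x = runif(10, 2, 16), y = runif(10, 2, 16),
      z = runif(10, 2, 16), occ = 1, b = 25))
    a <- mk(); b <- mk()
    got <- fmap_correlation(a, b, 2.5)
    # oracle: band-limited Fourier coefficients of sampled maps;
    # Re(sum Fa conj Fb) / norms == real-space correlation (Parseval)
    fa <- fft_structure_factors(a, 2.5, spacing = 0.45)
    fb <- fft_structure_factors(b, 2.5, spacing = 0.45)
    key <- function(o) paste(o$H[, 1], o$H[, 2], o$H[, 3])
    mi <- match(key(fa), key(fb))
    Fa <- fa$F; Fb <- fb$F[mi]
    oracle <- Re(sum(Fa * Conj(Fb))) / sqrt(sum(Mod(Fa)^2) * sum(Mod(Fb)^2))
    expect_equal(got, oracle, tolerance = 1e-3)
  }
})

test_that("R factors reproduce hand arithmetic and scale invariance", {
  cell <- unit_cell(10, 10, 10)
  obs <- reflection_set(cell, data.frame(
    h = c(1, 2, 3), k = 0, l = 0, fobs = c(10, 20, 30), free = c(1, 1, 1)))
  calc <- reflection_set(cell, data.frame(
    h = c(1, 2, 3), k = 0, l = 0, fobs = c(12, 18, 33)))
  out <- r_factor(obs, calc)
  k <- (10 * 12 + 20 * 18 + 30 * 33) / (12^2 + 18^2 + 33^2)
  r_hand <- (abs(10 - k * 12) + abs(20 - k * 18) + abs(30 - k * 33)) / 60
  expect_equal(out$k, k, tolerance = 1e-12)
  expect_equal(out$r_work, r_hand, tolerance = 1e-12)
  expect_equal(out$r_all, r_hand, tolerance = 1e-12)
  expect_true(is.na(out$r_free))
  # exactly proportional observations: all R factors vanish
  obs2 <- reflection_set(cell, data.frame(
    h = c(1, 2, 3), k = 0, l = 0, fobs = 2.5 * c(12, 18, 33),
    free = c(0, 1, 1)))
  out2 <- r_factor(obs2, calc)
  expect_equal(out2$r_all, 0, tolerance = 1e-12)
  expect_equal(out2$r_work, 0, tolerance = 1e-12)
  expect_equal(out2$r_free, 0, tolerance = 1e-12)
  # a perturbed model yields finite non-negative residuals
  m <- helix10()
  rs <- obs_from_model(m, 2.5)
  rr <- r_factor(rs, perturb_model(m, 0.4, seed = 8))
  expect_true(is.finite(rr$r_free) && rr$r_free >= 0)
  expect_error(r_factor(obs, reflection_set(cell, data.frame(
    h = 9, k = 9, l = 9, fobs = 1))), "overlap")
})

test_that("the quality gate reproduces a truth-table oracle", {
  for (d_min in c(1.0, 1.5, 2.0, 2.5, 3.0, 3.5)) {
    for (r_free in seq(0.15, 0.45, by = 0.02)) {
      for (comp in c(85, 89, 90, 95)) {
        for (fc in c(0.1, 0.2, 0.5)) {
          out <- quality_gate(d_min, r_free, comp, fc)
          bad <- c("r_free"[r_free > 0.06 * d_min + 0.17],
                   "completeness"[comp < 90],
                   "fmap_correlation"[fc < 0.2])
          expect_equal(out$pass, length(bad) == 0)
          expect_setequal(out$reasons, bad)
        }
      }
    }
  }
  # hand-derived boundary at 2.0 A: threshold 0.29
  expect_true(quality_gate(2.0, 0.25, 95, 0.5)$pass)
  expect_true(quality_gate(2.0, 0.29, 95, 0.5)$pass)
  expect_false(quality_gate(2.0, 0.30, 95, 0.5)$pass)
  expect_identical(quality_gate(2.0, 0.30, 95, 0.5)$reasons, "r_free")
  expect_false(quality_gate(2.0, 0.25, 89, 0.5)$pass)
})

test_that("superposed similarity removes rigid motion and counts matches", {
  ref <- helix10()
  # arbitrary rigid motion: rotation about z plus translation
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  a <- ref$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + 3; a$y <- xyz[, 2] - 2; a$z <- xyz[, 3] + 5
  moved <- structure_model(ref$cell, ref$spacegroup, a)
  expect_equal(superposed_similarity(moved, ref), 100)
  # displace half the residues 5 A in self-cancelling adjacent pairs
  # (zero net translation and negligible net moment, so the fit stays
  # anchored on the intact half): ~50% of the chain C-alphas match
  m20 <- make_helix_model(20, unit_cell(30, 30, 42), seed = 6)
  a2 <- m20$atoms
  pairs <- list(c(2, 3), c(6, 7), c(10, 11), c(14, 15), c(18, 19))
  disp <- numeric(20)
  for (i in seq_along(pairs)) {
    s <- c(1, -1, 1, -1, 1)[i]
    disp[pairs[[i]][1]] <- 5 * s
    disp[pairs[[i]][2]] <- -5 * s
  }
  a2$x <- a2$x + disp[a2$seqnum]
  half <- structure_model(m20$cell, m20$spacegroup, a2)
  sim <- superposed_similarity(half, m20)
  expect_gte(sim, 40); expect_lte(sim, 60)
  # unrelated random coordinates: essentially no matches
  set.seed(9)
  rnd <- m20$atoms
  rnd[, c("x", "y", "z")] <- matrix(runif(nrow(rnd) * 3, 0, 30), ncol = 3)
  noise <- structure_model(m20$cell, m20$spacegroup, rnd)
  expect_lte(superposed_similarity(noise, m20), 10)
  # needs at least 3 common C-alphas
  tiny <- subset_residues(m20, c("A|1|", "A|2|"), drop = FALSE)
  expect_error(superposed_similarity(tiny, m20), "3 common")
})

test_that("pLDDT truncation filters residues by the B-factor field", {
  m <- ca_chain_model(list(A = 4))
  m$atoms$b <- c(40, 60, 80, 95)
  expect_equal(mxbuild:::n_residues(truncate_by_plddt(m, 0)), 4)
  out <- truncate_by_plddt(m, 70)
  expect_equal(mxbuild:::n_residues(out), 2)
  expect_setequal(out$atoms$seqnum, c(3, 4))
  expect_warning(empty <- truncate_by_plddt(m, 100), "every residue")
  expect_equal(nrow(empty$atoms), 0)
})

test_that("the MR score is the correlation-packing product", {
  expect_equal(mr_score(0.5, 1.0), 0.5)
  expect_equal(mr_score(0.5, -1.0), -0.5)
  expect_equal(mr_score(0.73, 0), 0)
  expect_error(mr_score(0.5, 1.5), "packing")
})

test_that("data completeness counts symmetry-unique reflections", {
  m <- helix10()
  rs <- structure_factors(m, 2.5)
  expect_equal(data_completeness(rs), 100, tolerance = 1e-9)
  half <- reflection_set(rs$cell, rs$data[seq(1, nrow(rs$data), by = 2),
                                          c("h", "k", "l", "fobs")])
  expect_lt(data_completeness(half), 100)
  expect_gt(data_completeness(half), 40)
})
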