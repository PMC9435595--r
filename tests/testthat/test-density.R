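test_that("grid statistics match closed forms and an independent accumulation", {
  cell <- unit_cell(10, 10, 10)
  # constant map is flagged degenerate
  st <- grid_stats(density_grid(cell, array(3.5, c(4, 4, 4))))
  expect_equal(st$sigma, 0)
  expect_true(st$degenerate)
  expect_error(find_peaks(density_grid(cell, array(1, c(4, 4, 4)))), "constant")
  # single non-zero voxel: closed form
  v <- 7.3; N <- 64
  vals <- array(0, c(4, 4, 4)); vals[2, 3, 1] <- v
  st <- grid_stats(density_grid(cell, vals))
  expect_equal(st$mu, v / N)
  expect_equal(st$sigma, sqrt(((v - v / N)^2 + (N - 1) * (v / N)^2) / N))
  # synthetic blob map vs two-pass accumulation oracle
  g <- map_from_model(helix10(), 0.8, atom_width_B = 10)
  x <- as.numeric(g$values)
  mu <- sum(x) / length(x)
  ss <- 0; for (i in seq_along(x)) ss <- ss + (x[i] - mu)^2
  st <- grid_stats(g)
  expect_equal(st$mu, mu, tolerance = 1e-12)
  expect_equal(st$sigma, sqrt(ss / length(x)), tolerance = 1e-10)
})

test_that("an isolated blob yields exactly one peak at its center", {
  cell <- unit_cell(20, 20, 20)
  pos <- matrix(c(7.3, 11.2, 9.8), 1)
  g <- blob_map(cell, pos, b = 8, spacing = 0.5)
  pk <- find_peaks(g, 2)
  expect_equal(nrow(pk), 1)
  expect_lt(sqrt(sum((as.numeric(pk[1, c("x", "y", "z")]) - pos)^2)), 0.25)
  expect_gt(pk$height_sigma[1], 2)
  expect_gte(pk$volume[1], mxbuild:::voxel_volume(g))
})

test_that("peak lists equal a brute-force local-maximum scan on random grids", {
  set.seed(42)
  for (rep in 1:8) {
    vals <- array(rnorm(16^3), c(16, 16, 16))
    g <- density_grid(unit_cell(16, 16, 16), vals)
    pk <- find_peaks(g, 2)
    oracle <- brute_local_maxima(vals, 2)
    if (is.null(oracle)) {
      expect_equal(nrow(pk), 0)
    } else {
      expect_equal(nrow(pk), nrow(oracle))
      got <- sort(paste(pk$i, pk$j, pk$k))
      want <- sort(paste(oracle[, 1], oracle[, 2], oracle[, 3]))
      expect_identical(got, want)
      expect_equal(sort(pk$value), sort(oracle[, 4]))
    }
  }
})

test_that("peak volumes match an independent 6-connected region count", {
  # independent flood fill using a stack over linear indices
  region_size <- function(vals, thr, start) {
    d <- dim(vals)
    seen <- array(FALSE, d)
    stack <- list(start)
    seen[start[1], start[2], start[3]] <- TRUE
    count <- 0
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      count <- count + 1
      for (ax in 1:3) for (dd in c(-1, 1)) {
        nb <- cur
        nb[ax] <- ((nb[ax] - 1 + dd) %% d[ax]) + 1
        if (!seen[nb[1], nb[2], nb[3]] && vals[nb[1], nb[2], nb[3]] >= thr) {
          seen[nb[1], nb[2], nb[3]] <- TRUE
          stack[[length(stack) + 1]] <- nb
        }
      }
    }
    count
  }
  cell <- unit_cell(18, 18, 18)
  pos <- rbind(c(5, 5, 5), c(12, 11, 13))
  g <- blob_map(cell, pos, b = 6, spacing = 0.6)
  st <- grid_stats(g)
  thr <- st$mu + 2 * st$sigma
  pk <- find_peaks(g, 2)
  expect_equal(nrow(pk), 2)
  for (r in 1:2) {
    want <- region_size(g$values, thr, c(pk$i[r], pk$j[r], pk$k[r])) *
      mxbuild:::voxel_volume(g)
    expect_equal(pk$volume[r], want)
  }
})

test_that("dummy-atom flooding applies the distance band and pair rule", {
  cell <- std_cell()
  m <- helix10(cell = cell)
  ctr <- orthogonalize(cell, c(0.5, 0.5, 0.5))
  o5 <- as.numeric(m$atoms[m$atoms$seqnum == 5 & m$atoms$atom == "O",
                           c("x", "y", "z")])
  rad <- o5 - c(ctr[1], ctr[2], o5[3]); rad <- rad / sqrt(sum(rad^2))
  # one blob 3.0 A out (eligible), one 1.0 A out (too close)
  g <- blob_map(cell, rbind(o5 + 3.0 * rad, o5 + 1.0 * rad), b = 1,
                spacing = 0.4)
  dm <- flood_dummy_atoms(g, m, expand_symmetry = FALSE)
  expect_equal(nrow(dm), 1)
  expect_equal(nearest_model_distance(dm[1, ], m, FALSE), 3.0, tolerance = 0.2)
  # two eligible blobs 1.0 A apart: only the taller survives the 1.4 A rule
  p1 <- o5 + 3.0 * rad
  p2 <- p1 + c(0, 0, 1.0)
  blobs <- structure_model(cell, "P 1", data.frame(
    chain = "X", seqnum = 1:2, icode = "", resname = "DUM", atom = "O",
    element = "O", x = c(p1[1], p2[1]), y = c(p1[2], p2[2]),
    z = c(p1[3], p2[3]), occ = c(1, 0.6), b = 1))
  g2 <- map_from_model(blobs, 0.4)
  dm2 <- flood_dummy_atoms(g2, m, expand_symmetry = FALSE)
  expect_equal(nrow(dm2), 1)
  expect_lt(sqrt(sum((dm2[1, ] - p1)^2)), 0.3)  # the taller one
})

test_that("water picking honors volume, exclusion and hydrogen-bond rules over passes", {
  cell <- std_cell()
  m <- helix10(cell = cell)
  ctr <- orthogonalize(cell, c(0.5, 0.5, 0.5))
  o5 <- as.numeric(m$atoms[m$atoms$seqnum == 5 & m$atoms$atom == "O",
                           c("x", "y", "z")])
  rad <- o5 - c(ctr[1], ctr[2], o5[3]); rad <- rad / sqrt(sum(rad^2))
  w1 <- o5 + 2.8 * rad          # first shell
  w2 <- o5 + 5.6 * rad          # second shell: 2.8 from w1, 5.6 from model O
  g <- blob_map(cell, rbind(w1, w2), b = 1, spacing = 0.4)
  # fixture sanity: both blobs compact and isolated
  pk <- find_peaks(g, 2)
  expect_true(all(pk$volume < 15))
  out <- pick_waters(g, m, expand_symmetry = FALSE)
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "pass"), c(1L, 2L))
  d1 <- sqrt(rowSums(sweep(out, 2, w1)^2))
  expect_equal(sort(round(pmin(d1, sqrt(rowSums(sweep(out, 2, w2)^2))), 1)),
               c(0, 0))
  # passes = 1 output is a subset of passes = 3
  out1 <- pick_waters(g, m, passes = 1, expand_symmetry = FALSE)
  expect_equal(nrow(out1), 1)
  expect_lt(min(sqrt(rowSums(sweep(out, 2, out1[1, ])^2))), 1e-9)
  # far blob: no N/O within 3.2 A -> never placed
  far <- o5 + 9.0 * rad
  gf <- blob_map(cell, matrix(far, 1), b = 1, spacing = 0.4)
  expect_equal(nrow(pick_waters(gf, m, expand_symmetry = FALSE)), 0)
  # fat blob above 15 A^3 -> never placed even though well-positioned
  gfat <- blob_map(cell, matrix(w1, 1), b = 30, spacing = 0.4)
  pk_fat <- find_peaks(gfat, 2)
  expect_gt(pk_fat$volume[1], 15)
  expect_equal(nrow(pick_waters(gfat, m, expand_symmetry = FALSE)), 0)
})

test_that("every dummy and water pick satisfies the stated constraints post hoc", {
  set.seed(77)
  for (rep in 1:10) {
    cell <- unit_cell(20, 20, 20)
    base <- structure_model(cell, "P 1", data.frame(
      chain = "A", seqnum = 1:5, icode = "", resname = "ALA",
      atom = c("N", "CA", "C", "O", "CB"), element = c("N", "C", "C", "O", "C"),
      x = runif(5, 6, 14), y = runif(5, 6, 14), z = runif(5, 6, 14),
      occ = 1, b = 20))
    npk <- 6
    g <- blob_map(cell, cbind(runif(npk, 2, 18), runif(npk, 2, 18),
                              runif(npk, 2, 18)), b = 1, spacing = 0.5)
    dm <- flood_dummy_atoms(g, base)
    if (nrow(dm)) {
      dist_model <- apply(dm, 1, brute_min_dist, model = base)
      expect_true(all(dist_model >= 1.9 - 1e-9 & dist_model <= 10 + 1e-9))
      if (nrow(dm) > 1)
        expect_gte(min(dist(dm)), 1.4)
    }
    wt <- pick_waters(g, base)
    if (nrow(wt)) {
      st <- grid_stats(g)
      for (r in seq_len(nrow(wt))) {
        # above threshold, compact volume
        pkrow <- find_peaks(g, 2)
        hit <- which.min(sqrt(rowSums(sweep(as.matrix(
          pkrow[, c("x", "y", "z")]), 2, wt[r, ])^2)))
        expect_lt(pkrow$volume[hit], 15)
        # exclusion from the original model
        expect_gt(brute_min_dist(wt[r, ], base), 2.4)
      }
      if (nrow(wt) > 1) expect_gt(min(dist(wt)), 2.4)
      # each water has an N/O partner within 3.2 A (earlier waters count)
      for (r in seq_len(nrow(wt))) {
        no <- base$atoms[base$atoms$element %in% c("N", "O"), c("x", "y", "z")]
        cand <- rbind(as.matrix(no), wt[-r, , drop = FALSE])
        expect_lte(min(sqrt(rowSums(sweep(cand, 2, wt[r, ])^2))), 3.2)
      }
    }
  }
})

test_that("synthetic maps peak at atoms and integrate to the analytic value", {
  cell <- unit_cell(20, 20, 20)
  one <- structure_model(cell, "P 1", data.frame(
    chain = "A", seqnum = 1, icode = "", resname = "ALA", atom = "CA",
    element = "C", x = 7.2, y = 9.1, z = 12.4, occ = 1, b = 15))
  g <- map_from_model(one, 0.4)
  top <- which(g$values == max(g$values), arr.ind = TRUE)[1, ]
  top_xyz <- orthogonalize(cell, (top - 1) / dim(g$values))
  expect_lt(sqrt(sum((top_xyz - c(7.2, 9.1, 12.4))^2)), 0.35)
  # two identical atoms a whole number of voxels apart: two equal maxima
  two <- structure_model(cell, "P 1", data.frame(
    chain = "A", seqnum = 1:2, icode = "", resname = "ALA", atom = "CA",
    element = "C", x = c(5.13, 13.13), y = c(5.13, 13.13),
    z = c(5.13, 13.13), occ = 1, b = 15))
  g2 <- map_from_model(two, 0.4)
  pk <- find_peaks(g2, 2)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$value[1], pk$value[2], tolerance = 1e-6)
  # integral of the map ~ analytic Gaussian integral (a_el * occ per atom)
  ab <- mxbuild:::form_factor_ab("C")
  integral <- sum(g$values) * mxbuild:::voxel_volume(g)
  expect_equal(integral, ab[1, 1], tolerance = 0.01 * ab[1, 1])
  expect_error(map_from_model(one, -1), "positive")
})

test_that("direct-summation structure factors behave analytically", {
  cell <- unit_cell(15, 15, 15)
  origin_atom <- structure_model(cell, "P 1", data.frame(
    chain = "A", seqnum = 1, icode = "", resname = "ALA", atom = "CA",
    element = "C", x = 0, y = 0, z = 0, occ = 1, b = 20))
  rs <- structure_factors(origin_atom, 3)
  expect_true(all(abs(rs$data$phi) < 1e-6))
  # amplitudes strictly decrease with |s| (allowing ties at equal s)
  ord <- order(rs$data$d, decreasing = TRUE)
  dd <- rs$data$d[ord]; ff <- rs$data$fobs[ord]
  strict <- diff(dd) < -1e-9
  expect_true(all(diff(ff)[strict] < 0))
  # centrosymmetric pair: phases 0 or 180
  pair <- structure_model(cell, "P 1", data.frame(
    chain = "A", seqnum = 1:2, icode = "", resname = "ALA", atom = "CA",
    element = "C", x = c(3, -3), y = c(1.5, -1.5), z = c(2, -2),
    occ = 1, b = 20))
  rsp <- structure_factors(pair, 3)
  wrapped <- abs(((rsp$data$phi + 90) %% 180) - 90)
  expect_lt(max(wrapped), 1e-5)
})

test_that("direct summation agrees with an FFT oracle on a random 10-atom model", {
  set.seed(5)
  cell <- unit_cell(18, 18, 18)
  m <- structure_model(cell, "P 1", data.frame(
    chain = "A", seqnum = 1:10, icode = "", resname = "ALA", atom = "CA",
    element = "C", x = runif(10, 2, 16), y = runif(10, 2, 16),
    z = runif(10, 2, 16), occ = 1, b = 25))
  rs <- structure_factors(m, 2.5)
  oracle <- fft_structure_factors(m, 2.5, spacing = 0.45)
  okey <- paste(oracle$H[, 1], oracle$H[, 2], oracle$H[, 3])
  key <- paste(rs$data$h, rs$data$k, rs$data$l)
  mi <- match(key, okey)
  expect_false(any(is.na(mi)))
  famp <- Mod(oracle$F[mi])
  k <- sum(famp * rs$data$fobs) / sum(rs$data$fobs^2)
  relrms <- sqrt(mean((famp - k * rs$data$fobs)^2)) / sqrt(mean(famp^2))
  expect_lt(relrms, 0.01)
})

test_that("structure-factor amplitudes are translation invariant, phases shift by 2 pi h dot t", {
  m <- helix10()
  rs <- structure_factors(m, 3)
  shift_frac <- c(0.15, 0.25, 0.05)
  m2 <- translate_model(m, orthogonalize(m$cell, shift_frac))
  rs2 <- structure_factors(m2, 3)
  expect_equal(rs2$data$fobs, rs$data$fobs, tolerance = 1e-9)
  H <- as.matrix(rs$data[, c("h", "k", "l")])
  want <- (rs$data$phi + 360 * as.numeric(H %*% shift_frac)) %% 360
  got <- rs2$data$phi %% 360
  dphi <- abs(((got - want + 180) %% 360) - 180)
  # phases are only defined where the amplitude is non-negligible
  strong <- rs$data$fobs > 1e-8 * max(rs$data$fobs)
  expect_lt(max(dphi[strong]), 1e-6)
})

test_that("joint translation of model and map leaves picks invariant modulo wrap", {
  cell <- unit_cell(20, 20, 20)
  m <- structure_model(cell, "P 1", data.frame(
    chain = "A", seqnum = 1, icode = "", resname = "ALA",
    atom = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
    x = c(8, 9.4, 10.2, 10.2), y = c(8, 8.2, 9.3, 10.4), z = c(10, 10, 10, 9.2),
    occ = 1, b = 20))
  w <- c(10.2, 10.4, 9.2) + 2.8 * c(0, 1, 0)
  g <- blob_map(cell, matrix(w, 1), b = 1, spacing = 0.5)
  out <- pick_waters(g, m, expand_symmetry = FALSE)
  # translate by a whole number of voxels
  nvox <- dim(g$values)
  shift_vox <- c(8, 4, 12)
  shift_ang <- orthogonalize(cell, shift_vox / nvox)
  g2 <- density_grid(cell, g$values[
    ((seq_len(nvox[1]) - 1 - shift_vox[1]) %% nvox[1]) + 1,
    ((seq_len(nvox[2]) - 1 - shift_vox[2]) %% nvox[2]) + 1,
    ((seq_len(nvox[3]) - 1 - shift_vox[3]) %% nvox[3]) + 1])
  m2 <- translate_model(m, shift_ang)
  out2 <- pick_waters(g2, m2, expand_symmetry = FALSE)
  expect_equal(nrow(out2), nrow(out))
  dfr <- fractionalize(cell, out2[1, ]) - fractionalize(cell, out[1, ]) -
    shift_vox / nvox
  dfr <- ((dfr + 0.5) %% 1) - 0.5
  expect_lt(max(abs(orthogonalize(cell, dfr))), 0.2)
})
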