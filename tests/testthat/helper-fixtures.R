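# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files.

std_cell <- function() unit_cell(24, 24, 30)

helix10 <- function(spacegroup = "P 1", seed = 2, cell = std_cell()) {
  make_helix_model(10, cell, spacegroup = spacegroup, seed = seed)
}

# CA-only protein residues along a line: the cheapest model that the
# scoring rules can act on.
ca_chain_model <- function(chains, cell = unit_cell(60, 60, 200)) {
  rows <- list()
  z0 <- 0
  for (ch in names(chains)) {
    n <- chains[[ch]]
    rows[[ch]] <- data.frame(
      chain = ch, seqnum = seq_len(n), icode = "", resname = "ALA",
      atom = "CA", element = "C",
      x = 10 + 0.5 * seq_len(n), y = 10 + z0, z = 10 + 3.8 * seq_len(n) %% 150,
      occ = 1, b = 20, stringsAsFactors = FALSE)
    z0 <- z0 + 8
  }
  structure_model(cell, "P 1", do.call(rbind, rows))
}

uniform_scores <- function(model, main_chain, side_chain = main_chain,
                           llk = 5) {
  rt <- residue_table(model)
  rt <- rt[rt$category == "protein", ]
  n <- nrow(rt)
  rec <- function(v) if (length(v) == 1) rep(v, n) else v
  residue_scores(data.frame(
    chain = rt$chain, seqnum = rt$seqnum, icode = rt$icode,
    main_chain = rec(main_chain), side_chain = rec(side_chain),
    llk = rec(llk), stringsAsFactors = FALSE))
}

# Observed data for a model: calculated amplitudes + sig + free flags.
obs_from_model <- function(model, d_min = 2.2, free_seed = 7) {
  rs <- structure_factors(model, d_min)
  rs$data$sigf <- 0.05 * rs$data$fobs
  generate_free_flags(rs, 0.05, free_seed)
}

# Map fixture: sharp Gaussian blobs at given positions (rows of `pos`)
# over an optional base model density.
blob_map <- function(cell, pos, b = 1, spacing = 0.4, base_model = NULL) {
  atoms <- data.frame(
    chain = "X", seqnum = seq_len(nrow(pos)), icode = "", resname = "DUM",
    atom = "O", element = "O", x = pos[, 1], y = pos[, 2], z = pos[, 3],
    occ = 1, b = b, stringsAsFactors = FALSE)
  if (!is.null(base_model)) atoms <- rbind(base_model$atoms, atoms)
  map_from_model(structure_model(cell, "P 1", atoms), spacing)
}

# Independent brute-force local-maximum scan (oracle for find_peaks).
brute_local_maxima <- function(values, threshold_sigma) {
  d <- dim(values)
  mu <- mean(values)
  sig <- sqrt(mean((values - mu)^2))
  thr <- mu + threshold_sigma * sig
  hits <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    v0 <- values[i, j, k]
    if (v0 < thr) next
    ismax <- TRUE
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      ii <- ((i - 1 + di) %% d[1]) + 1
      jj <- ((j - 1 + dj) %% d[2]) + 1
      kk <- ((k - 1 + dk) %% d[3]) + 1
      if (values[ii, jj, kk] >= v0) { ismax <- FALSE; break }
    }
    if (ismax) hits <- rbind(hits, c(i, j, k, v0))
  }
  hits
}

# Independent symmetry-expanded minimum distance (oracle for the
# distance rules): all operators x 27 neighbor cells, plain loops.
brute_min_dist <- function(point, model, expand = TRUE) {
  fr <- fractionalize(model$cell, as.matrix(model$atoms[, c("x", "y", "z")]))
  ops <- if (expand) model$spacegroup$ops else model$spacegroup$ops[1]
  best <- Inf
  for (op in ops) {
    img <- apply_symop(op, fr, wrap = expand)
    for (du in if (expand) -1:1 else 0) for (dv in if (expand) -1:1 else 0)
      for (dw in if (expand) -1:1 else 0) {
        shifted <- sweep(img, 2, c(du, dv, dw), "+")
        xyz <- orthogonalize(model$cell, shifted)
        best <- min(best, min(sqrt(rowSums(sweep(xyz, 2, point)^2))))
      }
  }
  best
}

# FFT oracle: band-limited Fourier coefficients of a model's sampled
# Gaussian density, indexed by Miller h (list of H matrix, F complex).
fft_structure_factors <- function(model, d_min, spacing = 0.5) {
  g <- map_from_model(model, spacing)
  d <- dim(g$values)
  Fc <- fft(g$values)
  idx <- expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1), k = 0:(d[3] - 1))
  tohkl <- function(i, n) ifelse(i > n / 2, i - n, i)
  H <- cbind(tohkl(idx$i, d[1]), tohkl(idx$j, d[2]), tohkl(idx$k, d[3]))
  dsp <- d_spacing(g$cell, H)
  keep <- is.finite(dsp) & dsp >= d_min
  list(H = H[keep, , drop = FALSE], F = as.vector(Fc)[keep])
}
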