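test_that("median scoring handles odd, even and single counts", {
  mk <- function(v) residue_scores(data.frame(
    chain = "A", seqnum = seq_along(v), icode = "", main_chain = v))
  expect_equal(median_score(mk(c(0.2, 0.4, 0.6))), 0.4)
  expect_equal(median_score(mk(c(0.2, 0.4, 0.6, 0.8))), 0.5)
  expect_equal(median_score(mk(0.37)), 0.37)
  expect_error(median_score(mk(0.5), "llk"), "no scored residues")
})

test_that("chain pruning applies the short-chain mean-vs-median rule", {
  m <- ca_chain_model(list(A = 100, B = 10))
  sc <- uniform_scores(m, main_chain = c(rep(0.8, 100), rep(0.10, 10)))
  out <- prune_chains(m, sc)
  expect_identical(out$removed, "B")
  expect_false("B" %in% out$model$atoms$chain)
  expect_equal(sum(out$model$atoms$chain == "A"), 100)
  # too long to prune
  m2 <- ca_chain_model(list(A = 100, B = 25))
  sc2 <- uniform_scores(m2, main_chain = c(rep(0.8, 100), rep(0.10, 25)))
  expect_length(prune_chains(m2, sc2)$removed, 0)
  # at the threshold: 0.20 >= 0.2 * 0.8 -> kept
  sc3 <- uniform_scores(m, main_chain = c(rep(0.8, 100), rep(0.20, 10)))
  expect_length(prune_chains(m, sc3)$removed, 0)
})

test_that("chain pruning is independent of chain order in the file", {
  m <- ca_chain_model(list(A = 100, B = 10))
  sc <- uniform_scores(m, main_chain = c(rep(0.8, 100), rep(0.05, 10)))
  rev_atoms <- m$atoms[order(match(m$atoms$chain, c("B", "A"))), ]
  m_rev <- structure_model(m$cell, m$spacegroup, rev_atoms)
  expect_identical(sort(prune_chains(m, sc)$removed),
                   sort(prune_chains(m_rev, sc)$removed))
})

test_that("residue and side-chain pruning respects gates, thresholds and the 20% cap", {
  m <- ca_chain_model(list(A = 100))
  sc <- uniform_scores(m, main_chain = c(rep(1.0, 50), rep(0.01, 50)))
  out <- prune_residues_and_sidechains(m, sc, cycle_index = 2, d_min = 2.0)
  # median 0.505, threshold 0.2525, 50 below, cap floor(0.2*100) = 20
  expect_length(out$removed_residues, 20)
  expect_equal(mxbuild:::n_residues(out$model), 80)
  # removed are the lowest-scoring (all tied at 0.01, so first 20 by order)
  expect_true(all(out$removed_residues %in%
                    sc$key[sc$main_chain < 0.5 * median(sc$main_chain)]))
  # skipped in the first cycle
  out1 <- prune_residues_and_sidechains(m, sc, cycle_index = 1, d_min = 2.0)
  expect_length(out1$removed_residues, 0)
  expect_equal(mxbuild:::n_residues(out1$model), 100)
  # skipped when the data stop at 2.5 A
  out2 <- prune_residues_and_sidechains(m, sc, cycle_index = 2, d_min = 2.5)
  expect_length(out2$removed_residues, 0)
})

test_that("side-chain truncation keeps backbone plus C-beta", {
  cell <- unit_cell(30, 30, 30)
  arg_atoms <- c("N", "CA", "C", "O", "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2")
  atoms <- do.call(rbind, lapply(1:10, function(i) data.frame(
    chain = "A", seqnum = i, icode = "", resname = "ARG", atom = arg_atoms,
    element = substr(arg_atoms, 1, 1), x = i * 2, y = seq_along(arg_atoms),
    z = 5, occ = 1, b = 20)))
  m <- structure_model(cell, "P1", atoms)
  sc <- uniform_scores(m, main_chain = 0.9,
                       side_chain = c(0.05, rep(0.9, 9)))
  out <- prune_residues_and_sidechains(m, sc, cycle_index = 3, d_min = 1.8)
  expect_length(out$removed_residues, 0)
  expect_identical(out$removed_sidechains, "A|1|")
  kept <- out$model$atoms[out$model$atoms$seqnum == 1, "atom"]
  expect_setequal(kept, c("N", "CA", "C", "O", "CB"))
  full <- out$model$atoms[out$model$atoms$seqnum == 2, "atom"]
  expect_setequal(full, arg_atoms)
})

test_that("pruning rules agree with a brute-force re-implementation on random scores", {
  set.seed(123)
  for (rep in 1:60) {
    n <- sample(10:60, 1)
    m <- ca_chain_model(list(A = n))
    mc <- runif(n)
    sc <- uniform_scores(m, main_chain = mc)
    out <- prune_residues_and_sidechains(m, sc, cycle_index = 2, d_min = 2.0,
                                         factor = 0.5, cap = 0.2)
    # brute force: threshold, sort, cap
    med <- median(mc)
    victims <- which(mc < 0.5 * med)
    victims <- victims[order(mc[victims], victims)]
    victims <- victims[seq_len(min(length(victims), floor(0.2 * n)))]
    expect_identical(sort(out$removed_residues),
                     sort(sc$key[victims]), label = paste("rep", rep))
    expect_lte(length(out$removed_residues), floor(0.2 * n))
    # determinism: a repeat call returns the identical removal set
    out_again <- prune_residues_and_sidechains(m, sc, cycle_index = 2,
                                               d_min = 2.0, factor = 0.5,
                                               cap = 0.2)
    expect_identical(out_again$removed_residues, out$removed_residues)
  }
})

test_that("side-chain rebuild selection combines score and missing-atom criteria", {
  cell <- unit_cell(30, 30, 30)
  arg_atoms <- c("N", "CA", "C", "O", "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2")
  mk_res <- function(i, atoms) data.frame(
    chain = "A", seqnum = i, icode = "", resname = "ARG", atom = atoms,
    element = substr(atoms, 1, 1), x = i * 2.5, y = seq_along(atoms), z = 5,
    occ = 1, b = 20)
  m <- structure_model(cell, "P1", rbind(
    mk_res(1, arg_atoms), mk_res(2, arg_atoms), mk_res(3, arg_atoms),
    mk_res(4, c("N", "CA", "C", "O", "CB"))))  # residue 4 lacks its side chain
  # medians: sc 0.60, mc 0.80 (even-count medians by construction)
  sc <- uniform_scores(m, main_chain = c(0.90, 0.10, 0.70, 0.90),
                       side_chain = c(0.10, 0.10, 0.90, 0.90))
  expect_equal(median_score(sc, "side_chain"), 0.5)
  expect_equal(median_score(sc, "main_chain"), 0.8)
  out <- select_sidechain_rebuilds(m, sc)
  # residue 1: sc 0.10 < 0.125 and mc 0.90 > 0.20 -> selected
  # residue 2: mc too poor -> not selected on scores
  # residue 4: missing atoms -> selected regardless of scores
  expect_true("A|1|" %in% out)
  expect_false("A|2|" %in% out)
  expect_false("A|3|" %in% out)
  expect_true("A|4|" %in% out)
  # GLY/ALA are never selected
  m_ala <- ca_chain_model(list(A = 4))
  sc_ala <- uniform_scores(m_ala, main_chain = 0.9, side_chain = 0.01)
  expect_length(select_sidechain_rebuilds(m_ala, sc_ala), 0)
})

test_that("seed selection drops LLK outliers then takes every third survivor", {
  m <- ca_chain_model(list(A = 9))
  sc <- uniform_scores(m, main_chain = 0.9, llk = 5.0)
  seeds <- select_seed_residues(m, sc)
  expect_identical(seeds, c("A|1|", "A|4|", "A|7|"))
  # 100 good + 1 outlier: mean 3.96, sd 10.45, cutoff -16.9 -> outlier dropped
  m2 <- ca_chain_model(list(A = 101))
  llk <- c(rep(5, 100), -100)
  sc2 <- uniform_scores(m2, main_chain = 0.9, llk = llk)
  seeds2 <- select_seed_residues(m2, sc2)
  expect_length(seeds2, 34)        # ceiling(100 / 3)
  expect_false("A|101|" %in% seeds2)
  # independent check of the filter itself
  expect_equal(mean(llk), 400 / 101)
  cutoff <- mean(llk) - 2 * sd(llk)
  expect_true(-100 < cutoff && all(rep(5, 100) >= cutoff))
  # empty model
  m0 <- structure_model(unit_cell(10, 10, 10), "P1")
  expect_length(select_seed_residues(m0, sc), 0)
})

test_that("scores survive the JSON round trip", {
  m <- ca_chain_model(list(A = 5))
  sc <- make_scores(m, seed = 3)
  path <- tempfile(fileext = ".json")
  write_scores(sc, path)
  sc2 <- read_scores(path)
  expect_equal(sc2$main_chain, sc$main_chain, tolerance = 1e-12)
  expect_equal(sc2$llk, sc$llk, tolerance = 1e-12)
  expect_identical(sc2$key, sc$key)
})
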