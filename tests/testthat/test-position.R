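# Frequency records, the conservation law, history harvesting, and the
# message-passing position model.

test_that("update_frequency increments the position and its neighborhood", {
  path3 <- parse_molecule("CCO")           # A-B-C chain
  r <- frequency_record(path3)
  expect_equal(update_frequency(r, 2)$counts, c(1L, 1L, 1L))
  expect_equal(update_frequency(r, 1)$counts, c(1L, 1L, 0L))
  r1 <- frequency_record(parse_molecule("C"))
  expect_equal(update_frequency(r1, 1)$counts, 1L)
  expect_error(update_frequency(r, 9), "index")
})

test_that("frequency conservation: sum of counts equals sum of (deg+1)", {
  rng <- rng_stream(31)
  for (m in list(fx$fragments$aspirin, fx$named$cyclopentane,
                 fx$named$n_hexane)) {
    r <- frequency_record(m)
    deg <- atom_degree(m)
    expected <- 0L
    for (i in 1:25) {
      pos <- stream_index(rng, n_atoms(m))
      r <- update_frequency(r, pos)
      expected <- expected + deg[pos] + 1L
      expect_equal(sum(r$counts), expected)
    }
  }
})

test_that("transfer_frequency does exact index bookkeeping", {
  m <- parse_molecule("CCO")
  r <- frequency_record(m, c(2L, 3L, 1L))
  # insertion at atom 1: counts carried, one appended 0, then increment
  # at position 1 and its child neighborhood
  p_ins <- Filter(function(p) p$action$kind == "insertion",
                  enumerate_edits(m, 1))[[1]]
  r2 <- transfer_frequency(r, p_ins)
  deg_child_at1 <- atom_degree(p_ins$result)[1]
  expect_length(r2$counts, 4L)
  expect_equal(sum(r2$counts), sum(r$counts) + deg_child_at1 + 1L)
  expect_equal(r2$counts[3], r$counts[3])  # untouched O keeps its value

  # deletion of the terminal O: surviving atoms keep their entries
  p_del <- Filter(function(p) p$action$kind == "deletion",
                  enumerate_edits(m, 3))[[1]]
  r3 <- transfer_frequency(r, p_del)
  expect_equal(r3$counts, r$counts[p_del$atom_map])
  expect_length(r3$counts, n_atoms(p_del$result))

  # replacement keeps length; increment applied at the edited atom
  p_rep <- Filter(function(p) p$action$kind == "replacement",
                  enumerate_edits(m, 2))[[1]]
  r4 <- transfer_frequency(r, p_rep)
  expect_length(r4$counts, 3L)
  expect_equal(sum(r4$counts), sum(r$counts) + atom_degree(m)[2] + 1L)

  # mismatched parent is an internal error
  expect_error(transfer_frequency(frequency_record(fx$named$benzene), p_ins),
               "internal")
})

test_that("harvest_history collects conserving records deterministically", {
  spec <- objective_spec(surrogate_dock(fx$profiles$two_ring))
  sched <- anneal_schedule(n_steps = 40)
  h0 <- harvest_history(fx$named$n_hexane, spec, sched, n_runs = 0, seed = 1)
  expect_length(h0$records, 0L)

  h <- harvest_history(fx$named$n_hexane, spec, sched, n_runs = 2, seed = 7)
  expect_gt(length(h$records), 0L)
  for (r in h$records) {
    expect_length(r$counts, n_atoms(r$molecule))
    expect_true(all(r$counts >= 0L))
  }
  h2 <- harvest_history(fx$named$n_hexane, spec, sched, n_runs = 2, seed = 7)
  expect_identical(
    lapply(h$records, `[[`, "counts"),
    lapply(h2$records, `[[`, "counts"))

  # round-trips through the JSON-lines serialization
  pth <- withr::local_tempfile(fileext = ".jsonl")
  write_history(h, pth)
  back <- read_history(pth)
  expect_equal(length(back$records), length(h$records))
  expect_equal(back$records[[1]]$counts, h$records[[1]]$counts)
})

test_that("a ring-rewarding objective concentrates harvested edits on ring atoms", {
  # docking surrogate that pays for substituents attached to ring atoms
  # and penalizes chain atoms, so chain edits are mostly rejected while
  # ring edits are accepted
  ring_decor <- dock_scorer(function(mol) {
    inr <- atom_in_ring(mol)
    deg <- atom_degree(mol)
    sum(pmax(0, deg[inr] - 2)) - 0.6 * sum(!inr)
  }, orientation = "higher_better")
  spec <- objective_spec(ring_decor, alpha = 1, beta = 0, gamma = 0, delta = 0.3)
  sched <- anneal_schedule(t_init = 0.2, t_min = 0.05, n_steps = 30)
  tol <- parse_molecule("CCC1CCCCC1")  # ring + short chain
  ring_mass <- 0; chain_mass <- 0
  for (run in 1:20) {
    tr <- anneal(tol, spec, sched, options = list(mode = "wo-pos"),
                 seed = 9000 + run)
    for (r in tr$history) {
      inr <- atom_in_ring(r$molecule)
      if (any(inr)) ring_mass <- ring_mass + mean(r$counts[inr])
      if (any(!inr)) chain_mass <- chain_mass + mean(r$counts[!inr])
    }
  }
  expect_gt(ring_mass, chain_mass)
})

test_that("training reduces loss and predictions are permutation-equivariant", {
  spec <- objective_spec(surrogate_dock(fx$profiles$two_ring))
  h <- harvest_history(fx$named$n_hexane, spec, anneal_schedule(n_steps = 60),
                       n_runs = 3, seed = 21)
  model <- train_position_model(h)
  # loss after fit < loss at zero initialization (predict 0 everywhere)
  y <- unlist(lapply(h$records, `[[`, "counts"))
  yhat <- unlist(lapply(h$records, function(r)
    predict_frequencies(model, r$molecule)))
  expect_lt(mean((y - yhat)^2), mean(y^2))

  # equivariance: a reindexed parse of the same molecule permutes the
  # predictions identically
  a <- parse_molecule("CC(=O)Oc1ccccc1C(O)=O")
  b <- parse_molecule("OC(=O)c1ccccc1OC(C)=O")
  pa <- sort(round(predict_frequencies(model, a), 9))
  pb <- sort(round(predict_frequencies(model, b), 9))
  expect_equal(pa, pb)

  expect_error(train_position_model(structure(list(records = list()),
                                              class = "history_dataset")),
               "data error")
})

test_that("a model trained on planted positions recovers them", {
  # history where ONLY ring atoms ever receive edits
  train_mols <- fx$fragments[c("aspirin", "paracetamol", "benzamide",
                               "toluene", "phenol")]
  records <- list()
  for (m in train_mols) {
    r <- frequency_record(m)
    ring_atoms <- which(atom_in_ring(m))
    for (pos in rep(ring_atoms, 3)) r <- update_frequency(r, pos)
    records[[length(records) + 1L]] <- r
  }
  data <- structure(list(records = records), class = "history_dataset")
  model <- train_position_model(data)
  held_out <- c(fx$fragments[c("aniline", "anisole", "ibuprofen")],
                fx$named[c("benzene", "pyridine", "cyclopentane", "furan")])
  hits <- vapply(held_out, function(m) {
    top <- predict_positions(model, m, K = 5, rng_stream(3))$candidates
    any(atom_in_ring(m)[top])
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("predict_positions honors K, ties, and the random fallback", {
  m <- fx$named$n_hexane
  # K >= n gives the full atom set
  res <- predict_positions(NULL, m, K = 99, rng_stream(4))
  expect_setequal(res$candidates, seq_len(n_atoms(m)))
  # constant predictions tie-break by ascending atom index
  cm <- structure(list(coef = rep(0, 1 + 13 * 4), layers = 3L, loss = "mse",
                       lambda = 0, architecture = "const", n_records = 0L),
                  class = "position_model")
  res2 <- predict_positions(cm, m, K = 3, rng_stream(4))
  expect_equal(res2$candidates, 1:3)
  expect_true(res2$sampled %in% res2$candidates)
  # model serialization round-trip is exact
  pth <- withr::local_tempfile(fileext = ".json")
  write_position_model(cm, pth)
  cm2 <- read_position_model(pth)
  expect_equal(cm2$coef, cm$coef)
  expect_equal(predict_frequencies(cm2, m), predict_frequencies(cm, m))
})
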