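# Temperature schedule, acceptance rule, reversible sampling, the full
# loop, and the ablation harness.

surrogate_spec <- function(delta = 0.4) {
  objective_spec(surrogate_dock(fx$profiles$two_ring), delta = delta)
}

test_that("temperature follows max(T_min, T_init/(t+1)) to machine precision", {
  sched <- anneal_schedule(t_init = 1.0, t_min = 0.05, n_steps = 10)
  expect_identical(temperature(0, sched), 1.0)
  expect_identical(temperature(9, sched), 0.1)
  expect_identical(temperature(1e6, sched), 0.05)
  ts <- unique(round(c(0:100, 10^(2:6))))
  expect_identical(temperature(ts, sched), pmax(0.05, 1.0 / (ts + 1)))
  expect_true(!is.unsorted(rev(temperature(ts, sched))))
  expect_error(anneal_schedule(t_init = 0.01, t_min = 0.05))
})

test_that("accept_probability matches the closed form on the boundary cases", {
  expect_equal(accept_probability(1, 0, 0.7), 1)       # improvement
  expect_equal(accept_probability(0, 0, 0.7), 1)       # equal score
  expect_equal(accept_probability(-0.7, 0, 0.7), exp(-1))
  expect_equal(accept_probability(-Inf, 0, 0.7), 0)    # gated candidate
  expect_equal(accept_probability(-3, 0, 2), exp(-1.5))
})

test_that("reversible_step implements the strict secondary comparison", {
  spec <- surrogate_spec(delta = 0)   # ungated: secondary edits stay finite
  x0 <- fx$named$n_hexane
  fresh <- function() list(position = rng_stream(1, "p"),
                           reversible = rng_stream(1, "r"))
  opts <- list(use_model = FALSE, K = 5L, op_weights = rep(0.25, 4),
               ring_window = 3:8, max_atoms = 30L, sampling = "uniform",
               vocab = element_vocabulary())
  x_star <- insertion(x0, 1, "C", 1)
  # identical stream state => identical secondary edit in all three calls
  # incumbent far above anything reachable: strict > can never hold
  r_hi <- reversible_step(x_star, 1e6, x0, spec, NULL, fresh(), opts)
  expect_false(r_hi$accept)
  # incumbent far below: any finite secondary wins
  r_lo <- reversible_step(x_star, -1e6, x0, spec, NULL, fresh(), opts)
  expect_true(r_lo$accept)
  expect_true(is.finite(r_lo$secondary$total))
  # equality boundary: f(secondary) == f_cur must reject
  r_eq <- reversible_step(x_star, r_lo$secondary$total, x0, spec, NULL,
                          fresh(), opts)
  expect_false(r_eq$accept)
})

test_that("N = 0 returns the start; constant objective accepts every proposal", {
  spec <- surrogate_spec()
  x0 <- fx$named$n_hexane
  tr0 <- anneal(x0, spec, anneal_schedule(n_steps = 0), seed = 1,
                options = list(mode = "origin"))
  expect_null(tr0$steps)
  expect_equal(canonical_form(tr0$best$molecule), canonical_form(x0))

  const <- objective_spec(dock_scorer(function(mol) 5, "higher_better"),
                          alpha = 1, beta = 0, gamma = 0, delta = 0)
  trc <- anneal(x0, const, anneal_schedule(n_steps = 40), seed = 2,
                options = list(mode = "origin"))
  # delta = 0 and constant dock: valid proposals all have equal score,
  # so p = 1 and every valid primary proposal is accepted
  valid_steps <- trc$steps[trc$steps$valid, ]
  expect_true(all(valid_steps$decision == "accept"))
  expect_true(all(valid_steps$p_accept == 1))
})

test_that("trajectories are reproducible and best-so-far is non-decreasing", {
  spec <- surrogate_spec()
  x0 <- fx$named$n_hexane
  sched <- anneal_schedule(n_steps = 120)
  t1 <- anneal(x0, spec, sched, options = list(mode = "wo-pos"), seed = 11)
  t2 <- anneal(x0, spec, sched, options = list(mode = "wo-pos"), seed = 11)
  expect_identical(trajectory_hash(t1), trajectory_hash(t2))
  expect_identical(t1$steps, t2$steps)
  expect_false(is.unsorted(best_so_far(t1)))
  expect_equal(t1$best$score, max(best_so_far(t1)))
  # a different seed gives a different walk
  t3 <- anneal(x0, spec, sched, options = list(mode = "wo-pos"), seed = 12)
  expect_false(identical(trajectory_hash(t1), trajectory_hash(t3)))
})

test_that("gated proposals never become the incumbent", {
  spec <- surrogate_spec(delta = 0.55)   # tight gate forces many -Inf
  x0 <- fx$named$n_hexane
  tr <- anneal(x0, spec, anneal_schedule(n_steps = 150), seed = 5,
               options = list(mode = "wo-pos"))
  accepted <- tr$steps$decision %in% c("accept", "reversible-accept")
  expect_true(all(tr$steps$valid[accepted]))
  expect_true(all(tr$steps$sim[accepted] > 0.55))
  expect_true(all(is.finite(tr$steps$f_cur)))
})

test_that("ablation modes honor their contracts", {
  spec <- surrogate_spec()
  x0 <- fx$named$n_hexane
  sched <- anneal_schedule(n_steps = 60)
  h <- harvest_history(x0, spec, sched, n_runs = 2, seed = 3)
  model <- train_position_model(h)

  tr_origin <- anneal(x0, spec, sched, options = list(mode = "origin"), seed = 4)
  expect_false(any(grepl("reversible", tr_origin$steps$decision)))
  tr_worev <- anneal(x0, spec, sched, model = model,
                     options = list(mode = "wo-reverse"), seed = 4)
  expect_false(any(grepl("reversible", tr_worev$steps$decision)))
  expect_error(anneal(x0, spec, sched, model = NULL,
                      options = list(mode = "full")), "position model")

  ab <- run_ablation(x0, spec, sched, model, seeds = 1:2)
  expect_equal(ab$summary$mode, c("full", "wo-pos", "wo-reverse", "origin"))
  expect_equal(ab$summary$n, rep(2L, 4))
  expect_true(all(is.finite(ab$scores)))
})

test_that("wo-pos mode draws positions uniformly", {
  m <- fx$fragments$aspirin                    # 13 atoms
  rng <- rng_stream(99)
  n_draw <- 10000L
  draws <- vapply(seq_len(n_draw), function(i)
    predict_positions(NULL, m, K = n_atoms(m), rng)$sampled, integer(1))
  tab <- tabulate(draws, n_atoms(m))
  chi <- sum((tab - n_draw / n_atoms(m))^2 / (n_draw / n_atoms(m)))
  # chi-square with 12 df: 0.999 quantile ~ 32.9
  expect_lt(chi, stats::qchisq(0.999, n_atoms(m) - 1))
})

test_that("trajectory serialization embeds summary metadata", {
  spec <- surrogate_spec()
  tr <- anneal(fx$named$n_hexane, spec, anneal_schedule(n_steps = 25),
               options = list(mode = "origin"), seed = 8)
  pth <- withr::local_tempfile(fileext = ".jsonl")
  write_trajectory(tr, pth, config_hash = "cafe0001")
  expect_equal(length(readLines(pth)), nrow(tr$steps))
  smry <- jsonlite::fromJSON(paste0(pth, ".summary.json"))
  expect_equal(smry$config_hash, "cafe0001")
  expect_equal(smry$seed, 8)
  expect_equal(smry$best_smiles, canonical_form(tr$best$molecule))
})
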