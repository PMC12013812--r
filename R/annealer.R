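# The simulated-annealing engine: hyperbolic temperature schedule,
# Metropolis acceptance, the reversible sampling strategy (a rejected
# candidate earns one secondary edit; if that secondary edit beats the
# incumbent, the ORIGINAL candidate is accepted), and the full
# single-walker loop producing trajectories and best-found molecules.

#' Annealing schedule
#'
#' @param t_init initial temperature (> 0).
#' @param t_min floor temperature (0 < t_min <= t_init).
#' @param n_steps iteration budget (>= 0).
#' @return object of class `anneal_schedule`.
#' @export
anneal_schedule <- function(t_init = 1.0, t_min = 0.05, n_steps = 500L) {
  stopifnot(t_init > 0, t_min > 0, t_min <= t_init, n_steps >= 0)
  structure(list(t_init = t_init, t_min = t_min, n_steps = as.integer(n_steps)),
            class = "anneal_schedule")
}

#' Temperature at step t
#'
#' `max(T_min, T_init / (t + 1))`: hyperbolic cooling with a floor;
#' non-increasing in t.
#'
#' @param t step index (>= 0).
#' @param sched an [anneal_schedule()].
#' @return numeric temperature.
#' @export
temperature <- function(t, sched) {
  stopifnot(all(t >= 0))
  pmax(sched$t_min, sched$t_init / (t + 1))
}

#' Metropolis acceptance probability
#'
#' `min(1, exp((f_new - f_cur) / T))`; a `-Inf` candidate has acceptance
#' probability exactly 0, so gated-out molecules are never sampled.
#'
#' @param f_new candidate objective value (may be `-Inf`).
#' @param f_cur incumbent objective value (finite).
#' @param T temperature (> 0).
#' @return probability in `[0,1]`.
#' @export
accept_probability <- function(f_new, f_cur, T) {
  stopifnot(T > 0, is.finite(f_cur))
  if (f_new == -Inf) return(0)
  min(1, exp((f_new - f_cur) / T))
}

# one position draw honoring the configured mode
draw_position <- function(mol, model, use_model, K, streams, sampling) {
  predict_positions(if (use_model) model else NULL, mol, K = K,
                    rng = streams$position, sampling = sampling)$sampled
}

#' One reversible-sampling decision
#'
#' Invoked only after the primary Metropolis draw rejected `x_star`: a
#' secondary position is predicted on `x_star`, one secondary edit
#' `x'_*` is sampled and scored, and iff `f(x'_*) > f_cur` (strictly)
#' the decision is to accept `x_star` itself (not `x'_*`). Any failure
#' to produce a valid secondary edit counts as a rejection.
#'
#' @param x_star the rejected candidate (`molgraph`).
#' @param f_cur incumbent objective value.
#' @param x0 original starting fragment (similarity anchor).
#' @param spec an [objective_spec()].
#' @param model a `position_model` or `NULL` for random positions.
#' @param streams named rng streams (position, payload, reversible).
#' @param options annealer options (K, op_weights, ring_window,
#'   max_atoms, sampling).
#' @return list: `accept` (logical), `secondary` (breakdown or NULL).
#' @export
reversible_step <- function(x_star, f_cur, x0, spec, model, streams, options) {
  pos <- tryCatch(
    draw_position(x_star, model, options$use_model, options$K, streams,
                  options$sampling),
    error = function(e) NULL)
  if (is.null(pos)) return(list(accept = FALSE, secondary = NULL))
  sec <- tryCatch(
    propose(x_star, pos, options$op_weights, streams$reversible,
            vocab = options$vocab, ring_window = options$ring_window,
            max_atoms = options$max_atoms),
    error = function(e) NULL)
  if (is.null(sec)) return(list(accept = FALSE, secondary = NULL))
  x0_fp <- options$x0_fp %||% morgan_fingerprint(x0)
  b <- objective_cached(sec$result, x0_fp, spec)
  list(accept = is.finite(b$total) && b$total > f_cur, secondary = b)
}

default_options <- function(options, mol) {
  o <- options
  o$mode <- o$mode %||% "full"
  stopifnot(o$mode %in% c("full", "wo-pos", "wo-reverse", "origin"))
  o$K <- o$K %||% 5L
  o$op_weights <- o$op_weights %||% rep(0.25, 4)
  o$ring_window <- o$ring_window %||% 3:8
  o$max_atoms <- o$max_atoms %||% 60L
  o$vocab <- o$vocab %||% element_vocabulary()
  o$sampling <- o$sampling %||% "uniform"
  o$max_position_tries <- o$max_position_tries %||% max(4L, n_atoms(mol))
  o$use_model <- o$mode %in% c("full", "wo-reverse")
  o$reversible <- o$mode %in% c("full", "wo-pos")
  o
}

#' Run one annealing trajectory
#'
#' The full loop: position draw (predictor or uniform), one sampled edit,
#' gated scoring, Metropolis acceptance at the scheduled temperature,
#' and — when enabled — the reversible secondary-edit rescue on
#' rejection. The similarity gate always compares to the ORIGINAL `x0`.
#' Fully reproducible from `seed` via named substreams.
#'
#' @param x0 starting `molgraph`; its objective must be finite.
#' @param spec an [objective_spec()].
#' @param sched an [anneal_schedule()].
#' @param model a `position_model`, or `NULL` (required for modes that
#'   use the predictor).
#' @param options list: `mode` ("full", "wo-pos", "wo-reverse",
#'   "origin"), `K`, `op_weights`, `ring_window`, `max_atoms`,
#'   `sampling`, `collect_history`.
#' @param seed integer seed.
#' @return object of class `trajectory`: `steps` (data.frame), `best`
#'   (molecule, score, breakdown, step), `history` (frequency records of
#'   accepted states), `stuck`, `seed`, `mode`.
#' @export
anneal <- function(x0, spec, sched, model = NULL, options = list(), seed = 1L) {
  options <- default_options(options, x0)
  if (options$use_model && is.null(model)) {
    stop("mode '", options$mode, "' needs a position model", call. = FALSE)
  }
  b0 <- objective(x0, x0, spec)
  if (!is.finite(b0$total)) {
    stop("starting fragment fails its own objective gate", call. = FALSE)
  }
  # named substreams keep ablation modes variance-paired: disabling one
  # component does not shift any other component's draws
  streams <- list(
    position = rng_stream(seed, "position"),
    payload = rng_stream(seed, "payload"),
    metropolis = rng_stream(seed, "metropolis"),
    reversible = rng_stream(seed, "reversible")
  )
  cur <- x0
  f_cur <- b0$total
  cur_smi <- canonical_form(x0)
  options$x0_fp <- morgan_fingerprint(x0)
  freq <- frequency_record(x0)
  history <- list()
  best <- list(molecule = x0, score = f_cur, breakdown = b0, step = 0L)
  n_steps <- sched$n_steps
  # column accumulators (a data.frame per step is needless overhead)
  col <- list(t = integer(n_steps), temperature = numeric(n_steps),
              incumbent = character(n_steps), proposal = character(n_steps),
              operator = character(n_steps), position = integer(n_steps),
              f_cur = numeric(n_steps), f_new = numeric(n_steps),
              p_accept = numeric(n_steps), sim = numeric(n_steps),
              valid = logical(n_steps), decision = character(n_steps))
  done <- 0L
  stuck <- FALSE
  for (t in seq_len(n_steps) - 1L) {
    T <- temperature(t, sched)
    # draw a position with a valid edit (re-sample on no-edit positions)
    prop <- NULL; pos <- NA_integer_
    for (try in seq_len(options$max_position_tries)) {
      pos_try <- draw_position(cur, model, options$use_model, options$K,
                               streams, options$sampling)
      prop <- tryCatch(
        propose(cur, pos_try, options$op_weights, streams$payload,
                vocab = options$vocab, ring_window = options$ring_window,
                max_atoms = options$max_atoms),
        error = function(e) NULL)
      if (!is.null(prop)) { pos <- pos_try; break }
    }
    if (is.null(prop)) { stuck <- TRUE; break }
    b_new <- objective_cached(prop$result, options$x0_fp, spec)
    p_acc <- accept_probability(b_new$total, f_cur, T)
    u <- stream_runif(streams$metropolis)
    decision <- "reject"
    if (u <= p_acc && p_acc > 0) {
      decision <- "accept"
    } else if (options$reversible && is.finite(b_new$total)) {
      # gated (-Inf) candidates are never rescued: an invalid molecule
      # must not become the incumbent
      rev <- reversible_step(prop$result, f_cur, x0, spec, model, streams,
                             options)
      decision <- if (rev$accept) "reversible-accept" else "reversible-reject"
    }
    accepted <- decision %in% c("accept", "reversible-accept")
    done <- done + 1L
    prop_smi <- canonical_form(prop$result)
    col$t[done] <- t; col$temperature[done] <- T
    col$incumbent[done] <- cur_smi; col$proposal[done] <- prop_smi
    col$operator[done] <- prop$action$kind; col$position[done] <- pos
    col$f_cur[done] <- f_cur; col$f_new[done] <- b_new$total
    col$p_accept[done] <- p_acc; col$sim[done] <- b_new$sim
    col$valid[done] <- b_new$valid; col$decision[done] <- decision
    if (accepted) {
      freq <- transfer_frequency(freq, prop)
      cur <- prop$result
      cur_smi <- prop_smi
      f_cur <- b_new$total
      history[[length(history) + 1L]] <- freq
      if (f_cur > best$score) {
        best <- list(molecule = cur, score = f_cur, breakdown = b_new,
                     step = t + 1L)
      }
    }
  }
  steps_df <- if (done) {
    as.data.frame(lapply(col, function(v) v[seq_len(done)]),
                  stringsAsFactors = FALSE)
  } else NULL
  structure(list(steps = steps_df, best = best, history = history,
                 stuck = stuck, seed = seed, mode = options$mode, x0 = x0),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  ns <- if (is.null(x$steps)) 0L else nrow(x$steps)
  cat(sprintf("<trajectory> mode=%s seed=%s steps=%d best=%.4f @%d (%s)\n",
              x$mode, x$seed, ns, x$best$score, x$best$step,
              canonical_form(x$best$molecule)))
  invisible(x)
}

#' Serialize a trajectory as JSON-lines plus a summary
#'
#' One JSON object per step, then writes `<path>.summary.json` with the
#' best molecule, score breakdown, step index tau, config hash and seed.
#'
#' @param traj a `trajectory`.
#' @param path output JSON-lines path.
#' @param config_hash optional config fingerprint to embed.
#' @export
write_trajectory <- function(traj, path, config_hash = "") {
  if (!is.null(traj$steps)) {
    lines <- vapply(seq_len(nrow(traj$steps)), function(i) {
      r <- as.list(traj$steps[i, ])
      r$f_new <- if (is.finite(r$f_new)) r$f_new else "-Inf"
      jsonlite::toJSON(r, auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path)
  } else writeLines(character(0), path)
  b <- traj$best$breakdown
  jsonlite::write_json(
    list(best_smiles = canonical_form(traj$best$molecule),
         best_score = traj$best$score,
         breakdown = list(dock = b$dock, syn = b$syn, qed = b$qed,
                          sim = b$sim),
         tau = traj$best$step, mode = traj$mode,
         config_hash = config_hash, seed = traj$seed),
    paste0(path, ".summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Deterministic fingerprint of a trajectory log
#' @param traj a `trajectory`.
#' @return 8-hex-digit hash of the serialized step log.
#' @export
trajectory_hash <- function(traj) {
  if (is.null(traj$steps)) return(content_hash(""))
  txt <- apply(traj$steps, 1, paste, collapse = "|")
  content_hash(paste(txt, collapse = "\n"))
}

#' Best-so-far score series
#' @param traj a `trajectory`.
#' @return numeric vector: running maximum of the incumbent score.
#' @export
best_so_far <- function(traj) {
  if (is.null(traj$steps)) return(numeric(0))
  cummax(traj$steps$f_cur)
}

#' Ablation comparison across framework variants
#'
#' Runs the annealer in each requested mode over a common set of seeds
#' (variance-paired through the named substreams) and tabulates the
#' distribution of best scores, mirroring the ablation-table layout:
#' full = predictor + reversible, wo-pos = random positions + reversible,
#' wo-reverse = predictor only, origin = neither.
#'
#' @param x0 starting `molgraph`.
#' @param spec an [objective_spec()].
#' @param sched an [anneal_schedule()].
#' @param model a `position_model` (needed by full / wo-reverse).
#' @param modes subset of the four mode names.
#' @param seeds integer vector of seeds.
#' @param options extra [anneal()] options.
#' @return list: `summary` data.frame (mode, mean, median, sd, n) and
#'   `scores` (mode x seed matrix), plus `trajectories`.
#' @export
run_ablation <- function(x0, spec, sched, model = NULL,
                         modes = c("full", "wo-pos", "wo-reverse", "origin"),
                         seeds = 1:20, options = list()) {
  scores <- matrix(NA_real_, length(modes), length(seeds),
                   dimnames = list(modes, as.character(seeds)))
  trajs <- list()
  for (mi in seq_along(modes)) {
    for (si in seq_along(seeds)) {
      opts <- options
      opts$mode <- modes[mi]
      tr <- anneal(x0, spec, sched,
                   model = if (modes[mi] %in% c("full", "wo-reverse")) model else NULL,
                   options = opts, seed = seeds[si])
      scores[mi, si] <- tr$best$score
      trajs[[paste(modes[mi], seeds[si], sep = "/")]] <- tr
    }
  }
  summary <- data.frame(
    mode = modes,
    mean = apply(scores, 1, mean),
    median = apply(scores, 1, stats::median),
    sd = apply(scores, 1, stats::sd),
    n = length(seeds),
    stringsAsFactors = FALSE
  )
  list(summary = summary, scores = scores, trajectories = trajs)
}
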