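# History-guided editing-position prediction. During random-position
# annealing runs we record per-atom editing frequencies (the selected
# position and its graph neighbors are incremented each accepted edit),
# then fit a message-passing node regressor on those counts and propose
# top-K positions at generation time. Random selection is exactly the
# degenerate case K = n.

#' Create an atomic editing-frequency record
#'
#' One counts entry per atom, aligned to atom indices.
#'
#' @param mol a `molgraph`.
#' @param counts optional non-negative integer vector (defaults to 0).
#' @return object of class `frequency_record`.
#' @export
frequency_record <- function(mol, counts = NULL) {
  n <- n_atoms(mol)
  if (is.null(counts)) counts <- integer(n)
  counts <- as.integer(counts)
  stopifnot(length(counts) == n, all(counts >= 0L))
  structure(list(molecule = mol, counts = counts), class = "frequency_record")
}

#' Increment editing frequencies at a position
#'
#' The selected position and every one of its graph neighbors are
#' incremented by exactly one; all other entries are unchanged.
#'
#' @param record a [frequency_record()].
#' @param pos edited atom index.
#' @return the updated `frequency_record`.
#' @export
update_frequency <- function(record, pos) {
  mol <- record$molecule
  pos <- check_pos(mol, pos)
  nb <- neighbor_list(mol)$nb[[pos]]
  counts <- record$counts
  counts[c(pos, nb)] <- counts[c(pos, nb)] + 1L
  frequency_record(mol, counts)
}

#' Carry frequencies across an edit
#'
#' Maps the parent's counts onto the child molecule through the edit's
#' atom index map: surviving atoms keep their values, inserted atoms
#' start at zero, deleted atoms' entries are dropped (restricted to the
#' sampled component). The edited position is then incremented in the
#' child per the usual neighborhood rule; deletions have no surviving
#' edited atom, so no increment is applied there.
#'
#' @param record the parent's `frequency_record`.
#' @param edit an `edit_proposal` whose `parent` equals the record's
#'   molecule.
#' @return the child's `frequency_record`.
#' @export
transfer_frequency <- function(record, edit) {
  p <- edit$parent; m <- record$molecule
  if (!identical(m$element, p$element) || !identical(m$bond_i, p$bond_i) ||
      !identical(m$bond_j, p$bond_j) || !identical(m$bond_o, p$bond_o)) {
    stop("internal error: record/edit molecule mismatch", call. = FALSE)
  }
  map <- edit$atom_map
  child <- edit$result
  if (length(map) != n_atoms(child)) {
    stop("internal error: atom map length mismatch", call. = FALSE)
  }
  counts <- ifelse(is.na(map), 0L, record$counts[map])
  rec <- frequency_record(child, as.integer(counts))
  if (!is.na(edit$edited_child_pos)) {
    rec <- update_frequency(rec, edit$edited_child_pos)
  }
  rec
}

#' Harvest a frequency-history dataset from random-position runs
#'
#' Runs `n_runs` annealing trajectories in random-position (wo-pos) mode
#' and collects the (accepted molecule, counts) pairs tracked along each
#' chain. Deterministic given `seed`.
#'
#' @param x0 starting `molgraph` (or list of them, cycled over runs).
#' @param spec an [objective_spec()].
#' @param sched an [anneal_schedule()].
#' @param n_runs number of trajectories.
#' @param seed integer base seed.
#' @param options forwarded to [anneal()] (mode is forced to "wo-pos").
#' @return object of class `history_dataset`: list of
#'   `frequency_record`s.
#' @export
harvest_history <- function(x0, spec, sched, n_runs, seed = 1L,
                            options = list()) {
  starts <- if (inherits(x0, "molgraph")) list(x0) else x0
  records <- list()
  if (n_runs >= 1L) {
    for (r in seq_len(n_runs)) {
      options$mode <- "wo-pos"
      traj <- anneal(starts[[((r - 1L) %% length(starts)) + 1L]], spec, sched,
                     model = NULL, options = options,
                     seed = sub_seed(seed, paste0("harvest", r)))
      records <- c(records, traj$history)
    }
  }
  structure(list(records = records), class = "history_dataset")
}

#' Serialize a history dataset as JSON-lines
#' @param data a `history_dataset`.
#' @param path output file.
#' @export
write_history <- function(data, path) {
  lines <- vapply(data$records, function(r) {
    jsonlite::toJSON(list(smiles = canonical_form(r$molecule),
                          counts = r$counts), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a history dataset from JSON-lines
#' @param path file written by [write_history()].
#' @return a `history_dataset`.
#' @export
read_history <- function(path) {
  lines <- readLines(path, warn = FALSE)
  records <- lapply(lines, function(ln) {
    x <- jsonlite::fromJSON(ln)
    frequency_record(parse_molecule(x$smiles), as.integer(x$counts))
  })
  structure(list(records = records), class = "history_dataset")
}

## ---------------------------------------------------------------------
## Node features and the position model

# per-atom base features: element one-hot, degree, implicit H, ring flag,
# bond-order sum, aromatic flag
node_base_features <- function(mol) {
  n <- n_atoms(mol)
  per <- perceive_aromatic(mol)
  onehot <- matrix(0, n, length(.ELEMENTS))
  onehot[cbind(seq_len(n), match(mol$element, .ELEMENTS))] <- 1
  cbind(onehot, atom_degree(mol), implicit_h(mol),
        as.numeric(atom_in_ring(mol)), bond_order_sum(mol),
        as.numeric(per$arom))
}

# GIN-style propagation: h_l = h_{l-1} + A_w h_{l-1}, with bond-order
# edge weights (aromatic = 1.5); returns concatenated layer outputs
node_features <- function(mol, layers = 3L) {
  h <- node_base_features(mol)
  n <- n_atoms(mol)
  per <- perceive_aromatic(mol)
  w <- ifelse(per$order == 4L, 1.5, per$order)
  A <- matrix(0, n, n)
  if (length(mol$bond_i)) {
    A[cbind(mol$bond_i, mol$bond_j)] <- w
    A[cbind(mol$bond_j, mol$bond_i)] <- w
  }
  out <- h
  for (l in seq_len(layers)) {
    h <- h + A %*% h
    out <- cbind(out, h)
  }
  out
}

#' Train the editing-position model
#'
#' Fits a message-passing node regressor: graph-isomorphism-style sum
#' aggregation over `layers` rounds produces permutation-equivariant
#' per-atom features, and a penalized linear (ridge, default) or Poisson
#' readout regresses the editing frequencies. Deterministic given the
#' dataset and config.
#'
#' @param data a `history_dataset` with at least one record.
#' @param config list: `layers` (default 3), `lambda` ridge penalty
#'   (default 1e-2), `loss` "mse" or "poisson".
#' @return object of class `position_model`.
#' @export
train_position_model <- function(data, config = list()) {
  if (!length(data$records)) stop("data error: empty history dataset", call. = FALSE)
  layers <- config$layers %||% 3L
  lambda <- config$lambda %||% 1e-2
  loss <- config$loss %||% "mse"
  X <- do.call(rbind, lapply(data$records, function(r)
    node_features(r$molecule, layers)))
  y <- unlist(lapply(data$records, `[[`, "counts"))
  X <- cbind(1, X)
  p <- ncol(X)
  coef <- NULL
  if (loss == "poisson") {
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X, y, family = stats::poisson())),
      error = function(e) NULL)
    if (!is.null(fit) && all(is.finite(stats::coef(fit)))) coef <- stats::coef(fit)
  }
  if (is.null(coef)) {
    loss <- "mse"
    pen <- diag(lambda, p); pen[1, 1] <- 0
    coef <- solve(crossprod(X) + pen, crossprod(X, y))[, 1]
  }
  structure(list(coef = coef, layers = layers, loss = loss, lambda = lambda,
                 architecture = sprintf("gin-linear/L%d/%s", layers, loss),
                 n_records = length(data$records)),
            class = "position_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict per-atom editing frequencies
#' @param model a `position_model`.
#' @param mol a `molgraph`.
#' @return numeric vector, one predicted frequency per atom.
#' @export
predict_frequencies <- function(model, mol) {
  X <- cbind(1, node_features(mol, model$layers))
  eta <- as.numeric(X %*% model$coef)
  if (model$loss == "poisson") exp(eta) else eta
}

#' Propose top-K editing positions and sample one
#'
#' L_t is the set of the K atoms with the highest predicted frequencies
#' (ties broken by ascending atom index); l_t is drawn from L_t,
#' uniformly by default or softmax-weighted by predicted score. K is
#' capped at the atom count, so K >= n is exactly random selection over
#' all atoms.
#'
#' @param model a `position_model`, or `NULL` for the random-position
#'   fallback (all atoms, uniform).
#' @param mol a `molgraph`.
#' @param K candidate-set size (>= 1).
#' @param rng an [rng_stream()].
#' @param sampling "uniform" or "softmax".
#' @return list: `candidates` (L_t, in rank order) and `sampled` (l_t).
#' @export
predict_positions <- function(model, mol, K = 5L, rng,
                              sampling = c("uniform", "softmax")) {
  sampling <- match.arg(sampling)
  n <- n_atoms(mol)
  stopifnot(K >= 1L)
  if (is.null(model)) {
    cand <- seq_len(n)
  } else {
    pred <- predict_frequencies(model, mol)
    ord <- order(-pred, seq_len(n))
    cand <- ord[seq_len(min(K, n))]
  }
  if (sampling == "softmax" && !is.null(model)) {
    sc <- predict_frequencies(model, mol)[cand]
    p <- exp(sc - max(sc))
    k <- stream_categorical(rng, p)
  } else {
    k <- stream_index(rng, length(cand))
  }
  list(candidates = cand, sampled = cand[k])
}

#' Save / load a position model with its architecture manifest
#' @param model a `position_model`.
#' @param path JSON file path.
#' @export
write_position_model <- function(model, path) {
  jsonlite::write_json(list(coef = model$coef, layers = model$layers,
                            loss = model$loss, lambda = model$lambda,
                            architecture = model$architecture,
                            n_records = model$n_records),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_position_model
#' @param path JSON file path.
#' @return a `position_model`.
#' @export
read_position_model <- function(path) {
  x <- jsonlite::fromJSON(path)
  structure(list(coef = as.numeric(x$coef), layers = as.integer(x$layers),
                 loss = x$loss, lambda = x$lambda,
                 architecture = x$architecture, n_records = x$n_records),
            class = "position_model")
}
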