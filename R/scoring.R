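# Gated multi-property objective: f_p = alpha*f_Dock + beta*f_syn +
# gamma*f_QED, gated by Validity = f_g(x*) * 1{f_sim(x*, x0) > delta};
# invalid candidates score -Inf so they can never win an acceptance
# comparison. Docking scorers are pluggable; a deterministic surrogate
# keeps the whole framework testable offline.

#' Molecular feature counts used by the surrogate docking profile
#'
#' Heavy-atom count, ring count (cyclomatic), hydrogen-bond donors
#' (N/O with at least one implicit H) and acceptors (any N/O).
#'
#' @param mol a `molgraph`.
#' @return named numeric vector: heavy, rings, hbd, hba.
#' @export
feature_counts <- function(mol) {
  nh <- implicit_h(mol)
  no <- mol$element %in% c("N", "O")
  c(heavy = n_atoms(mol),
    rings = ring_count(mol),
    hbd = sum(no & nh > 0L),
    hba = sum(no))
}

#' Count rotatable bonds
#'
#' Acyclic single bonds between two non-terminal heavy atoms.
#'
#' @param mol a `molgraph`.
#' @return integer count.
#' @export
rotatable_bonds <- function(mol) {
  if (!length(mol$bond_i)) return(0L)
  deg <- atom_degree(mol)
  ring <- bond_in_ring(mol)
  sum(mol$bond_o == 1L & !ring &
        deg[mol$bond_i] > 1L & deg[mol$bond_j] > 1L)
}

# Gaussian desirability, 1 at mu
desir <- function(x, mu, sigma) exp(-((x - mu)^2) / (2 * sigma^2))

#' Drug-likeness score (QED-style composite)
#'
#' A lightweight quantitative-drug-likeness analogue: the geometric mean
#' of Gaussian desirability functions over molecular weight, H-bond
#' donors/acceptors, ring count and rotatable bonds, in `[0,1]`. It is
#' not RDKit's fitted QED (no R toolkit provides one) but preserves the
#' contract: bounded, higher for balanced drug-like profiles.
#'
#' @param mol a `molgraph`.
#' @return numeric in `[0,1]`.
#' @export
qed_score <- function(mol) {
  fc <- feature_counts(mol)
  ds <- c(
    desir(mol_weight(mol), 300, 130),
    desir(fc[["hbd"]], 1.5, 2.0),
    desir(fc[["hba"]], 3.5, 3.0),
    desir(fc[["rings"]], 2.5, 1.8),
    desir(rotatable_bonds(mol), 4.5, 3.5)
  )
  unname(exp(mean(log(pmax(ds, 1e-12)))))
}

#' Synthetic-accessibility heuristic (1 easy .. 10 hard)
#'
#' Size, ring complexity (counts beyond two rings, uncommon ring sizes,
#' ring-fusion atoms), heteroatom load and triple bonds each add
#' difficulty. A lightweight stand-in for the fragment-contribution SA
#' score; clamped to `[1,10]`.
#'
#' @param mol a `molgraph`.
#' @return numeric in `[1,10]`.
#' @export
sa_heuristic <- function(mol) {
  n <- n_atoms(mol)
  rc <- ring_count(mol)
  # ring sizes via smallest-ring scan on ring bonds
  ring <- bond_in_ring(mol)
  odd_ring_pen <- 0
  if (any(ring)) {
    for (k in which(ring)) {
      sz <- graph_distance(mol, mol$bond_i[k], mol$bond_j[k],
                           skip_bond = c(mol$bond_i[k], mol$bond_j[k])) + 1L
      if (is.finite(sz) && (sz < 5L || sz > 6L)) odd_ring_pen <- odd_ring_pen + 0.25
    }
  }
  deg <- atom_degree(mol)
  inr <- atom_in_ring(mol)
  fusion <- sum(inr & deg >= 3L & vapply(seq_len(n), function(i) {
    sum(inr[neighbor_list(mol)$nb[[i]]]) >= 3L
  }, logical(1)))
  hetero <- mean(!(mol$element %in% "C"))
  s <- 1 +
    0.12 * max(0, n - 10) +
    0.5 * max(0, rc - 2) +
    odd_ring_pen +
    0.4 * fusion +
    2.0 * max(0, hetero - 0.5) +
    0.3 * sum(mol$bond_o == 3L)
  min(10, max(1, s))
}

#' Normalized synthetic accessibility (f_syn)
#'
#' Maps the 1-10 heuristic to `[0,1]` with higher = easier, so that the
#' beta weight has the same orientation as the other objective terms.
#'
#' @param mol a `molgraph`.
#' @return numeric in `[0,1]`.
#' @export
syn_score <- function(mol) 1 - (sa_heuristic(mol) - 1) / 9

## ---------------------------------------------------------------------
## Docking scorers

#' Construct a docking scorer handle
#'
#' A scorer is a deterministic function of a molecule plus an orientation
#' convention. `orientation = "lower_better"` (native docking energies)
#' is negated inside the objective so that larger total is always better;
#' logged values keep the native sign.
#'
#' @param score function(molgraph) -> numeric.
#' @param orientation "higher_better" or "lower_better".
#' @param label free-text description.
#' @return object of class `dock_scorer`.
#' @export
dock_scorer <- function(score, orientation = c("higher_better", "lower_better"),
                        label = "custom") {
  orientation <- match.arg(orientation)
  structure(list(score = score, orientation = orientation, label = label),
            class = "dock_scorer")
}

#' Surrogate docking scorer from a pharmacophore-count profile
#'
#' Deterministic offline stand-in for the docking term: the score is
#' `-sum_f w_f * |count_f(mol) - target_f|` over the [feature_counts()]
#' features, maximized (0) when the molecule matches the profile exactly.
#' Invariant under atom reindexing because all features are graph
#' invariants.
#'
#' @param profile list with numeric vectors `targets` and `weights`,
#'   named by feature (heavy, rings, hbd, hba); missing weights default
#'   to 1.
#' @return a `dock_scorer` with orientation "higher_better".
#' @export
surrogate_dock <- function(profile) {
  stopifnot(is.list(profile), !is.null(profile$targets))
  feats <- names(profile$targets)
  w <- profile$weights
  if (is.null(w)) w <- stats::setNames(rep(1, length(feats)), feats)
  dock_scorer(function(mol) {
    fc <- feature_counts(mol)
    -sum(w[feats] * abs(fc[feats] - profile$targets[feats]))
  }, orientation = "higher_better",
  label = paste0("surrogate(", paste(feats, profile$targets, sep = "=",
                                     collapse = ","), ")"))
}

#' External docking adapter (AutoDock Vina / QVina style)
#'
#' Wraps an external docking binary as a scorer: validates the docking
#' box up front, caches results by canonical form + receptor hash + box,
#' and parses the best-pose affinity (kcal/mol, lower = better). The
#' adapter requires the binary and a ligand-preparation command on PATH;
#' the framework itself never depends on it (use [surrogate_dock()]
#' offline). Pose generation internals are deliberately out of scope.
#'
#' @param receptor path to a prepared receptor PDBQT file.
#' @param box list with numeric `center` (x,y,z) and `size` (x,y,z) in
#'   angstroms.
#' @param binary docking executable name or path.
#' @param prepare_ligand function(molgraph, pdbqt_path) writing a ligand
#'   PDBQT; defaults to an error stub since 3D embedding needs external
#'   tooling.
#' @return a `dock_scorer` with orientation "lower_better".
#' @export
external_dock <- function(receptor, box, binary = "vina",
                          prepare_ligand = NULL) {
  if (!is.list(box) || length(box$center) != 3L || length(box$size) != 3L ||
      !all(is.finite(c(box$center, box$size))) || any(box$size <= 0)) {
    stop("malformed docking box: need positive size and finite center", call. = FALSE)
  }
  if (!file.exists(receptor)) {
    stop("environment error: receptor file not found: ", receptor, call. = FALSE)
  }
  bin <- Sys.which(binary)
  if (!nzchar(bin)) {
    stop("environment error: docking binary '", binary,
         "' not on PATH; use surrogate_dock() for offline runs", call. = FALSE)
  }
  rec_hash <- content_hash(paste(readLines(receptor, warn = FALSE), collapse = "\n"))
  box_key <- paste(c(box$center, box$size), collapse = ",")
  cache <- new.env(parent = emptyenv())
  if (is.null(prepare_ligand)) {
    prepare_ligand <- function(mol, path) {
      stop("scorer error: no ligand-preparation hook configured", call. = FALSE)
    }
  }
  dock_scorer(function(mol) {
    key <- paste(canonical_form(mol), rec_hash, box_key, sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    lig <- tempfile(fileext = ".pdbqt")
    out <- tempfile(fileext = ".pdbqt")
    on.exit(unlink(c(lig, out)), add = TRUE)
    prepare_ligand(mol, lig)
    args <- c("--receptor", receptor, "--ligand", lig, "--out", out,
              "--center_x", box$center[1], "--center_y", box$center[2],
              "--center_z", box$center[3],
              "--size_x", box$size[1], "--size_y", box$size[2],
              "--size_z", box$size[3])
    res <- suppressWarnings(system2(bin, args, stdout = TRUE, stderr = TRUE))
    ln <- grep("^\\s+1\\s", res, value = TRUE)
    if (!length(ln)) {
      stop("scorer error: could not parse docking output for ",
           canonical_form(mol), call. = FALSE)
    }
    val <- suppressWarnings(as.numeric(strsplit(trimws(ln[1]), "\\s+")[[1]][2]))
    if (!is.finite(val)) {
      stop("scorer error: non-numeric affinity for ", canonical_form(mol),
           call. = FALSE)
    }
    cache[[key]] <- val
    val
  }, orientation = "lower_better", label = paste0("external(", binary, ")"))
}

## ---------------------------------------------------------------------
## Objective

#' Objective configuration
#'
#' Weights for the three property terms, the similarity threshold delta
#' of the validity gate, and the docking scorer handle. Defaults follow
#' the design choice that the docking term is weighted most heavily;
#' all values are config knobs.
#'
#' @param dock_scorer a [dock_scorer()] handle (f_Dock).
#' @param alpha docking weight (>= 0).
#' @param beta synthetic-accessibility weight (>= 0).
#' @param gamma drug-likeness weight (>= 0).
#' @param delta Morgan-similarity threshold in `[0,1]`; a candidate must
#'   be strictly more similar than this to the starting fragment.
#' @return object of class `objective_spec`.
#' @export
objective_spec <- function(dock_scorer, alpha = 1.0, beta = 0.2, gamma = 0.2,
                           delta = 0.4) {
  stopifnot(inherits(dock_scorer, "dock_scorer"),
            alpha >= 0, beta >= 0, gamma >= 0, delta >= 0, delta <= 1)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, delta = delta,
                 dock_scorer = dock_scorer),
            class = "objective_spec")
}

# dock value oriented so larger is better
oriented_dock <- function(spec, mol) {
  raw <- spec$dock_scorer$score(mol)
  if (!is.finite(raw)) {
    stop("scorer error: non-finite docking value for ", canonical_form(mol),
         call. = FALSE)
  }
  list(raw = raw,
       oriented = if (spec$dock_scorer$orientation == "lower_better") -raw else raw)
}

#' Weighted property score (ungated)
#'
#' `alpha*f_Dock + beta*f_syn + gamma*f_QED` with the docking term
#' oriented so larger is better. Returns the partial breakdown without
#' the gate.
#'
#' @param x_star candidate `molgraph`.
#' @param spec an [objective_spec()].
#' @return list: dock (native sign), dock_oriented, syn, qed, weighted.
#' @export
property_score <- function(x_star, spec) {
  d <- oriented_dock(spec, x_star)
  syn <- syn_score(x_star)
  qed <- qed_score(x_star)
  list(dock = d$raw, dock_oriented = d$oriented, syn = syn, qed = qed,
       weighted = spec$alpha * d$oriented + spec$beta * syn + spec$gamma * qed)
}

#' Validity gate (Eq.-4-style constraint)
#'
#' TRUE iff the candidate passes the valence check and its Morgan
#' similarity to the starting fragment strictly exceeds delta.
#'
#' @param x_star candidate `molgraph`.
#' @param x0 starting fragment.
#' @param spec an [objective_spec()].
#' @return logical scalar.
#' @export
validity_gate <- function(x_star, x0, spec) {
  check_valence(x_star) && similarity(x_star, x0) > spec$delta
}

#' Gated objective f(x*)
#'
#' The full score breakdown: `total` equals the weighted property score
#' when the validity gate passes and `-Inf` otherwise, so gated-out
#' candidates can never win an acceptance comparison.
#'
#' @param x_star candidate `molgraph`.
#' @param x0 starting fragment (the ORIGINAL input; the similarity gate
#'   always compares to it, not to the current incumbent).
#' @param spec an [objective_spec()].
#' @return object of class `score_breakdown`: dock, syn, qed, sim, valid,
#'   total.
#' @export
objective <- function(x_star, x0, spec) {
  objective_cached(x_star, morgan_fingerprint(x0), spec)
}

# tanimoto over precomputed bit sets
tanimoto_bits <- function(fa, fb) {
  u <- length(union(fa, fb))
  if (u == 0L) return(0)
  length(intersect(fa, fb)) / u
}

# hot-path variant: the starting fragment's fingerprint is fixed for a
# whole run, so the annealer precomputes it once
objective_cached <- function(x_star, x0_fp, spec) {
  sim <- tanimoto_bits(morgan_fingerprint(x_star), x0_fp)
  valid <- check_valence(x_star) && sim > spec$delta
  if (valid) {
    ps <- property_score(x_star, spec)
    out <- list(dock = ps$dock, syn = ps$syn, qed = ps$qed, sim = sim,
                valid = TRUE, total = ps$weighted)
  } else {
    out <- list(dock = NA_real_, syn = NA_real_, qed = NA_real_, sim = sim,
                valid = FALSE, total = -Inf)
  }
  structure(out, class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf("<score> total=%s dock=%s syn=%s qed=%s sim=%.3f valid=%s\n",
              format(x$total), format(x$dock), format(x$syn), format(x$qed),
              x$sim, x$valid))
  invisible(x)
}

#' Append score breakdowns to a JSON-lines log
#' @param breakdowns list of `score_breakdown` objects.
#' @param path output file (appended).
#' @param step optional step indices.
#' @export
write_score_log <- function(breakdowns, path, step = seq_along(breakdowns)) {
  lines <- vapply(seq_along(breakdowns), function(i) {
    b <- breakdowns[[i]]
    jsonlite::toJSON(list(step = step[i], dock = b$dock, syn = b$syn,
                          qed = b$qed, sim = b$sim, valid = b$valid,
                          total = if (is.finite(b$total)) b$total else "-Inf"),
                     auto_unbox = TRUE, na = "null")
  }, character(1))
  cat(lines, file = path, sep = "\n", append = TRUE)
  invisible(path)
}
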