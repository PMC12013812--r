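# The complete operation set A = {insertion, replacement, deletion,
# cyclization} over heavy-atom graphs, plus the candidate generator that
# proposes one local edit per annealing step. Every operator manipulates
# heavy atoms only; implicit hydrogens refill free valence afterwards.

.OPERATORS <- c("insertion", "replacement", "deletion", "cyclization")

#' Editing operator names
#' @return character vector: insertion, replacement, deletion, cyclization.
#' @export
operator_set <- function() .OPERATORS

free_valence <- function(mol) {
  .MAXVAL[mol$element] - bond_order_sum(mol)
}

check_pos <- function(mol, pos) {
  if (!is.numeric(pos) || length(pos) != 1L || pos < 1L || pos > n_atoms(mol)) {
    stop("index error: position out of range", call. = FALSE)
  }
  as.integer(pos)
}

#' Insertion operator
#'
#' Appends one new atom (index `n + 1`) bonded to the atom at `pos` with
#' the given order. Indices of existing atoms are unchanged and the
#' result is connected by construction.
#'
#' @param mol a `molgraph`.
#' @param pos attachment atom index.
#' @param element new-atom element symbol (see [element_vocabulary()]).
#' @param order bond order 1, 2 or 3.
#' @return the edited `molgraph`.
#' @export
insertion <- function(mol, pos, element, order = 1L) {
  pos <- check_pos(mol, pos)
  if (!(element %in% .ELEMENTS)) stop("unsupported element: ", element, call. = FALSE)
  order <- as.integer(order)
  fv <- free_valence(mol)
  if (fv[pos] < order) {
    stop("valence error: no free valence at position ", pos, call. = FALSE)
  }
  if (.MAXVAL[[element]] < order) {
    stop("valence error: ", element, " cannot carry a bond of order ", order,
         call. = FALSE)
  }
  molgraph(c(mol$element, element),
           c(mol$bond_i, pos), c(mol$bond_j, n_atoms(mol) + 1L),
           c(mol$bond_o, order),
           charge = c(mol$charge, 0L),
           provenance = mol$provenance)
}

#' Replacement operator
#'
#' Swaps the element at `pos`; bonds are unchanged and implicit
#' hydrogens are recomputed.
#'
#' @inheritParams insertion
#' @param element new element (must differ from the current one).
#' @return the edited `molgraph`.
#' @export
replacement <- function(mol, pos, element) {
  pos <- check_pos(mol, pos)
  if (!(element %in% .ELEMENTS)) stop("unsupported element: ", element, call. = FALSE)
  if (mol$element[pos] == element) {
    stop("replacement must change the element", call. = FALSE)
  }
  bs <- bond_order_sum(mol)
  if (.MAXVAL[[element]] < bs[pos]) {
    stop("valence error: ", element, " valence below bond-order sum at position ",
         pos, call. = FALSE)
  }
  el <- mol$element
  el[pos] <- element
  molgraph(el, mol$bond_i, mol$bond_j, mol$bond_o,
           charge = mol$charge, provenance = mol$provenance)
}

# remove atom pos; decompose the remainder into connected components.
# Each entry carries `sampleable`: valence-valid AND at least
# `min_component` atoms when the parent had >= 3 (prevents collapse to
# single atoms); valence-failing components are dropped outright.
deletion_components <- function(mol, pos, min_component = 2L) {
  pos <- check_pos(mol, pos)
  n <- n_atoms(mol)
  if (n < 2L) stop("degenerate-input error: cannot delete the only atom", call. = FALSE)
  keep <- setdiff(seq_len(n), pos)
  sel <- mol$bond_i != pos & mol$bond_j != pos
  remap <- match(seq_len(n), keep)
  bi <- remap[mol$bond_i[sel]]; bj <- remap[mol$bond_j[sel]]
  bo <- mol$bond_o[sel]
  comp <- graph_components(length(keep), bi, bj)
  floor_sz <- if (n >= 3L) min_component else 1L
  out <- list()
  for (cid in seq_len(max(comp))) {
    members <- which(comp == cid)
    sub_remap <- match(seq_along(keep), members)
    in_sub <- !is.na(sub_remap[bi]) & !is.na(sub_remap[bj])
    m <- molgraph(mol$element[keep[members]],
                  sub_remap[bi[in_sub]], sub_remap[bj[in_sub]], bo[in_sub],
                  charge = mol$charge[keep[members]],
                  provenance = mol$provenance)
    if (!check_valence(m)) next
    out[[length(out) + 1L]] <- list(mol = m, parent_index = keep[members],
                                    sampleable = length(members) >= floor_sz)
  }
  # deterministic ordering by smallest surviving parent index
  if (length(out) > 1L) {
    out <- out[order(vapply(out, function(x) min(x$parent_index), integer(1)))]
  }
  out
}

#' Raw deletion decomposition
#'
#' The substructure set S_t: remove the atom at `pos` and its incident
#' bonds and return every valence-valid connected component, regardless
#' of the sampling size floor applied by [deletion()].
#'
#' @param mol a `molgraph` with at least 2 heavy atoms.
#' @param pos atom index to delete.
#' @return list of `molgraph` components (deterministic order).
#' @export
deletion_substructures <- function(mol, pos) {
  lapply(deletion_components(mol, pos), `[[`, "mol")
}

#' Deletion operator
#'
#' Removes the atom at `pos` and its incident bonds. The remaining graph
#' may fall apart into several substructures; components below the
#' minimum-size floor (fewer than 2 heavy atoms when the parent had at
#' least 3) or failing the valence check are discarded, and one survivor
#' is sampled uniformly as the candidate.
#'
#' @param mol a `molgraph` with at least 2 heavy atoms.
#' @param pos atom index to delete.
#' @param rng an [rng_stream()] used for the uniform component draw.
#' @return list with `substructures` (all valence-valid components of the
#'   decomposition), `sampled` (the drawn `molgraph`, restricted to
#'   components above the size floor), and `parent_index` (mapping of the
#'   sampled component's atoms to parent indices).
#' @export
deletion <- function(mol, pos, rng) {
  comps <- deletion_components(mol, pos)
  ok <- which(vapply(comps, `[[`, logical(1), "sampleable"))
  if (!length(ok)) {
    stop("empty-result error: no surviving component after deletion", call. = FALSE)
  }
  k <- ok[stream_index(rng, length(ok))]
  list(substructures = lapply(comps, `[[`, "mol"),
       sampled = comps[[k]]$mol,
       parent_index = comps[[k]]$parent_index)
}

#' Cyclization operator
#'
#' Adds one new bond between two not-yet-bonded atoms, closing a ring
#' whose size (graph distance + 1) must fall inside `ring_window`. The
#' atom set is unchanged and the ring count increases by exactly one.
#'
#' @param mol a `molgraph`.
#' @param pos_a,pos_b distinct atom indices.
#' @param order bond order 1, 2 or 3.
#' @param ring_window allowed ring sizes (default 3:8).
#' @return the edited `molgraph`.
#' @export
cyclization <- function(mol, pos_a, pos_b, order = 1L, ring_window = 3:8) {
  pos_a <- check_pos(mol, pos_a); pos_b <- check_pos(mol, pos_b)
  order <- as.integer(order)
  if (pos_a == pos_b) stop("cyclization requires two distinct atoms", call. = FALSE)
  lo <- min(pos_a, pos_b); hi <- max(pos_a, pos_b)
  if (any(mol$bond_i == lo & mol$bond_j == hi)) {
    stop("duplicate-bond error: atoms already bonded", call. = FALSE)
  }
  fv <- free_valence(mol)
  if (fv[pos_a] < order || fv[pos_b] < order) {
    stop("valence error: insufficient free valence for cyclization", call. = FALSE)
  }
  ring_size <- graph_distance(mol, pos_a, pos_b) + 1L
  if (!(ring_size %in% ring_window)) {
    stop("ring-size error: ring of size ", ring_size, " outside window", call. = FALSE)
  }
  molgraph(mol$element, c(mol$bond_i, lo), c(mol$bond_j, hi),
           c(mol$bond_o, order), charge = mol$charge,
           provenance = mol$provenance)
}

#' Construct an edit action descriptor
#'
#' @param kind one of [operator_set()].
#' @param position target atom index.
#' @param payload operator-specific: insertion `list(element, order)`;
#'   replacement `list(element)`; deletion `list(component)` (index into
#'   the deterministic surviving-component ordering); cyclization
#'   `list(partner, order)`.
#' @return object of class `edit_action`.
#' @export
edit_action <- function(kind, position, payload = list()) {
  stopifnot(kind %in% .OPERATORS)
  structure(list(kind = kind, position = as.integer(position), payload = payload),
            class = "edit_action")
}

# build an edit_proposal: result + bookkeeping used by the frequency
# transfer (atom map child -> parent, NA for inserted atoms) and by logs
new_proposal <- function(action, parent, result, atom_map, edited_child_pos) {
  structure(list(action = action, parent = parent, result = result,
                 valid = check_valence(result),
                 atom_map = atom_map,
                 edited_child_pos = edited_child_pos),
            class = "edit_proposal")
}

#' @export
print.edit_proposal <- function(x, ...) {
  cat(sprintf("<edit_proposal> %s @%d: %s -> %s\n", x$action$kind,
              x$action$position, canonical_form(x$parent),
              canonical_form(x$result)))
  invisible(x)
}

#' Enumerate all valid single edits at a position
#'
#' Every valid edit at `pos` across the four operators, the element
#' vocabulary, bond orders 1-3, and (for cyclization) all legal ring
#' partners, in deterministic order (operator, then payload in fixed
#' vocabulary order). Deletion contributes one proposal per surviving
#' component.
#'
#' @param mol a `molgraph`.
#' @param pos atom index.
#' @param vocab element vocabulary to draw new atoms from.
#' @param ring_window allowed ring sizes for cyclization.
#' @param max_atoms optional cap: skip insertions that would exceed it.
#' @param operators restrict enumeration to a subset of [operator_set()].
#' @return list of `edit_proposal` objects (possibly empty), all valid.
#' @export
enumerate_edits <- function(mol, pos, vocab = element_vocabulary(),
                            ring_window = 3:8, max_atoms = Inf,
                            operators = operator_set()) {
  pos <- check_pos(mol, pos)
  n <- n_atoms(mol)
  fv <- free_valence(mol)
  bs <- bond_order_sum(mol)
  out <- list()

  # insertion: element x order
  if ("insertion" %in% operators && n + 1L <= max_atoms) {
    for (el in vocab) {
      for (o in 1:3) {
        if (fv[pos] >= o && .MAXVAL[[el]] >= o) {
          res <- insertion(mol, pos, el, o)
          out[[length(out) + 1L]] <- new_proposal(
            edit_action("insertion", pos, list(element = el, order = o)),
            mol, res, c(seq_len(n), NA_integer_), pos)
        }
      }
    }
  }
  # replacement: element
  if ("replacement" %in% operators) for (el in vocab) {
    if (el != mol$element[pos] && .MAXVAL[[el]] >= bs[pos]) {
      res <- replacement(mol, pos, el)
      out[[length(out) + 1L]] <- new_proposal(
        edit_action("replacement", pos, list(element = el)),
        mol, res, seq_len(n), pos)
    }
  }
  # deletion: one proposal per sampleable surviving component
  if ("deletion" %in% operators && n >= 2L) {
    comps <- tryCatch(deletion_components(mol, pos), error = function(e) list())
    for (ci in seq_along(comps)) {
      if (!comps[[ci]]$sampleable) next
      out[[length(out) + 1L]] <- new_proposal(
        edit_action("deletion", pos, list(component = ci)),
        mol, comps[[ci]]$mol, comps[[ci]]$parent_index, NA_integer_)
    }
  }
  # cyclization: partner x order
  if ("cyclization" %in% operators) for (partner in seq_len(n)) {
    if (partner == pos) next
    lo <- min(pos, partner); hi <- max(pos, partner)
    if (any(mol$bond_i == lo & mol$bond_j == hi)) next
    rs <- graph_distance(mol, pos, partner) + 1L
    if (!(rs %in% ring_window)) next
    for (o in 1:3) {
      if (fv[pos] >= o && fv[partner] >= o) {
        res <- cyclization(mol, pos, partner, o, ring_window)
        out[[length(out) + 1L]] <- new_proposal(
          edit_action("cyclization", pos, list(partner = partner, order = o)),
          mol, res, seq_len(n), pos)
      }
    }
  }
  out
}

#' Propose one random edit at a position
#'
#' Samples an operator from `op_weights` (Eq.-12-style action draw), then
#' a payload uniformly among that operator's valid edits at `pos`. If the
#' drawn operator has no valid edit there, the weights are renormalized
#' over operators that do (fallback keeps the chain irreducible). With an
#' identical stream state the proposal is identical.
#'
#' @param mol a `molgraph`.
#' @param pos atom index.
#' @param op_weights non-negative weights over
#'   insertion/replacement/deletion/cyclization summing to 1.
#' @param rng an [rng_stream()].
#' @param vocab,ring_window,max_atoms as in [enumerate_edits()].
#' @return an `edit_proposal`.
#' @export
propose <- function(mol, pos, op_weights = rep(0.25, 4), rng,
                    vocab = element_vocabulary(), ring_window = 3:8,
                    max_atoms = Inf) {
  stopifnot(length(op_weights) == 4L, all(op_weights >= 0),
            abs(sum(op_weights) - 1) < 1e-8)
  # lazy per-operator enumeration: draw an operator, enumerate only its
  # pool, and renormalize over operators not yet found infeasible
  tried_empty <- logical(4L)
  repeat {
    if (all(tried_empty)) {
      stop("no-edit error: no valid edit of any kind at position ", pos,
           call. = FALSE)
    }
    active <- op_weights * !tried_empty
    if (sum(active) == 0) active <- as.numeric(!tried_empty)
    k <- stream_categorical(rng, active)
    pool <- enumerate_edits(mol, pos, vocab, ring_window, max_atoms,
                            operators = .OPERATORS[k])
    if (length(pool)) {
      return(pool[[stream_index(rng, length(pool))]])
    }
    tried_empty[k] <- TRUE
  }
}

## ---------------------------------------------------------------------
## Edit-path search (operation-set completeness for optimization):
## delete toward a maximum common substructure, then grow.

# injective embedding of (induced, connected) subgraph of `a` given by
# atom set `sub` into `b`: elements equal, every a-bond present in b with
# equal order. Returns a mapping or NULL.
embed_subgraph <- function(a, sub, b) {
  nb_b <- neighbor_list(b)
  b_key <- if (length(b$bond_i)) {
    stats::setNames(b$bond_o, paste0(b$bond_i, "-", b$bond_j))
  } else stats::setNames(integer(0), character(0))
  b_order <- function(i, j) {
    k <- paste0(min(i, j), "-", max(i, j))
    if (k %in% names(b_key)) b_key[[k]] else 0L
  }
  a_nb <- neighbor_list(a)
  # order sub atoms so each (after the first) touches an earlier one
  ordered <- sub[1]
  rest <- sub[-1]
  while (length(rest)) {
    nxt <- NA_integer_
    for (r in rest) {
      if (length(intersect(a_nb$nb[[r]], ordered))) { nxt <- r; break }
    }
    if (is.na(nxt)) return(NULL)  # sub not connected
    ordered <- c(ordered, nxt); rest <- setdiff(rest, nxt)
  }
  map <- stats::setNames(rep(NA_integer_, length(ordered)), ordered)
  rec <- function(k) {
    if (k > length(ordered)) return(TRUE)
    v <- ordered[k]
    used <- map[!is.na(map)]
    cands <- setdiff(which(b$element == a$element[v]), used)
    # bonds from v to already-mapped sub atoms must exist in b
    prev <- intersect(a_nb$nb[[v]], ordered[seq_len(k - 1L)])
    for (cb in cands) {
      ok <- TRUE
      for (p in prev) {
        oa <- a_nb$order[[v]][match(p, a_nb$nb[[v]])]
        if (b_order(cb, map[[as.character(p)]]) != oa) { ok <- FALSE; break }
      }
      if (ok) {
        map[[as.character(v)]] <<- cb
        if (rec(k + 1L)) return(TRUE)
        map[[as.character(v)]] <<- NA_integer_
      }
    }
    FALSE
  }
  if (rec(1L)) map else NULL
}

# all connected atom subsets of mol of a given size (small molecules:
# brute force over combinations is plenty here)
connected_subsets <- function(mol, size) {
  n <- n_atoms(mol)
  if (size > n) return(list())
  if (size == 1L) return(as.list(seq_len(n)))
  sets <- utils::combn(n, size, simplify = FALSE)
  Filter(function(sub) {
    sel <- mol$bond_i %in% sub & mol$bond_j %in% sub
    is_connected_graph(size, match(mol$bond_i[sel], sub), match(mol$bond_j[sel], sub))
  }, sets)
}

# maximum common connected substructure: largest induced-in-a connected
# atom set embeddable into b (exact for small a; greedy shrink otherwise)
common_substructure <- function(a, b, exhaustive_limit = 10L) {
  n <- n_atoms(a)
  sizes <- seq(min(n, n_atoms(b)), 1L)
  if (n <= exhaustive_limit) {
    for (sz in sizes) {
      for (sub in connected_subsets(a, sz)) {
        map <- embed_subgraph(a, sub, b)
        if (!is.null(map)) return(list(sub = sub, map = map))
      }
    }
    return(NULL)
  }
  # greedy: single best-matching atom, then grow while embeddable
  for (v in seq_len(n)) {
    map <- embed_subgraph(a, v, b)
    if (is.null(map)) next
    sub <- v
    nb <- neighbor_list(a)$nb
    repeat {
      fr <- setdiff(unique(unlist(nb[sub])), sub)
      grown <- FALSE
      for (f in fr) {
        m2 <- embed_subgraph(a, sort(c(sub, f)), b)
        if (!is.null(m2)) { sub <- sort(c(sub, f)); map <- m2; grown <- TRUE; break }
      }
      if (!grown) break
    }
    return(list(sub = sub, map = map))
  }
  NULL
}

# replacements-only route: if a and b share their bond skeleton (an
# isomorphism preserving bond orders, elements free), b is reachable by
# replacing each mismatched element. Returns step descriptions or NULL.
replacement_route <- function(a, b, max_iso = 2000L) {
  n <- n_atoms(a)
  if (n != n_atoms(b) || length(a$bond_i) != length(b$bond_i)) return(NULL)
  nb_a <- neighbor_list(a); nb_b <- neighbor_list(b)
  deg_a <- atom_degree(a); deg_b <- atom_degree(b)
  best <- NULL; best_mis <- Inf; tried <- 0L
  map <- rep(NA_integer_, n)
  b_order <- function(i, j) {
    k <- which(b$bond_i == min(i, j) & b$bond_j == max(i, j))
    if (length(k)) b$bond_o[k] else 0L
  }
  rec <- function(v) {
    if (tried > max_iso) return(invisible(NULL))
    if (v > n) {
      tried <<- tried + 1L
      mis <- sum(a$element != b$element[map])
      if (mis < best_mis) { best_mis <<- mis; best <<- map }
      return(invisible(NULL))
    }
    for (cb in setdiff(which(deg_b == deg_a[v]), map)) {
      ok <- TRUE
      for (p in intersect(nb_a$nb[[v]], seq_len(v - 1L))) {
        oa <- nb_a$order[[v]][match(p, nb_a$nb[[v]])]
        if (b_order(cb, map[p]) != oa) { ok <- FALSE; break }
      }
      if (ok) { map[v] <<- cb; rec(v + 1L); map[v] <<- NA_integer_ }
    }
  }
  rec(1L)
  if (is.null(best)) return(NULL)
  # map is a->b; replacement at each mismatched atom is valence-safe
  # because bond orders are preserved and b is valence-valid
  mism <- which(a$element != b$element[best])
  sprintf("replacement @%d -> %s", mism, b$element[best][mism])
}

#' Search for an edit path between two molecules
#'
#' Implements the completeness route for optimization: delete-only steps
#' from `a` down to a maximum common substructure, then grow toward `b`
#' with insertion (new atoms), cyclization (missing ring bonds) and, in
#' the degenerate single-atom case, replacement. Returns the found path
#' (a character vector of step descriptions plus the step count) or
#' `FALSE` if no path within `max_steps` was found.
#'
#' @param a,b `molgraph` objects.
#' @param max_steps step budget (>= 1).
#' @param ring_window allowed ring sizes for the growth cyclizations.
#' @return list with `found`, `steps`, `path` (descriptions), or
#'   `found = FALSE`.
#' @export
edit_path_exists <- function(a, b, max_steps = 12L, ring_window = 3:8) {
  stopifnot(max_steps >= 1L)
  if (same_molecule(a, b)) {
    return(list(found = TRUE, steps = 0L, path = character(0)))
  }
  rr <- replacement_route(a, b)
  if (!is.null(rr) && length(rr) <= max_steps) {
    return(list(found = TRUE, steps = length(rr), path = rr))
  }
  cs <- common_substructure(a, b)
  path <- character(0)
  cur <- a
  cur_core <- NULL; cur_map <- NULL
  if (is.null(cs)) {
    # no common atom: shrink a to one atom, replace it to match b's root
    while (n_atoms(cur) > 1L) {
      d <- vapply(seq_len(n_atoms(cur)), function(v)
        max(vapply(seq_len(n_atoms(cur)), function(w)
          as.numeric(graph_distance(cur, 1L, w)), numeric(1))), numeric(1))
      # delete an eccentric atom, keep the largest piece
      drop_at <- which.max(vapply(seq_len(n_atoms(cur)), function(v)
        as.numeric(graph_distance(cur, which.min(d), v)), numeric(1)))
      comps <- deletion_components(cur, drop_at, min_component = 1L)
      if (!length(comps)) return(list(found = FALSE))
      sizes <- vapply(comps, function(x) n_atoms(x$mol), integer(1))
      cur <- comps[[which.max(sizes)]]$mol
      path <- c(path, sprintf("deletion @%d", drop_at))
    }
    path <- c(path, sprintf("replacement @1 -> %s", b$element[1]))
    cur <- molgraph(b$element[1])
    cur_core <- 1L
    cur_map <- stats::setNames(1L, "1")
    cs <- list(sub = 1L, map = cur_map)
    target_root <- 1L
  }
  if (is.null(cur_core)) {
    core <- cs$sub
    # delete non-core atoms of a, farthest-from-core first; after each
    # deletion keep the component containing the core
    while (n_atoms(cur) > length(core)) {
      non_core <- setdiff(seq_len(n_atoms(cur)), core)
      dists <- vapply(non_core, function(v)
        min(vapply(core, function(cc) as.numeric(graph_distance(cur, v, cc)),
                   numeric(1))), numeric(1))
      drop_at <- non_core[which.max(dists)]
      comps <- deletion_components(cur, drop_at, min_component = 1L)
      if (!length(comps)) return(list(found = FALSE))
      keep <- NULL
      for (cmp in comps) {
        if (all(core %in% cmp$parent_index)) { keep <- cmp; break }
      }
      if (is.null(keep)) return(list(found = FALSE))
      cur <- keep$mol
      core <- match(core, keep$parent_index)
      path <- c(path, sprintf("deletion @%d", drop_at))
      if (length(path) > max_steps) return(list(found = FALSE))
    }
    # atoms of cur now correspond to cs$sub in order keep$parent_index;
    # build map cur-index -> b-index
    cur_map <- integer(n_atoms(cur))
    for (i in seq_len(n_atoms(cur))) {
      cur_map[i] <- cs$map[[as.character(cs$sub[order(cs$sub)][i])]]
    }
    # note: deletion keeps relative order of surviving atoms, and core was
    # tracked through remaps, so sorted(cs$sub) aligns with cur indices
  } else {
    cur_map <- as.integer(cur_map)
  }

  # grow: BFS over b atoms not yet present
  present_b <- cur_map                      # b-index of each cur atom
  nb_b <- neighbor_list(b)
  repeat {
    missing <- setdiff(seq_len(n_atoms(b)), present_b)
    if (!length(missing)) break
    nxt <- NA_integer_; attach_b <- NA_integer_
    for (mb in missing) {
      anchors <- intersect(nb_b$nb[[mb]], present_b)
      if (length(anchors)) { nxt <- mb; attach_b <- anchors[1]; break }
    }
    if (is.na(nxt)) return(list(found = FALSE))
    o <- nb_b$order[[nxt]][match(attach_b, nb_b$nb[[nxt]])]
    pos_cur <- match(attach_b, present_b)
    cur <- insertion(cur, pos_cur, b$element[nxt], o)
    present_b <- c(present_b, nxt)
    path <- c(path, sprintf("insertion %s(order %d) @%d", b$element[nxt], o, pos_cur))
    if (length(path) > max_steps) return(list(found = FALSE))
  }
  # add missing bonds (ring closures) via cyclization
  for (k in seq_along(b$bond_i)) {
    bi <- b$bond_i[k]; bj <- b$bond_j[k]
    ci <- match(bi, present_b); cj <- match(bj, present_b)
    lo <- min(ci, cj); hi <- max(ci, cj)
    if (any(cur$bond_i == lo & cur$bond_j == hi)) next
    res <- tryCatch(cyclization(cur, ci, cj, b$bond_o[k], ring_window),
                    error = function(e) NULL)
    if (is.null(res)) return(list(found = FALSE))
    cur <- res
    path <- c(path, sprintf("cyclization @%d-%d order %d", ci, cj, b$bond_o[k]))
    if (length(path) > max_steps) return(list(found = FALSE))
  }
  if (!same_molecule(cur, b)) return(list(found = FALSE))
  if (length(path) > max_steps) return(list(found = FALSE))
  list(found = TRUE, steps = length(path), path = path)
}

#' Serialize proposals as JSON-lines
#'
#' @param proposals list of `edit_proposal` objects.
#' @param path output file; appended to if it exists.
#' @param step optional step numbers (recycled).
#' @export
write_proposal_log <- function(proposals, path, step = seq_along(proposals)) {
  step <- rep_len(step, length(proposals))
  lines <- vapply(seq_along(proposals), function(i) {
    p <- proposals[[i]]
    jsonlite::toJSON(list(step = step[i], operator = p$action$kind,
                          position = p$action$position,
                          payload = p$action$payload,
                          parent = canonical_form(p$parent),
                          child = canonical_form(p$result),
                          valid = p$valid),
                     auto_unbox = TRUE)
  }, character(1))
  cat(lines, file = path, sep = "\n", append = TRUE)
  invisible(path)
}
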