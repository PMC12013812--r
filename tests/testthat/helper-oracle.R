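# Independent oracles, coded against the raw graph representation and
# kept free of the package's operator / enumeration code paths. Only the
# molgraph container and canonical_form are shared (the comparison key).

ORACLE_VAL <- c(C = 4L, N = 3L, O = 2L, F = 1L, P = 5L, S = 6L, Cl = 1L, Br = 1L)

oracle_bondsum <- function(el, bi, bj, bo) {
  bs <- numeric(length(el))
  for (k in seq_along(bi)) {
    bs[bi[k]] <- bs[bi[k]] + bo[k]
    bs[bj[k]] <- bs[bj[k]] + bo[k]
  }
  bs
}

oracle_valid <- function(el, bi, bj, bo) {
  all(oracle_bondsum(el, bi, bj, bo) <= ORACLE_VAL[el])
}

oracle_components <- function(n, bi, bj) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (k in seq_along(bi)) {
      a <- comp[bi[k]]; b <- comp[bj[k]]
      if (a != b) { comp[comp == max(a, b)] <- min(a, b); changed <- TRUE }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

oracle_dist <- function(n, bi, bj, from, to) {
  if (from == to) return(0L)
  dist <- rep(NA_integer_, n); dist[from] <- 0L
  frontier <- from
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (k in seq_along(bi)) {
        w <- if (bi[k] == v) bj[k] else if (bj[k] == v) bi[k] else next
        if (is.na(dist[w])) { dist[w] <- dist[v] + 1L; nxt <- c(nxt, w) }
      }
    }
    frontier <- nxt
  }
  if (is.na(dist[to])) Inf else dist[to]
}

# brute-force single-edit enumeration at a position: returns the sorted
# set of canonical forms of all valid candidates
oracle_enumerate <- function(mol, pos, vocab = element_vocabulary(),
                             ring_window = 3:8) {
  el <- mol$element; bi <- mol$bond_i; bj <- mol$bond_j; bo <- mol$bond_o
  n <- length(el)
  res <- character(0)
  keep <- function(el2, bi2, bj2, bo2) {
    if (!oracle_valid(el2, bi2, bj2, bo2)) return(invisible(NULL))
    cmp <- oracle_components(length(el2), bi2, bj2)
    if (max(cmp) != 1L && length(el2) > 1L) return(invisible(NULL))
    m <- molgraph(el2, bi2, bj2, bo2)
    res[length(res) + 1L] <<- canonical_form(m)
  }
  # insertion
  for (e2 in vocab) for (o in 1:3) {
    keep(c(el, e2), c(bi, pos), c(bj, n + 1L), c(bo, o))
  }
  # replacement
  for (e2 in setdiff(vocab, el[pos])) {
    el2 <- el; el2[pos] <- e2
    keep(el2, bi, bj, bo)
  }
  # deletion: each surviving component (size floor 2 when parent >= 3)
  if (n >= 2L) {
    kp <- setdiff(seq_len(n), pos)
    sel <- bi != pos & bj != pos
    rm <- match(seq_len(n), kp)
    bi2 <- rm[bi[sel]]; bj2 <- rm[bj[sel]]; bo2 <- bo[sel]
    cmp <- oracle_components(length(kp), bi2, bj2)
    floor_sz <- if (n >= 3L) 2L else 1L
    for (cid in unique(cmp)) {
      mem <- which(cmp == cid)
      if (length(mem) < floor_sz) next
      rm2 <- match(seq_along(kp), mem)
      insel <- !is.na(rm2[bi2]) & !is.na(rm2[bj2])
      keep(el[kp[mem]], rm2[bi2[insel]], rm2[bj2[insel]], bo2[insel])
    }
  }
  # cyclization
  fv <- ORACLE_VAL[el] - oracle_bondsum(el, bi, bj, bo)
  for (q in seq_len(n)) {
    if (q == pos) next
    bonded <- any((bi == min(pos, q)) & (bj == max(pos, q)))
    if (bonded) next
    rs <- oracle_dist(n, bi, bj, pos, q) + 1L
    if (!(rs %in% ring_window)) next
    for (o in 1:3) {
      if (fv[pos] >= o && fv[q] >= o) {
        keep(el, c(bi, min(pos, q)), c(bj, max(pos, q)), c(bo, o))
      }
    }
  }
  sort(unique(res))
}

# ---------------------------------------------------------------------
# exhaustive valence-valid connected chemical space over {C,N,O} with
# <= max_atoms heavy atoms, deduplicated by permutation-minimal codes
.space_cache <- new.env(parent = emptyenv())

oracle_space_cno <- function(max_atoms = 4L) {
  key <- as.character(max_atoms)
  if (!is.null(.space_cache[[key]])) return(.space_cache[[key]])
  elements <- c("C", "N", "O")
  reps <- list()     # representative graphs keyed by perm-min code
  codes <- new.env(parent = emptyenv())
  for (n in seq_len(max_atoms)) {
    slots <- if (n >= 2L) utils::combn(n, 2L) else matrix(integer(0), 2, 0)
    n_slots <- ncol(slots)
    order_grid <- as.matrix(expand.grid(rep(list(0:3), n_slots)))
    if (!n_slots) order_grid <- matrix(0L, 1, 0)
    # connectivity depends only on the nonzero-slot mask
    mask_conn <- new.env(parent = emptyenv())
    conn_ok <- function(orders) {
      if (n == 1L) return(TRUE)
      mk <- paste(orders > 0L, collapse = "")
      v <- mask_conn[[mk]]
      if (is.null(v)) {
        sel <- orders > 0L
        v <- if (n == 1L) TRUE else {
          cmp <- oracle_components(n, slots[1, sel], slots[2, sel])
          max(cmp) == 1L
        }
        mask_conn[[mk]] <- v
      }
      v
    }
    perms <- perm_list(n)
    el_grid <- as.matrix(expand.grid(rep(list(elements), n),
                                     stringsAsFactors = FALSE))
    for (gi in seq_len(nrow(order_grid))) {
      orders <- as.integer(order_grid[gi, ])
      if (!conn_ok(orders)) next
      bs <- numeric(n)
      for (s in seq_len(n_slots)) {
        if (orders[s] > 0L) {
          bs[slots[1, s]] <- bs[slots[1, s]] + orders[s]
          bs[slots[2, s]] <- bs[slots[2, s]] + orders[s]
        }
      }
      for (ei in seq_len(nrow(el_grid))) {
        els <- el_grid[ei, ]
        if (any(bs > ORACLE_VAL[els])) next
        code <- perm_min_code(els, orders, slots, perms, n)
        if (is.null(codes[[code]])) {
          codes[[code]] <- TRUE
          sel <- orders > 0L
          reps[[length(reps) + 1L]] <- molgraph(
            els, slots[1, sel], slots[2, sel], orders[sel])
        }
      }
    }
  }
  smis <- vapply(reps, canonical_form, character(1))
  stopifnot(!anyDuplicated(smis))
  out <- list(molecules = reps, smiles = sort(smis))
  .space_cache[[key]] <- out
  out
}

perm_list <- function(n) {
  if (n == 1L) return(list(1L))
  ps <- list()
  rec <- function(cur, rest) {
    if (!length(rest)) { ps[[length(ps) + 1L]] <<- cur; return(invisible(NULL)) }
    for (r in rest) rec(c(cur, r), setdiff(rest, r))
  }
  rec(integer(0), seq_len(n))
  ps
}

perm_min_code <- function(els, orders, slots, perms, n) {
  n_slots <- ncol(slots)
  best <- NULL
  for (p in perms) {
    # permuted adjacency: slot (i,j) under p becomes (p[i], p[j])
    om <- matrix(0L, n, n)
    for (s in seq_len(n_slots)) {
      a <- p[slots[1, s]]; b <- p[slots[2, s]]
      om[min(a, b), max(a, b)] <- orders[s]
    }
    el2 <- character(n); el2[p] <- els
    code <- paste(c(el2, om[upper.tri(om)]), collapse = ",")
    if (is.null(best) || code < best) best <- code
  }
  best
}

# independent feature counter for the surrogate docking profile
oracle_features <- function(mol) {
  el <- mol$element; bi <- mol$bond_i; bj <- mol$bond_j; bo <- mol$bond_o
  bs <- oracle_bondsum(el, bi, bj, bo)
  smallest_val <- vapply(seq_along(el), function(i) {
    vals <- switch(el[i], C = 4L, N = 3L, O = 2L, F = 1L, P = c(3L, 5L),
                   S = c(2L, 4L, 6L), Cl = 1L, Br = 1L)
    fit <- vals[vals >= bs[i]]
    if (length(fit)) min(fit) else bs[i]
  }, numeric(1))
  nh <- pmax(0, smallest_val - bs)
  no <- el %in% c("N", "O")
  c(heavy = length(el),
    rings = length(bi) - length(el) + 1L,
    hbd = sum(no & nh > 0),
    hba = sum(no))
}
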