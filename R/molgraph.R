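# Molecular-graph data model: attributed heavy-atom graphs with implicit
# hydrogens, a hand-rolled SMILES parser/writer, canonical serialization,
# and circular (Morgan-type) fingerprints. Everything downstream edits
# these objects, so the representation is deliberately plain vectors.

# Allowed-element vocabulary with standard neutral valences. Edited atoms
# are always neutral; charges are carried but never created.
.VALENCES <- list(
  C = 4L, N = 3L, O = 2L, F = 1L,
  P = c(3L, 5L), S = c(2L, 4L, 6L), Cl = 1L, Br = 1L
)
.ELEMENTS <- names(.VALENCES)
.MAXVAL <- vapply(.VALENCES, max, integer(1))
.ATOMIC_MASS <- c(
  C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904
)

#' Element vocabulary
#'
#' The heavy-atom vocabulary used by the editing operators, with the
#' standard neutral valences assumed throughout: C 4, N 3, O 2, F 1,
#' P (3,5), S (2,4,6), Cl 1, Br 1.
#'
#' @return Character vector of element symbols.
#' @export
element_vocabulary <- function() .ELEMENTS

#' Construct a molecular graph
#'
#' A `molgraph` is a connected heavy-atom graph: elements, formal charges,
#' and a set of unordered unique bonds with integer (kekulized) orders.
#' Hydrogens are implicit and recomputed from free valence on demand.
#' Atom indices are 1-based, dense, and stable within one object.
#'
#' @param element character vector of element symbols (see
#'   [element_vocabulary()]).
#' @param bond_i,bond_j integer vectors of bonded atom index pairs.
#' @param bond_o integer bond orders (1, 2, or 3; aromatic systems are
#'   stored kekulized and re-perceived on serialization).
#' @param charge integer formal charges (default all zero).
#' @param provenance free-text origin tag carried through edits.
#' @return An object of class `molgraph`.
#' @export
molgraph <- function(element, bond_i = integer(), bond_j = integer(),
                     bond_o = integer(), charge = NULL, provenance = "") {
  element <- as.character(element)
  n <- length(element)
  if (n < 1L) stop("molgraph must have at least one atom", call. = FALSE)
  bad <- setdiff(unique(element), .ELEMENTS)
  if (length(bad)) {
    stop("unsupported element(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(charge)) charge <- integer(n)
  bond_i <- as.integer(bond_i); bond_j <- as.integer(bond_j)
  bond_o <- as.integer(bond_o)
  if (length(bond_i) != length(bond_j) || length(bond_i) != length(bond_o)) {
    stop("bond vectors must have equal length", call. = FALSE)
  }
  if (length(bond_i)) {
    if (any(bond_i < 1L | bond_i > n | bond_j < 1L | bond_j > n)) {
      stop("bond index out of range", call. = FALSE)
    }
    if (any(bond_i == bond_j)) stop("self-bond not allowed", call. = FALSE)
    if (!all(bond_o %in% 1:3)) stop("bond order must be 1, 2 or 3", call. = FALSE)
    swap <- bond_i > bond_j
    tmp <- bond_i[swap]; bond_i[swap] <- bond_j[swap]; bond_j[swap] <- tmp
    key <- bond_i * (n + 1L) + bond_j
    if (anyDuplicated(key)) stop("duplicate bond", call. = FALSE)
    o <- order(bond_i, bond_j)
    bond_i <- bond_i[o]; bond_j <- bond_j[o]; bond_o <- bond_o[o]
  }
  m <- structure(
    list(element = element, charge = as.integer(charge),
         bond_i = bond_i, bond_j = bond_j, bond_o = bond_o,
         provenance = provenance),
    class = "molgraph"
  )
  if (!is_connected_graph(n, bond_i, bond_j)) {
    stop("molgraph must be connected", call. = FALSE)
  }
  m
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph> %d atoms, %d bonds: %s\n",
              n_atoms(x), length(x$bond_i), canonical_form(x)))
  invisible(x)
}

#' Number of heavy atoms
#' @param mol a `molgraph`.
#' @return integer atom count.
#' @export
n_atoms <- function(mol) length(mol$element)

#' Number of bonds
#' @param mol a `molgraph`.
#' @return integer bond count.
#' @export
n_bonds <- function(mol) length(mol$bond_i)

# sum of bond orders incident to each atom
bond_order_sum <- function(mol) {
  n <- n_atoms(mol)
  bs <- numeric(n)
  if (length(mol$bond_i)) {
    for (k in seq_along(mol$bond_i)) {
      bs[mol$bond_i[k]] <- bs[mol$bond_i[k]] + mol$bond_o[k]
      bs[mol$bond_j[k]] <- bs[mol$bond_j[k]] + mol$bond_o[k]
    }
  }
  bs
}

# adjacency as list of neighbor indices (parallel list of bond orders)
neighbor_list <- function(mol) {
  n <- n_atoms(mol)
  nb <- vector("list", n)
  bo <- vector("list", n)
  if (length(mol$bond_i)) {
    for (k in seq_along(mol$bond_i)) {
      i <- mol$bond_i[k]; j <- mol$bond_j[k]; o <- mol$bond_o[k]
      nb[[i]] <- c(nb[[i]], j); bo[[i]] <- c(bo[[i]], o)
      nb[[j]] <- c(nb[[j]], i); bo[[j]] <- c(bo[[j]], o)
    }
  }
  list(nb = nb, order = bo)
}

#' Atom degrees
#' @param mol a `molgraph`.
#' @return integer vector of heavy-atom degrees.
#' @export
atom_degree <- function(mol) {
  n <- n_atoms(mol)
  d <- integer(n)
  if (length(mol$bond_i)) {
    t1 <- tabulate(mol$bond_i, n); t2 <- tabulate(mol$bond_j, n)
    d <- t1 + t2
  }
  d
}

#' Implicit hydrogen counts
#'
#' Implicit hydrogens fill the free valence up to the smallest allowed
#' valence of the element that accommodates the atom's bond-order sum
#' (e.g. S with 6 bonds gets 0 H via the 6-valent state).
#'
#' @param mol a `molgraph`.
#' @return integer vector of implicit H counts (0 for hypervalent atoms).
#' @export
implicit_h <- function(mol) {
  bs <- bond_order_sum(mol)
  n <- n_atoms(mol)
  h <- integer(n)
  for (i in seq_len(n)) {
    vals <- .VALENCES[[mol$element[i]]]
    fit <- vals[vals >= bs[i]]
    h[i] <- if (length(fit)) as.integer(min(fit) - bs[i]) else 0L
  }
  h
}

#' Valence check (the validity predicate f_g)
#'
#' Returns `TRUE` iff every atom's bond-order sum is within its element's
#' maximum allowed valence and formal charges are zero. Total on any
#' structurally well-formed `molgraph`; never raises.
#'
#' @param mol a `molgraph`.
#' @return logical scalar.
#' @export
check_valence <- function(mol) {
  bs <- bond_order_sum(mol)
  all(bs <= .MAXVAL[mol$element]) && all(mol$charge == 0L)
}

is_connected_graph <- function(n, bond_i, bond_j) {
  if (n == 1L) return(TRUE)
  if (!length(bond_i)) return(FALSE)
  adj <- vector("list", n)
  for (k in seq_along(bond_i)) {
    adj[[bond_i[k]]] <- c(adj[[bond_i[k]]], bond_j[k])
    adj[[bond_j[k]]] <- c(adj[[bond_j[k]]], bond_i[k])
  }
  seen <- logical(n)
  queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  all(seen)
}

# connected components of an arbitrary (element, bond table) fragment;
# returns integer membership vector
graph_components <- function(n, bond_i, bond_j) {
  comp <- integer(n)
  adj <- vector("list", n)
  for (k in seq_along(bond_i)) {
    adj[[bond_i[k]]] <- c(adj[[bond_i[k]]], bond_j[k])
    adj[[bond_j[k]]] <- c(adj[[bond_j[k]]], bond_i[k])
  }
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] == 0L) {
      cid <- cid + 1L
      queue <- s; comp[s] <- cid
      while (length(queue)) {
        v <- queue[1L]; queue <- queue[-1L]
        for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- cid; queue <- c(queue, w) }
      }
    }
  }
  comp
}

#' Graph distance between two atoms
#'
#' Unweighted shortest-path length (number of bonds); used e.g. to size
#' the ring a cyclization would close.
#'
#' @param mol a `molgraph`.
#' @param a,b atom indices.
#' @param skip_bond optional length-2 vector: treat this bond as absent.
#' @return integer distance, or `Inf` if unreachable.
#' @export
graph_distance <- function(mol, a, b, skip_bond = NULL) {
  n <- n_atoms(mol)
  adj <- neighbor_list(mol)$nb
  if (!is.null(skip_bond)) {
    u <- skip_bond[1]; v <- skip_bond[2]
    adj[[u]] <- setdiff(adj[[u]], v)
    adj[[v]] <- setdiff(adj[[v]], u)
  }
  if (a == b) return(0L)
  dist <- rep(NA_integer_, n)
  dist[a] <- 0L
  queue <- a
  while (length(queue)) {
    x <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[x]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[x] + 1L
        if (w == b) return(dist[w])
        queue <- c(queue, w)
      }
    }
  }
  Inf
}

# per-bond: does the bond lie on a ring? (non-bridge test by BFS)
bond_in_ring <- function(mol) {
  m <- length(mol$bond_i)
  if (!m) return(logical(0))
  out <- logical(m)
  for (k in seq_len(m)) {
    d <- graph_distance(mol, mol$bond_i[k], mol$bond_j[k],
                        skip_bond = c(mol$bond_i[k], mol$bond_j[k]))
    out[k] <- is.finite(d)
  }
  out
}

#' Ring membership of atoms
#' @param mol a `molgraph`.
#' @return logical vector: atom lies on at least one ring.
#' @export
atom_in_ring <- function(mol) {
  n <- n_atoms(mol)
  inr <- logical(n)
  br <- bond_in_ring(mol)
  if (any(br)) {
    inr[unique(c(mol$bond_i[br], mol$bond_j[br]))] <- TRUE
  }
  inr
}

#' Ring count (cyclomatic number)
#' @param mol a connected `molgraph`.
#' @return integer number of independent rings.
#' @export
ring_count <- function(mol) length(mol$bond_i) - n_atoms(mol) + 1L

## ---------------------------------------------------------------------
## Aromatic perception (serialization/fingerprint view only)
##
## Internally every molgraph is kekulized. For canonical output and
## fingerprints we perceive six-membered C/N rings whose bond orders
## alternate single/double and flag them aromatic, so that the two kekule
## forms of e.g. benzene collapse to one canonical string. Five-membered
## heteroaromatics and fused systems stay kekulized (see vignette).

# ALL simple 6-cycles, by DFS anchored at each cycle's smallest atom
# index (exhaustive, so perception cannot depend on atom ordering)
six_rings <- function(mol) {
  if (length(mol$bond_i) < 6L) return(list())
  adj <- neighbor_list(mol)$nb
  found <- list()
  keys <- character(0)
  n <- n_atoms(mol)
  for (s in seq_len(n)) {
    # paths s -> ... -> s of length 6 visiting only atoms > s in between
    stack <- list(s)
    dfs <- function(path) {
      v <- path[length(path)]
      if (length(path) == 6L) {
        if (s %in% adj[[v]]) {
          key <- paste(sort(path), collapse = "-")
          if (!(key %in% keys)) {
            keys <<- c(keys, key)
            found[[length(found) + 1L]] <- path
          }
        }
        return(invisible(NULL))
      }
      for (w in adj[[v]]) {
        if (w > s && !(w %in% path)) dfs(c(path, w))
      }
    }
    dfs(s)
  }
  found
}

# returns list(order = bond orders with 4L where aromatic, arom = atom flags)
perceive_aromatic <- function(mol) {
  ord <- mol$bond_o
  arom <- logical(n_atoms(mol))
  rings <- six_rings(mol)
  if (length(rings)) {
    n <- n_atoms(mol)
    bidx <- function(i, j) {
      which((mol$bond_i == min(i, j)) & (mol$bond_j == max(i, j)))
    }
    for (path in rings) {
      if (!all(mol$element[path] %in% c("C", "N"))) next
      eb <- integer(6)
      for (s in 1:6) {
        i <- path[s]; j <- path[if (s == 6) 1 else s + 1]
        k <- bidx(i, j)
        if (!length(k)) { eb <- NULL; break }
        eb[s] <- mol$bond_o[k]
      }
      if (is.null(eb)) next
      alt1 <- all(eb == c(1L, 2L, 1L, 2L, 1L, 2L))
      alt2 <- all(eb == c(2L, 1L, 2L, 1L, 2L, 1L))
      if (alt1 || alt2) {
        arom[path] <- TRUE
        for (s in 1:6) {
          i <- path[s]; j <- path[if (s == 6) 1 else s + 1]
          ord[bidx(i, j)] <- 4L
        }
      }
    }
  }
  list(order = ord, arom = arom)
}

## ---------------------------------------------------------------------
## SMILES parsing

#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic subset of the element vocabulary, branches, ring
#' closures (including `%nn`), explicit bonds `- = # :`, aromatic
#' lowercase atoms (kekulized on input), and minimal bracket atoms such
#' as `[nH]`. Stereochemistry markers (`/ \ @`) are stripped: the editing
#' calculus is 2D. Charged or isotopic bracket atoms are rejected.
#' Multi-fragment (dot-separated) input is rejected with a connectivity
#' error.
#'
#' @param text a single SMILES string.
#' @param provenance optional free-text origin tag.
#' @return a `molgraph`.
#' @export
parse_molecule <- function(text, provenance = "") {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    stop("format error: empty SMILES input", call. = FALSE)
  }
  s <- trimws(text)
  if (grepl(".", s, fixed = TRUE)) {
    stop("connectivity error: multi-fragment (dot-separated) SMILES", call. = FALSE)
  }
  s <- gsub("[/\\\\]", "", s)            # strip cis/trans markers
  chars <- strsplit(s, "")[[1]]
  n_ch <- length(chars)

  element <- character(0)
  aromflag <- logical(0)
  explH <- integer(0)
  b_i <- integer(0); b_j <- integer(0); b_o <- integer(0)  # 4 = aromatic input
  prev <- NA_integer_
  stack <- integer(0)
  pending <- NA_integer_
  ringmap <- list()   # digit -> c(atom, pending_order)

  add_atom <- function(sym, arom, eh) {
    element[length(element) + 1L] <<- sym
    aromflag[length(aromflag) + 1L] <<- arom
    explH[length(explH) + 1L] <<- eh
    length(element)
  }
  add_bond <- function(i, j, o) {
    b_i[length(b_i) + 1L] <<- i
    b_j[length(b_j) + 1L] <<- j
    b_o[length(b_o) + 1L] <<- o
  }
  connect <- function(idx) {
    force(idx)
    if (!is.na(prev)) {
      o <- pending
      if (is.na(o)) o <- if (aromflag[prev] && aromflag[idx]) 4L else 1L
      add_bond(prev, idx, o)
    }
    pending <<- NA_integer_
    prev <<- idx
  }
  close_ring <- function(d) {
    key <- as.character(d)
    if (is.null(ringmap[[key]])) {
      ringmap[[key]] <<- c(prev, if (is.na(pending)) -1L else pending)
      pending <<- NA_integer_
    } else {
      st <- ringmap[[key]]
      ringmap[[key]] <<- NULL
      other <- st[1]
      o <- pending
      if (is.na(o) && st[2] != -1L) o <- st[2]
      if (is.na(o)) o <- if (aromflag[other] && aromflag[prev]) 4L else 1L
      if (other == prev) stop("format error: ring closure to self", call. = FALSE)
      add_bond(other, prev, o)
      pending <<- NA_integer_
    }
  }

  i <- 1L
  while (i <= n_ch) {
    ch <- chars[i]
    if (ch == "(") {
      if (is.na(prev)) stop("format error: branch before any atom", call. = FALSE)
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop("format error: unbalanced parenthesis", call. = FALSE)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]; i <- i + 1L
    } else if (ch == "-") { pending <- 1L; i <- i + 1L
    } else if (ch == "=") { pending <- 2L; i <- i + 1L
    } else if (ch == "#") { pending <- 3L; i <- i + 1L
    } else if (ch == ":") { pending <- 4L; i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(as.integer(ch)); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n_ch) stop("format error: bad %nn ring closure", call. = FALSE)
      close_ring(as.integer(paste0(chars[i + 1L], chars[i + 2L]))); i <- i + 3L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n_ch && chars[j] != "]") j <- j + 1L
      if (j > n_ch) stop("format error: unterminated bracket atom", call. = FALSE)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      if (grepl("[+@*-]|^[0-9]", body)) {
        stop("format error: unsupported bracket atom [", body, "]", call. = FALSE)
      }
      mm <- regmatches(body, regexec("^([A-Za-z][a-z]?)(H([0-9]?))?$", body))[[1]]
      if (!length(mm)) stop("format error: unsupported bracket atom [", body, "]", call. = FALSE)
      sym <- mm[2]
      arom <- sym %in% c("c", "n", "o", "s", "p")
      usym <- if (arom) paste0(toupper(substr(sym, 1, 1)), substring(sym, 2)) else sym
      if (!(usym %in% .ELEMENTS)) {
        stop("format error: element ", usym, " not in vocabulary", call. = FALSE)
      }
      eh <- if (mm[3] == "") 0L else if (mm[4] == "") 1L else as.integer(mm[4])
      connect(add_atom(usym, arom, eh))
      i <- j + 1L
    } else if (grepl("[A-Za-z]", ch)) {
      two <- if (i < n_ch) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        connect(add_atom(two, FALSE, -1L)); i <- i + 2L
      } else if (ch %in% c("C", "N", "O", "F", "P", "S")) {
        connect(add_atom(ch, FALSE, -1L)); i <- i + 1L
      } else if (ch %in% c("c", "n", "o", "s", "p")) {
        connect(add_atom(toupper(ch), TRUE, -1L)); i <- i + 1L
      } else {
        stop("format error: unsupported atom symbol '", ch, "'", call. = FALSE)
      }
    } else {
      stop("format error: unexpected character '", ch, "'", call. = FALSE)
    }
  }
  if (length(stack)) stop("format error: unbalanced parenthesis", call. = FALSE)
  if (length(ringmap)) stop("format error: unmatched ring closure", call. = FALSE)
  if (!length(element)) stop("format error: no atoms parsed", call. = FALSE)

  ## kekulize aromatic-flagged bonds
  if (any(b_o == 4L) || any(aromflag)) {
    kek <- kekulize_input(element, aromflag, explH, b_i, b_j, b_o)
    b_o <- kek
  }
  m <- molgraph(element, b_i, b_j, b_o, provenance = provenance)
  m
}

# assign single/double to aromatic bonds by perfect matching over atoms
# that need one in-ring double bond
kekulize_input <- function(element, aromflag, explH, b_i, b_j, b_o) {
  n <- length(element)
  deg <- tabulate(b_i, n) + tabulate(b_j, n)
  needs <- logical(n)
  for (v in seq_len(n)) {
    if (!aromflag[v]) next
    el <- element[v]
    needs[v] <- switch(el,
      C = TRUE,
      N = !(explH[v] > 0L || deg[v] >= 3L),
      FALSE)
  }
  ar_edges <- which(b_o == 4L)
  # adjacency restricted to aromatic bonds between 'needs' atoms
  cand <- ar_edges[needs[b_i[ar_edges]] & needs[b_j[ar_edges]]]
  matched_edge <- integer(0)
  match_of <- rep(NA_integer_, n)
  need_atoms <- which(needs)
  rec <- function(remaining) {
    if (!length(remaining)) return(TRUE)
    v <- remaining[1]
    opts <- cand[(b_i[cand] == v & is.na(match_of[b_j[cand]])) |
                 (b_j[cand] == v & is.na(match_of[b_i[cand]]))]
    for (e in opts) {
      w <- if (b_i[e] == v) b_j[e] else b_i[e]
      match_of[v] <<- w; match_of[w] <<- v
      matched_edge <<- c(matched_edge, e)
      if (rec(setdiff(remaining, c(v, w)))) return(TRUE)
      match_of[v] <<- NA_integer_; match_of[w] <<- NA_integer_
      matched_edge <<- matched_edge[-length(matched_edge)]
    }
    FALSE
  }
  if (!rec(need_atoms)) {
    stop("format error: cannot kekulize aromatic system", call. = FALSE)
  }
  b_o[b_o == 4L] <- 1L
  b_o[matched_edge] <- 2L
  b_o
}

## ---------------------------------------------------------------------
## Canonical serialization

# iterative invariant refinement; returns integer ranks (may have ties)
refine_ranks <- function(keys, nb, bo) {
  n <- length(keys)
  ranks <- match(keys, sort(unique(keys)))
  reps <- 0L
  repeat {
    reps <- reps + 1L
    newkeys <- character(n)
    for (i in seq_len(n)) {
      if (length(nb[[i]])) {
        nbk <- sort(paste0(bo[[i]], ".", formatC(ranks[nb[[i]]], width = 5, flag = "0")))
        newkeys[i] <- paste0(formatC(ranks[i], width = 5, flag = "0"), "|",
                             paste(nbk, collapse = ","))
      } else {
        newkeys[i] <- formatC(ranks[i], width = 5, flag = "0")
      }
    }
    newranks <- match(newkeys, sort(unique(newkeys)))
    if (length(unique(newranks)) == length(unique(ranks)) || reps > n) break
    ranks <- newranks
  }
  ranks
}

# full canonical ranking with tie branching; returns list of discrete
# rank vectors (deduplicated), capped to keep pathological symmetry cheap
canonical_rank_sets <- function(init_keys, nb, bo, cap = 64L) {
  out <- list()
  rec <- function(keys) {
    if (length(out) >= cap) return(invisible(NULL))
    ranks <- refine_ranks(keys, nb, bo)
    if (!anyDuplicated(ranks)) {
      out[[length(out) + 1L]] <<- ranks
      return(invisible(NULL))
    }
    tie_rank <- min(ranks[duplicated(ranks) | duplicated(ranks, fromLast = TRUE)])
    members <- which(ranks == tie_rank)
    for (m in members) {
      keys2 <- paste0(formatC(ranks, width = 5, flag = "0"), "x")
      keys2[m] <- paste0(formatC(ranks[m], width = 5, flag = "0"), "a")
      rec(keys2)
      if (length(out) >= cap) break
    }
  }
  rec(init_keys)
  out
}

# named vector "i-j" -> perceived bond order (empty-safe)
bond_key_orders <- function(mol, per) {
  if (!length(mol$bond_i)) return(stats::setNames(integer(0), character(0)))
  keys <- paste0(pmin(mol$bond_i, mol$bond_j), "-", pmax(mol$bond_i, mol$bond_j))
  stats::setNames(per$order, keys)
}

smiles_atom_token <- function(el, arom, nh) {
  if (arom) {
    t <- tolower(el)
    if (el == "N" && nh > 0L) t <- "[nH]"
    t
  } else el
}

bond_token <- function(o, arom_a, arom_b, arom_bond) {
  if (o == 4L) return("")
  if (o == 1L) {
    if (arom_a && arom_b && !arom_bond) return("-")
    return("")
  }
  if (o == 2L) return("=")
  if (o == 3L) return("#")
  ""
}

# write SMILES under a fixed discrete atom ranking
write_smiles_ranked <- function(mol, ranks, per) {
  n <- n_atoms(mol)
  nh <- implicit_h(mol)
  nbl <- neighbor_list(mol)
  ordmap <- new.env(parent = emptyenv())   # "i-j" -> perceived order
  for (k in seq_along(mol$bond_i)) {
    assign(paste0(mol$bond_i[k], "-", mol$bond_j[k]), per$order[k], envir = ordmap)
  }
  get_order <- function(i, j) get(paste0(min(i, j), "-", max(i, j)), envir = ordmap)

  root <- which.min(ranks)
  visited <- logical(n)
  parent <- rep(NA_integer_, n)
  order_visit <- integer(0)
  tree_children <- vector("list", n)
  back_edges <- list()   # list of c(i, j) with i visited before j
  # iterative DFS honoring rank order
  dfs <- function(v) {
    visited[v] <<- TRUE
    order_visit[length(order_visit) + 1L] <<- v
    nbs <- nbl$nb[[v]]
    if (length(nbs)) {
      nbs <- nbs[order(ranks[nbs])]
      for (w in nbs) {
        if (!visited[w]) {
          parent[w] <<- v
          tree_children[[v]] <<- c(tree_children[[v]], w)
          dfs(w)
        } else if (!identical(parent[v], w)) {
          key_exists <- any(vapply(back_edges, function(e) {
            (e[1] == w && e[2] == v) || (e[1] == v && e[2] == w)
          }, logical(1)))
          if (!key_exists) back_edges[[length(back_edges) + 1L]] <<- c(w, v)
        }
      }
    }
  }
  dfs(root)

  # assign ring-closure digits by visit order of the closing endpoint
  digit_of <- function(d) if (d <= 9) as.character(d) else sprintf("%%%02d", d)
  closures <- vector("list", n)  # per atom: list of c(partner, digit)
  if (length(back_edges)) {
    pos_in_visit <- match(seq_len(n), order_visit)
    ordbe <- order(vapply(back_edges, function(e) pos_in_visit[e[1]], numeric(1)),
                   vapply(back_edges, function(e) pos_in_visit[e[2]], numeric(1)))
    d <- 0L
    for (idx in ordbe) {
      e <- back_edges[[idx]]
      d <- d + 1L
      closures[[e[1]]] <- c(closures[[e[1]]], list(c(e[2], d)))
      closures[[e[2]]] <- c(closures[[e[2]]], list(c(e[1], d)))
    }
  }

  emit <- function(v) {
    tok <- smiles_atom_token(mol$element[v], per$arom[v], nh[v])
    cl <- ""
    if (!is.null(closures[[v]])) {
      for (c2 in closures[[v]]) {
        w <- c2[1]; d <- c2[2]
        o <- get_order(v, w)
        # bond symbol on the first (earlier-visited) endpoint only
        bsym <- ""
        if (match(v, order_visit) < match(w, order_visit)) {
          bsym <- bond_token(o, per$arom[v], per$arom[w], o == 4L)
        }
        cl <- paste0(cl, bsym, digit_of(d))
      }
    }
    kids <- tree_children[[v]]
    body <- ""
    if (length(kids)) {
      parts <- character(length(kids))
      for (ki in seq_along(kids)) {
        w <- kids[ki]
        o <- get_order(v, w)
        bsym <- bond_token(o, per$arom[v], per$arom[w], o == 4L)
        sub <- emit(w)
        parts[ki] <- if (ki < length(kids)) paste0("(", bsym, sub, ")")
                     else paste0(bsym, sub)
      }
      body <- paste(parts, collapse = "")
    }
    paste0(tok, cl, body)
  }
  emit(root)
}

#' Canonical SMILES serialization
#'
#' Equal graphs (up to atom reindexing and kekule form of perceived
#' aromatic rings) map to equal strings. Canonicalization refines
#' Morgan-style atom invariants to a discrete ranking, branching over
#' residual ties and taking the lexicographically smallest output.
#'
#' @param mol a `molgraph`.
#' @return a canonical SMILES string.
#' @export
canonical_form <- function(mol) {
  stopifnot(inherits(mol, "molgraph"))
  per <- perceive_aromatic(mol)
  n <- n_atoms(mol)
  nh <- implicit_h(mol)
  nbl <- neighbor_list(mol)
  # neighbor bond orders in the perceived view
  bo_per <- vector("list", n)
  per_ord <- bond_key_orders(mol, per)
  for (i in seq_len(n)) {
    if (length(nbl$nb[[i]])) {
      ks <- paste0(pmin(i, nbl$nb[[i]]), "-", pmax(i, nbl$nb[[i]]))
      bo_per[[i]] <- as.integer(per_ord[ks])
    } else bo_per[[i]] <- integer(0)
  }
  deg <- atom_degree(mol)
  bs2 <- integer(n)   # 2x bond-order sum with aromatic = 3 (i.e. 1.5 x 2)
  for (i in seq_len(n)) {
    o <- bo_per[[i]]
    bs2[i] <- sum(ifelse(o == 4L, 3L, o * 2L))
  }
  init <- paste(mol$element, as.integer(per$arom), deg, bs2, nh, mol$charge, sep = "_")
  rank_sets <- canonical_rank_sets(init, nbl$nb, bo_per)
  smis <- unique(vapply(rank_sets, function(r) write_smiles_ranked(mol, r, per),
                        character(1)))
  min(smis)
}

#' Canonical-form equality helper
#' @param a,b `molgraph` objects.
#' @return logical: same molecule up to atom reindexing.
#' @export
same_molecule <- function(a, b) identical(canonical_form(a), canonical_form(b))

## ---------------------------------------------------------------------
## Circular fingerprints and Tanimoto similarity

# exact 29-bit polynomial hash over integer sequences
hash_ints <- function(xs) {
  h <- 17
  for (x in xs) h <- (h * 31 + (x %% 536870909)) %% 536870909
  as.integer(h)
}

#' Morgan-type circular fingerprint
#'
#' Atom-environment hashing up to `radius` bond steps, folded into
#' `nbits` bits. Defaults (radius 2, 2048 bits) are the de-facto standard
#' Morgan parameters.
#'
#' @param mol a `molgraph`.
#' @param radius environment radius in bonds.
#' @param nbits fingerprint length.
#' @return sorted integer vector of set bit positions (0-based).
#' @export
morgan_fingerprint <- function(mol, radius = 2L, nbits = 2048L) {
  per <- perceive_aromatic(mol)
  n <- n_atoms(mol)
  nh <- implicit_h(mol)
  deg <- atom_degree(mol)
  nbl <- neighbor_list(mol)
  per_ord <- bond_key_orders(mol, per)
  elcode <- match(mol$element, .ELEMENTS)
  ids <- integer(n)
  for (i in seq_len(n)) {
    ids[i] <- hash_ints(c(elcode[i], deg[i], nh[i], as.integer(per$arom[i]),
                          mol$charge[i]))
  }
  all_ids <- ids
  for (r in seq_len(radius)) {
    new_ids <- integer(n)
    for (i in seq_len(n)) {
      nbs <- nbl$nb[[i]]
      if (length(nbs)) {
        ks <- paste0(pmin(i, nbs), "-", pmax(i, nbs))
        os <- as.integer(per_ord[ks])
        pairs <- order(os, ids[nbs])
        flat <- as.integer(rbind(os[pairs], ids[nbs][pairs]))
      } else flat <- integer(0)
      new_ids[i] <- hash_ints(c(r, ids[i], flat))
    }
    ids <- new_ids
    all_ids <- c(all_ids, ids)
  }
  sort(unique(all_ids %% nbits))
}

#' Tanimoto similarity of circular fingerprints (f_sim)
#'
#' Symmetric, 1 for identical canonical forms, in `[0,1]`.
#'
#' @param a,b `molgraph` objects.
#' @param radius,nbits fingerprint parameters.
#' @return numeric similarity in `[0,1]`.
#' @export
similarity <- function(a, b, radius = 2L, nbits = 2048L) {
  fa <- morgan_fingerprint(a, radius, nbits)
  fb <- morgan_fingerprint(b, radius, nbits)
  u <- length(union(fa, fb))
  if (u == 0L) return(0)
  length(intersect(fa, fb)) / u
}

## ---------------------------------------------------------------------
## Standard-format I/O

#' Read a one-molecule-per-line SMILES file
#'
#' Lines may carry an optional whitespace-separated name, used as the
#' provenance tag. Unparsable lines are dropped with a warning.
#'
#' @param path file path.
#' @return list of `molgraph` objects.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "[[:space:]]+")[[1]]
    m <- tryCatch(parse_molecule(parts[1],
                                 provenance = if (length(parts) > 1) parts[2] else ""),
                  error = function(e) NULL)
    if (is.null(m)) warning("dropped unparsable SMILES line: ", ln, call. = FALSE)
    else out[[length(out) + 1L]] <- m
  }
  out
}

#' Write molecules to a SMILES file
#' @param mols list of `molgraph` objects.
#' @param path output file path.
#' @export
write_smiles_file <- function(mols, path) {
  lines <- vapply(mols, function(m) {
    paste(canonical_form(m), m$provenance)
  }, character(1))
  writeLines(trimws(lines), path)
  invisible(path)
}

#' Read an SDF (V2000) file
#'
#' Minimal multi-record reader: atom elements and the bond block are
#' used; coordinates and properties are ignored. Aromatic (type 4) bonds
#' are kekulized.
#'
#' @param path file path.
#' @return list of `molgraph` objects.
#' @export
read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- split(lines, cumsum(c(TRUE, head(lines, -1) == "$$$$")))
  out <- list()
  for (rec in recs) {
    rec <- rec[rec != "$$$$"]
    if (length(rec) < 4L) next
    counts <- rec[4]
    na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
    nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
    if (is.na(na) || is.na(nb)) next
    m <- tryCatch({
      el <- character(na); bi <- integer(nb); bj <- integer(nb); bo <- integer(nb)
      arom <- logical(na)
      for (i in seq_len(na)) {
        el[i] <- trimws(substr(rec[4 + i], 32, 34))
      }
      for (k in seq_len(nb)) {
        ln <- rec[4 + na + k]
        bi[k] <- as.integer(substr(ln, 1, 3))
        bj[k] <- as.integer(substr(ln, 4, 6))
        bo[k] <- as.integer(substr(ln, 7, 9))
      }
      if (any(bo == 4L)) {
        arom_atoms <- unique(c(bi[bo == 4L], bj[bo == 4L]))
        af <- logical(na); af[arom_atoms] <- TRUE
        bo <- kekulize_input(el, af, integer(na), bi, bj, bo)
      }
      molgraph(el, bi, bj, bo, provenance = trimws(rec[1]))
    }, error = function(e) NULL)
    if (!is.null(m)) out[[length(out) + 1L]] <- m
  }
  out
}

#' Write molecules to an SDF (V2000) file
#'
#' 2D-less molblocks (zero coordinates); numeric score properties can be
#' attached per molecule as SD tags.
#'
#' @param mols list of `molgraph` objects.
#' @param path output path.
#' @param properties optional list (parallel to `mols`) of named numeric
#'   vectors written as SD data tags.
#' @export
write_sdf <- function(mols, path, properties = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (mi in seq_along(mols)) {
    m <- mols[[mi]]
    n <- n_atoms(m); nb <- length(m$bond_i)
    writeLines(c(if (nzchar(m$provenance)) m$provenance else canonical_form(m),
                 "  molanneal", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb), con)
    for (i in seq_len(n)) {
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         0, 0, 0, m$element[i]), con)
    }
    for (k in seq_len(nb)) {
      writeLines(sprintf("%3d%3d%3d  0", m$bond_i[k], m$bond_j[k], m$bond_o[k]), con)
    }
    writeLines("M  END", con)
    if (!is.null(properties) && length(properties) >= mi && length(properties[[mi]])) {
      pr <- properties[[mi]]
      for (nm in names(pr)) {
        writeLines(c(sprintf(">  <%s>", nm), format(pr[[nm]]), ""), con)
      }
    }
    writeLines("$$$$", con)
  }
  invisible(path)
}

#' Molecular weight (heavy atoms + implicit hydrogens)
#' @param mol a `molgraph`.
#' @return numeric molecular weight.
#' @export
mol_weight <- function(mol) {
  sum(.ATOMIC_MASS[mol$element]) + sum(implicit_h(mol)) * 1.008
}
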