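# The four-operator editing calculus and the candidate generator.

test_that("insertion appends one atom and one bond", {
  expect_equal(canonical_form(insertion(parse_molecule("C"), 1, "C", 1)),
               canonical_form(parse_molecule("CC")))
  # water has exactly one free valence slot left after one insertion
  expect_equal(canonical_form(insertion(parse_molecule("O"), 1, "C", 1)),
               canonical_form(parse_molecule("CO")))
  sat <- parse_molecule("FC(F)(F)F")
  expect_error(insertion(sat, 2, "C", 1), "valence")
  expect_error(insertion(parse_molecule("C"), 1, "F", 2), "valence")
  expect_error(insertion(parse_molecule("C"), 5, "C", 1), "index")
})

test_that("replacement swaps the element and keeps bonds", {
  expect_equal(canonical_form(replacement(parse_molecule("CC"), 2, "N")),
               canonical_form(parse_molecule("CN")))
  expect_equal(canonical_form(replacement(parse_molecule("C"), 1, "O")),
               canonical_form(parse_molecule("O")))
  neo <- parse_molecule("CC(C)(C)C")
  expect_error(replacement(neo, 2, "F"), "valence")
  expect_error(replacement(parse_molecule("C"), 1, "C"), "change")
})

test_that("deletion decomposes, filters, and samples deterministically", {
  # raw decomposition of the central-atom deletion
  subs <- deletion_substructures(parse_molecule("CCO"), 2)
  expect_equal(sort(vapply(subs, canonical_form, character(1))), c("C", "O"))
  # but no component passes the sampling floor (parent had 3 atoms)
  expect_error(deletion(parse_molecule("CCO"), 2, rng_stream(1)), "empty-result")

  d <- deletion(parse_molecule("C1CCCCC1"), 1, rng_stream(1))
  expect_length(d$substructures, 1L)
  expect_equal(canonical_form(d$sampled), "CCCCC")

  expect_error(deletion(parse_molecule("C"), 1, rng_stream(1)), "degenerate")

  # all returned components are connected molgraphs (constructor enforces),
  # and terminal deletion keeps the rest intact
  d2 <- deletion(parse_molecule("CC(C)CCO"), 1, rng_stream(2))
  expect_true(all(vapply(d2$substructures, check_valence, logical(1))))
})

test_that("cyclization closes exactly one ring inside the window", {
  cp <- cyclization(parse_molecule("CCCCC"), 1, 5, 1)
  expect_equal(canonical_form(cp), canonical_form(parse_molecule("C1CCCC1")))
  expect_equal(ring_count(cp), 1L)
  expect_equal(canonical_form(cyclization(parse_molecule("CCCCCC"), 1, 6, 1)),
               canonical_form(parse_molecule("C1CCCCC1")))
  expect_error(cyclization(parse_molecule("CC"), 1, 2, 1), "duplicate-bond")
  expect_error(cyclization(parse_molecule("CCCCCCCCCC"), 1, 10, 1),
               "ring-size")
  expect_error(cyclization(parse_molecule("FCCCF"), 1, 5, 1), "valence")
})

test_that("every operator output differs from its input by one atom or one bond", {
  rng <- rng_stream(77)
  for (m in test_corpus()[seq(1, 110, by = 9)]) {
    for (rep in 1:4) {
      pos <- stream_index(rng, n_atoms(m))
      p <- tryCatch(propose(m, pos, rep(0.25, 4), rng, max_atoms = 40L),
                    error = function(e) NULL)
      if (is.null(p)) next
      dn <- n_atoms(p$result) - n_atoms(p$parent)
      db <- n_bonds(p$result) - n_bonds(p$parent)
      switch(p$action$kind,
        insertion = { expect_equal(dn, 1L); expect_equal(db, 1L) },
        replacement = { expect_equal(dn, 0L); expect_equal(db, 0L) },
        cyclization = { expect_equal(dn, 0L); expect_equal(db, 1L) },
        deletion = expect_lte(dn, -1L))
      expect_true(p$valid)
      expect_true(check_valence(p$result))
    }
  }
})

test_that("enumerate_edits matches the independent brute force", {
  for (smi in c("C", "CCO", "C1CC1", "O=C=O", "CC(N)=O", "C1=CC=CC=C1")) {
    m <- parse_molecule(smi)
    for (pos in seq_len(n_atoms(m))) {
      ee <- enumerate_edits(m, pos, vocab = c("C", "N", "O"))
      got <- sort(unique(vapply(ee, function(p) canonical_form(p$result),
                                character(1))))
      expect_identical(got, oracle_enumerate(m, pos, vocab = c("C", "N", "O")),
                       info = paste(smi, pos))
      expect_true(all(vapply(ee, `[[`, logical(1), "valid")))
    }
  }
})

test_that("enumerate_edits on methane has no deletions or cyclizations", {
  kinds <- vapply(enumerate_edits(parse_molecule("C"), 1),
                  function(p) p$action$kind, character(1))
  expect_setequal(unique(kinds), c("insertion", "replacement"))
})

test_that("propose is deterministic given the stream state", {
  m <- fx$fragments$aspirin
  s1 <- vapply(1:100, function(i)
    canonical_form(propose(m, 3, rep(0.25, 4), rng_stream(500 + i))$result),
    character(1))
  s2 <- vapply(1:100, function(i)
    canonical_form(propose(m, 3, rep(0.25, 4), rng_stream(500 + i))$result),
    character(1))
  expect_identical(s1, s2)
})

test_that("propose respects operator weights where all operators are feasible", {
  # interior chain atom of octane: insertion, replacement, deletion and
  # cyclization (ring of size >= 3) are all feasible at position 3
  m <- parse_molecule("CCCCCCCC")
  feas <- unique(vapply(enumerate_edits(m, 3), function(p) p$action$kind,
                        character(1)))
  expect_setequal(feas, operator_set())
  w <- c(0.4, 0.3, 0.2, 0.1)
  rng <- rng_stream(123)
  n_draw <- 10000L
  kinds <- character(n_draw)
  for (i in seq_len(n_draw)) {
    kinds[i] <- propose(m, 3, w, rng)$action$kind
  }
  freq <- table(factor(kinds, levels = operator_set())) / n_draw
  for (k in seq_along(w)) {
    sigma <- sqrt(w[k] * (1 - w[k]) / n_draw)
    expect_lt(abs(freq[[k]] - w[k]), 3 * sigma)
  }
})

test_that("propose falls back over feasible operators and errors when stuck", {
  # delta(insertion) on methane must give an insertion
  p <- propose(parse_molecule("C"), 1, c(1, 0, 0, 0), rng_stream(5))
  expect_equal(p$action$kind, "insertion")
  # delta(deletion) on methane: infeasible, falls back to what exists
  p2 <- propose(parse_molecule("C"), 1, c(0, 0, 1, 0), rng_stream(5))
  expect_true(p2$action$kind %in% c("insertion", "replacement"))
  # CO2's central carbon still admits a C->S replacement under the full
  # vocabulary; sulfate's S(VI) center admits nothing at all
  expect_error(propose(parse_molecule("OS(=O)(=O)O"), 2, rep(0.25, 4),
                       rng_stream(1)),
               "no-edit")
})

test_that("edit_path_exists finds the documented paths", {
  r0 <- edit_path_exists(parse_molecule("CCO"), parse_molecule("CCO"), 5)
  expect_true(r0$found); expect_equal(r0$steps, 0L)

  r1 <- edit_path_exists(parse_molecule("CC"), parse_molecule("CN"), 1)
  expect_true(r1$found); expect_equal(r1$steps, 1L)
  expect_match(r1$path, "replacement")

  r2 <- edit_path_exists(parse_molecule("C"), parse_molecule("c1ccccc1"), 9)
  expect_true(r2$found)
  expect_lte(r2$steps, 9L)
})
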