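# Shared fixtures, built in code. The corpus generator grows >=100
# distinct drug-like molecules from the fixture set by applying seeded
# random edits, exercising the operators while building round-trip data.

fx <- generate_fixtures(1L)

.corpus_cache <- new.env(parent = emptyenv())

# >= n distinct molecules (canonical SMILES) derived from the fixtures
test_corpus <- function(n = 110L) {
  key <- as.character(n)
  if (!is.null(.corpus_cache[[key]])) return(.corpus_cache[[key]])
  seeds_mols <- c(fx$named, fx$fragments)
  seen <- character(0)
  out <- list()
  add <- function(m) {
    smi <- canonical_form(m)
    if (!(smi %in% seen)) {
      seen <<- c(seen, smi)
      out[[length(out) + 1L]] <<- m
    }
  }
  for (m in seeds_mols) add(m)
  rng <- rng_stream(20260910L, "corpus")
  pool <- seeds_mols
  guard <- 0L
  while (length(out) < n && guard < 2000L) {
    guard <- guard + 1L
    m <- pool[[stream_index(rng, length(pool))]]
    pos <- stream_index(rng, n_atoms(m))
    p <- tryCatch(propose(m, pos, rep(0.25, 4), rng, max_atoms = 30L),
                  error = function(e) NULL)
    if (is.null(p)) next
    add(p$result)
    pool[[length(pool) + 1L]] <- p$result
    if (length(pool) > 60L) pool <- pool[-1L]
  }
  .corpus_cache[[key]] <- out
  out
}
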