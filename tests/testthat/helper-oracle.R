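# Independent brute-force oracles over a reaction universe. These use only
# the raw decomposition table (never the generator's stored ground truth or
# the planner), so they can arbitrate both.

# Exhaustive AND-OR solvability: a molecule is solvable when it is a block
# or some template decomposes it entirely into solvable molecules. The path
# argument guards against cycles in hand-built universes.
oracle_solvable <- function(u, m, max_depth = 60L, path = character(0)) {
  if (m %in% u$blocks) return(TRUE)
  if (max_depth <= 0L || m %in% path) return(FALSE)
  for (tid in u$mol_templates[[m]]$template) {
    rs <- u$reactants[[tid]]
    if (all(vapply(rs, oracle_solvable, logical(1),
                   u = u, max_depth = max_depth - 1L, path = c(path, m)))) {
      return(TRUE)
    }
  }
  FALSE
}

# Exhaustive minimal synthesis-set size: the fewest distinct reactions a
# route for m can contain, with intermediates shared across branches.
# Enumerates every possible synthesis set; tractable on toy universes only.
oracle_min_route_size <- function(u, m) {
  all_sets <- function(mol) {
    if (mol %in% u$blocks) return(list(character(0)))
    out <- list()
    for (tid in u$mol_templates[[mol]]$template) {
      rs <- u$reactants[[tid]]
      branch_sets <- lapply(rs, all_sets)
      if (any(lengths(branch_sets) == 0L)) next
      combos <- list(character(0))
      for (bs in branch_sets) {
        combos <- unlist(lapply(combos, function(cur) {
          lapply(bs, function(s) union(cur, s))
        }), recursive = FALSE)
      }
      out <- c(out, lapply(combos, function(s) union(s, mol)))
    }
    keys <- vapply(out, function(s) paste(sort(s), collapse = "|"), character(1))
    out[!duplicated(keys)]
  }
  sizes <- lengths(all_sets(m))
  if (length(sizes) == 0L) Inf else min(sizes)
}

# Exhaustive minimal route length counted with repetition (every occurrence
# of an intermediate counts), matching the generator's min_len semantics.
oracle_min_len <- function(u, m, path = character(0)) {
  if (m %in% u$blocks) return(0)
  if (m %in% path) return(Inf)
  best <- Inf
  for (tid in u$mol_templates[[m]]$template) {
    rs <- u$reactants[[tid]]
    s <- 1 + sum(vapply(rs, oracle_min_len, numeric(1),
                        u = u, path = c(path, m)))
    best <- min(best, s)
  }
  best
}
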