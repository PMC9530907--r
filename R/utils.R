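# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = .GlobalEnv), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Union-find over the bipartite graph with genotype nodes 1..ng and environment
# nodes ng+1..ng+ne; edges are the observed (gi, ei) pairs.  Returns integer
# component ids (1-based, in order of first appearance) for genotype and
# environment levels; levels with no observations get NA.
bipartite_components <- function(gi, ei, ng, ne) {
  parent <- seq_len(ng + ne)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (k in seq_along(gi)) {
    ra <- find(gi[k])
    rb <- find(ng + ei[k])
    if (ra != rb) parent[rb] <- ra
  }
  roots_g <- vapply(seq_len(ng), find, integer(1))
  roots_e <- vapply(ng + seq_len(ne), find, integer(1))
  roots_g[!seq_len(ng) %in% gi] <- NA_integer_
  roots_e[!seq_len(ne) %in% ei] <- NA_integer_
  ids <- unique(stats::na.omit(c(roots_g, roots_e)))
  list(
    g_comp = match(roots_g, ids),
    e_comp = match(roots_e, ids),
    n_comp = length(ids)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
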