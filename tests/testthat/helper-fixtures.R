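# shared fixtures, all built in code

# tiny expression file on disk
write_expr_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# brute-force AUC: enumerate all cross-class pairs, ties count 1/2
brute_auc <- function(scores, labels) {
  hi <- scores[labels == "high"]
  lo <- scores[labels == "low"]
  tot <- 0
  for (a in hi) for (b in lo)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(hi) * length(lo))
}

# brute-force Benjamini-Hochberg step-up: with p sorted ascending,
# q_(i) = min_{j >= i} m p_(j) / j, capped at 1, original order restored
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) m * p[o[j]] / j, numeric(1))
    q[o[i]] <- min(1, vals)
  }
  q
}

# hypergeometric upper tail by direct combinatorial enumeration
brute_overlap_p <- function(k, na, nb, U) {
  js <- k:min(na, nb)
  sum(choose(na, js) * choose(U - na, nb - js)) / choose(U, nb)
}

# adjacency matrix of c disjoint cliques of size s, optional bridge
# between the last node of clique 1 and the first node of clique 2
clique_graph <- function(s, c = 2, bridge = FALSE) {
  n <- s * c
  adj <- matrix(0, n, n, dimnames = rep(list(paste0("v", seq_len(n))), 2))
  for (ci in seq_len(c)) {
    ix <- ((ci - 1) * s + 1):(ci * s)
    adj[ix, ix] <- 1
  }
  diag(adj) <- 0
  if (bridge) adj[s, s + 1] <- adj[s + 1, s] <- 1
  adj
}

# small fast cohort for derivation tests
small_cohort <- function(seed = 5, effect = 2, n = 120, g = 400) {
  simulate_cohort(sim_config(n_samples = n, n_genes = g,
                             planted_up = 15, planted_down = 15,
                             effect_size = effect, seed = seed))
}
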