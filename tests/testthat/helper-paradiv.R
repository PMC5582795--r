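# Shared fixtures and independent oracles for the test suite.

make_aln <- function(...) {
  seqs <- c(...)
  aa_alignment(seqs)
}

write_fasta_tmp <- function(seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

# a small 8-sequence family: two clusters of four, one outgroup-free block
toy_family <- function() {
  aln <- make_aln(
    A1 = "MKTFFSDE", A2 = "MKTFFSDE", A3 = "MKTFFSDE", A4 = "MKTFYSDE",
    B1 = "MKTSFSDQ", B2 = "MKTSFSDQ", B3 = "MKTSFADQ", B4 = "MKTSFSDQ"
  )
  clusters <- cluster_pair(paste0("A", 1:4), paste0("B", 1:4),
                           name1 = "A", name2 = "B")
  tree <- ape::read.tree(text = paste0(
    "(((A1:1,A2:1):1,(A3:1,A4:1):1):2,((B1:1,B2:1):1,(B3:1,B4:1):1):2);"
  ))
  list(aln = aln, clusters = clusters, tree = tree)
}

# brute-force minimum-change count on a rooted/unrooted binary tree by
# enumerating internal-node labelings over the states observed in the column
brute_min_changes <- function(tree, states) {
  stopifnot(length(states) == length(tree$tip.label))
  obs <- unique(states)
  if (length(obs) == 1) return(0L)
  n_tip <- length(tree$tip.label)
  internal <- seq_len(tree$Nnode) + n_tip
  combos <- expand.grid(rep(list(obs), length(internal)),
                        stringsAsFactors = FALSE)
  best <- Inf
  for (i in seq_len(nrow(combos))) {
    lab <- c(states, unlist(combos[i, ], use.names = FALSE))
    changes <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    best <- min(best, changes)
  }
  as.integer(best)
}

# closed-form Pearson chi-square on a 2x2 table
chisq_closed <- function(a, b, cc, d) {
  n <- a + b + cc + d
  n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
}

# two-sided Fisher exact p by hypergeometric enumeration
fisher_enum <- function(a, b, cc, d) {
  m <- a + b          # divergent
  n <- cc + d         # non-divergent
  k <- a + cc         # binding
  x <- max(0, k - n):min(k, m)
  probs <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# build disjoint position sets realizing a given 2x2 table
sets_from_table <- function(a, b, cc, d) {
  list(
    divergent = seq_len(a + b),
    binding = c(seq_len(a), a + b + seq_len(cc)),
    total = a + b + cc + d
  )
}

# minimal posterior profile for call-set tests
fake_profile <- function(Q, model = "type2") {
  out <- tibble::tibble(
    site = seq_along(Q), ref_pos = seq_along(Q),
    x1 = 0L, x2 = 0L, Q = Q, R = Q / (1 - Q)
  )
  class(out) <- c("site_posterior_profile", class(out))
  attr(out, "model") <- model
  out
}
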