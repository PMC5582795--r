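quartet <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

aln_from_states <- function(states, tips) {
  aa_alignment(setNames(states, tips))
}

test_that("Fitch counts match hand-worked quartet cases", {
  tr <- quartet()
  tips <- c("A", "B", "C", "D")
  expect_equal(fitch_counts(aln_from_states(c("F", "F", "F", "F"), tips), tr)$count, 0L)
  expect_equal(fitch_counts(aln_from_states(c("F", "F", "S", "S"), tips), tr)$count, 1L)
  expect_equal(fitch_counts(aln_from_states(c("F", "S", "F", "S"), tips), tr)$count, 2L)
})

test_that("root state sets and tie flags follow the Fitch pass", {
  tr <- quartet()
  tips <- c("A", "B", "C", "D")
  r <- cluster_root_state(aln_from_states(c("K", "K", "K", "K"), tips), tr)
  expect_equal(r$state, "K")
  expect_false(r$tie)

  r <- cluster_root_state(aln_from_states(c("F", "F", "S", "S"), tips), tr)
  expect_true(r$tie)           # root set {F,S}
  expect_equal(r$state, "F")   # 2:2 frequency tie -> alphabetical

  r <- cluster_root_state(aln_from_states(c("F", "F", "F", "S"), tips), tr)
  expect_equal(r$state, "F")
  expect_false(r$tie)

  # frequency breaks the tie before the alphabet does
  tr5 <- ape::read.tree(text = "(((A:1,B:1):1,(C:1,D:1):1):1,E:1);")
  r <- cluster_root_state(
    aln_from_states(c("S", "S", "S", "F", "F"), c("A", "B", "C", "D", "E")), tr5)
  if (r$tie) expect_equal(r$state, "S")
})

test_that("Fitch equals brute-force minimum-change enumeration on 6-leaf trees", {
  set.seed(402)
  for (rep in 1:12) {
    tr <- ape::rtree(6)
    tr$tip.label <- paste0("t", 1:6)
    states <- sample(c("A", "C", "D", "F"), 6, replace = TRUE)
    aln <- aln_from_states(states, tr$tip.label)
    got <- fitch_counts(aln, tr)$count
    expect_equal(got, brute_min_changes(tr, states),
                 info = paste(states, collapse = ""))
  }
})

test_that("Fitch counts agree with an independent parsimony implementation", {
  skip_if_not_installed("phangorn")
  fam <- simulate_family(sim_config(L = 120, theta1 = 0.3, seed = 17))
  sub <- cluster_subtree(fam$tree, fam$clusters$members1)
  got <- fitch_counts(fam$alignment, sub)$count
  rows <- fam$alignment$seq[match(sub$tip.label, fam$alignment$id)]
  dat <- phangorn::phyDat(setNames(strsplit(rows, ""), sub$tip.label),
                          type = "AA")
  want <- phangorn::fitch(sub, dat, site = "site")[attr(dat, "index")]
  expect_equal(got, as.integer(want))
})

test_that("Fitch count is invariant to leaf order and rerooting", {
  set.seed(7)
  tr <- ape::rtree(6)
  tr$tip.label <- paste0("t", 1:6)
  states <- c("A", "A", "C", "D", "C", "A")
  aln <- aln_from_states(states, tr$tip.label)
  base <- fitch_counts(aln, tr)$count

  perm <- sample(seq_len(6))
  aln_perm <- aa_alignment(setNames(states[perm], tr$tip.label[perm]))
  expect_equal(fitch_counts(aln_perm, tr)$count, base)

  for (tip in tr$tip.label[1:3]) {
    rerooted <- ape::root(ape::unroot(tr), outgroup = tip, resolve.root = TRUE)
    expect_equal(fitch_counts(aln, rerooted)$count, base)
  }
})

test_that("Fitch counts respect the parsimony bounds", {
  set.seed(11)
  tr <- ape::rtree(6)
  tr$tip.label <- paste0("t", 1:6)
  for (rep in 1:20) {
    states <- sample(c("A", "C", "D", "E", "F"), 6, replace = TRUE)
    cnt <- fitch_counts(aln_from_states(states, tr$tip.label), tr)$count
    expect_gte(cnt, length(unique(states)) - 1L)
    expect_lte(cnt, 5L)  # leaves - 1
  }
})

test_that("count table assembles both clusters with reference coordinates", {
  fam <- toy_family()
  tab <- build_count_table(fam$aln, fam$tree, fam$clusters, reference_id = "A1")
  expect_s3_class(tab, "site_count_table")
  expect_equal(nrow(tab), 8L)
  expect_equal(tab$ref_pos, 1:8)
  # column 4: fixed F in cluster A vs fixed S in cluster B
  expect_equal(tab$x1[4], 0L)
  expect_equal(tab$x2[4], 0L)
  expect_equal(tab$a1[4], "F")
  expect_equal(tab$a2[4], "S")
  # column 5: A cluster F,F,F,Y -> one change; B cluster all F -> none
  expect_equal(tab$x1[5], 1L)
  expect_equal(tab$x2[5], 0L)
  # column 6: polymorphism only in cluster B
  expect_equal(tab$x1[6], 0L)
  expect_equal(tab$x2[6], 1L)
  # fully conserved columns
  expect_equal(tab$x1[1:3], rep(0L, 3))
  expect_equal(tab$x2[1:3], rep(0L, 3))
  expect_equal(tab$a1[1:3], tab$a2[1:3])
})

test_that("fully conserved alignments give an all-zero table", {
  aln <- make_aln(a1 = "MKTA", a2 = "MKTA", a3 = "MKTA",
                  b1 = "MKTA", b2 = "MKTA", b3 = "MKTA")
  cl <- cluster_pair(c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  tree <- ape::read.tree(
    text = "(((a1:1,a2:1):1,a3:2):1,((b1:1,b2:1):1,b3:2):1);")
  tab <- build_count_table(aln, tree, cl)
  expect_true(all(tab$x1 == 0L & tab$x2 == 0L))
  expect_equal(tab$a1, tab$a2)
})

test_that("parsimony counts track simulator-realized counts on low-rate sites", {
  fam <- simulate_family(sim_config(L = 400, seed = 5))
  tab <- build_count_table(fam$alignment, fam$tree, fam$clusters)
  low <- fam$truth$lambda1 < 1  # sites where multiple hits are unlikely
  agree <- mean(tab$x1[low] == fam$truth$n_changes1[low])
  expect_gte(agree, 0.95)
  # parsimony never exceeds the realized number of changes
  expect_true(all(tab$x1 <= fam$truth$n_changes1))
  expect_true(all(tab$x2 <= fam$truth$n_changes2))
})

test_that("missing leaves are a hard error", {
  fam <- toy_family()
  aln <- fam$aln[fam$aln$id != "A1", ]
  expect_error(fitch_counts(aln, cluster_subtree(fam$tree, paste0("A", 1:4))),
               "absent")
})
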