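# Fitch parsimony: per-site minimum substitution counts within each cluster
# and ancestral states at each cluster root. State sets are 20-bit masks so
# the bottom-up pass is vectorised across sites.

aa_bit <- function(letters) {
  idx <- match(letters, AA_LETTERS)
  bad <- letters[is.na(idx) & !(letters %in% c("-", "X"))]
  if (length(bad) > 0) {
    abort(paste0("invalid residue letters: ", paste(unique(bad), collapse = ", ")))
  }
  out <- ifelse(is.na(idx), bitwShiftL(1L, 20L) - 1L, bitwShiftL(1L, idx - 1L))
  as.integer(out)
}

bitmask_letters <- function(mask) {
  AA_LETTERS[bitwAnd(mask, bitwShiftL(1L, seq_len(20) - 1L)) != 0L]
}

popcount20 <- function(masks) {
  out <- integer(length(masks))
  for (b in seq_len(20)) {
    out <- out + (bitwAnd(masks, bitwShiftL(1L, b - 1L)) != 0L)
  }
  out
}

# Bottom-up (pairwise-fold) Fitch over all columns at once.
# Returns per-site minimum change counts and the root state-set bitmask.
# Exact for binary trees; polytomies are folded child-by-child.
fitch_engine <- function(aln, subtree, sites = NULL) {
  stopifnot(inherits(aln, "aa_alignment"), inherits(subtree, "phylo"))
  tips <- subtree$tip.label
  missing <- setdiff(tips, aln$id)
  if (length(missing) > 0) {
    abort(paste0("tree leaves absent from alignment: ",
                 paste(missing, collapse = ", ")))
  }
  m <- aln_matrix(aln)[tips, , drop = FALSE]
  if (!is.null(sites)) m <- m[, sites, drop = FALSE]
  L <- ncol(m)
  ntip <- length(tips)
  nnode <- subtree$Nnode
  S <- matrix(0L, nrow = ntip + nnode, ncol = L)
  for (i in seq_len(ntip)) S[i, ] <- aa_bit(m[i, ])
  count <- integer(L)
  po <- ape::reorder.phylo(subtree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1]
    child <- po$edge[e, 2]
    cm <- S[child, ]
    pm <- S[parent, ]
    first <- pm == 0L
    inter <- bitwAnd(pm, cm)
    un <- bitwOr(pm, cm)
    S[parent, ] <- ifelse(first, cm, ifelse(inter != 0L, inter, un))
    count <- count + (!first & inter == 0L)
  }
  root <- ntip + 1L
  list(count = count, root_mask = S[root, ], tips = tips, m = m)
}

#' Per-site minimum substitution counts on a cluster subtree
#'
#' Runs the Fitch bottom-up pass on every usable column and returns the
#' minimum number of residue changes required on the subtree at each site —
#' the site observable of the count-based divergence models.
#'
#' @param aln An `aa_alignment`.
#' @param subtree A rooted `phylo` whose leaves (>= 3) are alignment ids.
#' @param mask Optional mask from [build_site_mask()]; counts are reported
#'   for usable sites only.
#' @return A tibble with columns `site` and `count`.
#' @export
fitch_counts <- function(aln, subtree, mask = NULL) {
  if (length(subtree$tip.label) < 3) abort("subtree needs at least 3 leaves")
  sites <- if (is.null(mask)) seq_len(alignment_length(aln)) else
    mask$site[mask$usable]
  eng <- fitch_engine(aln, subtree, sites)
  tibble::tibble(site = sites, count = eng$count)
}

#' Ancestral amino acid at a cluster root
#'
#' Decodes the Fitch root state set per usable site. When the set holds more
#' than one residue the tie is broken deterministically: the residue most
#' frequent among the cluster's leaves at that site, then the alphabetically
#' smallest; `tie` records that the root set was ambiguous so downstream
#' classification can report or drop those sites.
#'
#' @inheritParams fitch_counts
#' @return A tibble with columns `site`, `state` (single letter), `tie`.
#' @export
cluster_root_state <- function(aln, subtree, mask = NULL) {
  if (length(subtree$tip.label) < 3) abort("subtree needs at least 3 leaves")
  sites <- if (is.null(mask)) seq_len(alignment_length(aln)) else
    mask$site[mask$usable]
  eng <- fitch_engine(aln, subtree, sites)
  nset <- popcount20(eng$root_mask)
  state <- character(length(sites))
  for (k in seq_along(sites)) {
    cand <- bitmask_letters(eng$root_mask[k])
    if (length(cand) == 1) {
      state[k] <- cand
    } else {
      freq <- table(factor(eng$m[, k], levels = cand))
      state[k] <- names(freq)[which.max(freq)]  # ties -> first = alphabetical
    }
  }
  tibble::tibble(site = sites, state = state, tie = nset > 1L)
}

#' Assemble the per-site substitution count table
#'
#' Runs the two per-cluster Fitch passes and joins them into the table the
#' divergence models consume: per usable site, the minimum substitution
#' counts `x1`, `x2` within each cluster and the inferred ancestral residues
#' `a1`, `a2` at the two cluster roots (with ambiguity flags).
#'
#' @param aln An `aa_alignment`.
#' @param tree A `phylo` over (at least) all cluster members; typically from
#'   [nj_tree()] or user-supplied Newick.
#' @param clusters A `cluster_pair`.
#' @param mask Optional mask; defaults to [build_site_mask()] on `aln`.
#' @param reference_id Optional reference sequence id; adds reference
#'   coordinates in `ref_pos` (columns where the reference is gapped get NA).
#' @return A `site_count_table` tibble with columns `site`, `ref_pos`, `x1`,
#'   `x2`, `a1`, `a2`, `tie1`, `tie2`. Cluster names and monophyly flags are
#'   carried as attributes.
#' @export
build_count_table <- function(aln, tree, clusters, mask = NULL,
                              reference_id = NULL) {
  check_clusters(aln, clusters)
  if (is.null(mask)) mask <- build_site_mask(aln, clusters)
  sub1 <- cluster_subtree(tree, clusters$members1)
  sub2 <- cluster_subtree(tree, clusters$members2)
  c1 <- fitch_counts(aln, sub1, mask)
  c2 <- fitch_counts(aln, sub2, mask)
  r1 <- cluster_root_state(aln, sub1, mask)
  r2 <- cluster_root_state(aln, sub2, mask)
  ref <- if (is.null(reference_id)) c1$site else
    reference_positions(aln, reference_id)[c1$site]
  out <- tibble::tibble(
    site = c1$site, ref_pos = as.integer(ref),
    x1 = as.integer(c1$count), x2 = as.integer(c2$count),
    a1 = r1$state, a2 = r2$state,
    tie1 = r1$tie, tie2 = r2$tie
  )
  class(out) <- c("site_count_table", class(out))
  attr(out, "cluster_names") <- c(clusters$name1, clusters$name2)
  attr(out, "monophyletic") <- c(attr(sub1, "monophyletic"),
                                 attr(sub2, "monophyletic"))
  out
}
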