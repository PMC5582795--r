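# Poisson-corrected distances, neighbor-joining trees, cluster subtrees.

#' Poisson-corrected protein distance matrix
#'
#' For each pair of sequences, the observed proportion of differing residues
#' p is computed over the columns usable for the pair (the cluster mask, if
#' supplied, intersected with pairwise complete columns: no gap or `X` in
#' either sequence), then corrected for multiple hits as d = -ln(1 - p).
#' Near-saturated pairs have p capped at `p_cap` with a warning rather than
#' failing, so batch runs stay alive.
#'
#' @param aln An `aa_alignment` (>= 2 sequences).
#' @param mask Optional site mask from [build_site_mask()]; only `usable`
#'   columns enter the comparison.
#' @param p_cap Cap applied to p before the log correction (default 0.95).
#' @return A symmetric numeric matrix with ids as dimnames, zero diagonal.
#' @export
poisson_distance <- function(aln, mask = NULL, p_cap = 0.95) {
  stopifnot(inherits(aln, "aa_alignment"))
  n <- nrow(aln)
  if (n < 2) abort("need at least 2 sequences")
  m <- aln_matrix(aln)
  if (!is.null(mask)) m <- m[, mask$usable, drop = FALSE]
  ok <- m != "-" & m != "X"
  d <- matrix(0, n, n, dimnames = list(aln$id, aln$id))
  capped <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      shared <- ok[i, ] & ok[j, ]
      if (!any(shared)) {
        abort(paste0("no shared usable columns for pair ",
                     aln$id[i], " / ", aln$id[j]))
      }
      p <- mean(m[i, shared] != m[j, shared])
      if (p > p_cap) {
        p <- p_cap
        capped <- TRUE
      }
      d[i, j] <- d[j, i] <- -log(1 - p)
    }
  }
  if (capped) {
    warn(paste0("some pairwise differences exceeded ", p_cap,
                "; capped before the Poisson correction"))
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining via [ape::nj()]. Negative estimated branch
#' lengths are clamped to zero (standard practice); the pre-clamp lengths are
#' kept in the `original_edge_lengths` attribute.
#'
#' @param dm Symmetric distance matrix with id dimnames (>= 3 taxa), or a
#'   `dist` object.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  if (nrow(dm) < 3) abort("neighbor joining needs at least 3 taxa")
  tree <- ape::nj(stats::as.dist(dm))
  orig <- tree$edge.length
  if (any(orig < 0)) {
    tree$edge.length <- pmax(orig, 0)
    attr(tree, "original_edge_lengths") <- orig
  }
  tree
}

#' Extract the subtree induced by one cluster
#'
#' Roots the tree between the two clusters, checks that `members` form a
#' clade, and returns the induced subtree with path branch lengths preserved.
#' A non-monophyletic cluster is not fatal: the induced subtree is returned
#' anyway with a warning and `monophyletic = FALSE` in the attributes, since
#' Fitch substitution counts do not depend on where the subtree is rooted.
#'
#' @param tree A `phylo` over all taxa.
#' @param members Character vector of leaf labels forming the cluster.
#' @return A rooted `phylo` on `members`, with attribute `monophyletic`.
#' @export
cluster_subtree <- function(tree, members) {
  stopifnot(inherits(tree, "phylo"))
  members <- unique(as.character(members))
  missing <- setdiff(members, tree$tip.label)
  if (length(missing) > 0) {
    abort(paste0("cluster members absent from tree: ",
                 paste(missing, collapse = ", ")))
  }
  others <- setdiff(tree$tip.label, members)
  if (length(others) == 0) {
    sub <- tree
    if (!ape::is.rooted(sub)) sub <- ape::root(sub, 1, resolve.root = TRUE)
    attr(sub, "monophyletic") <- TRUE
    return(sub)
  }
  rooted <- ape::root(ape::unroot(tree), outgroup = others[1],
                      resolve.root = TRUE)
  mono <- ape::is.monophyletic(rooted, members)
  if (mono && length(members) >= 2) {
    node <- ape::getMRCA(rooted, members)
    sub <- ape::extract.clade(rooted, node)
  } else {
    if (!mono) {
      warn("cluster is not monophyletic in the tree; using the induced subtree")
    }
    sub <- ape::keep.tip(rooted, members)
    if (!ape::is.rooted(sub)) sub <- ape::root(sub, 1, resolve.root = TRUE)
  }
  attr(sub, "monophyletic") <- mono
  sub
}
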