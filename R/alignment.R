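# Protein alignment input, validation, masking and column resampling.

AA_LETTERS <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)
ALN_ALPHABET <- c(AA_LETTERS, "-", "X")

new_alignment <- function(ids, rows) {
  out <- tibble::tibble(id = ids, seq = rows)
  class(out) <- c("aa_alignment", class(out))
  out
}

#' Construct a protein alignment from sequences
#'
#' Builds the validated alignment container used throughout the package: a
#' tibble with one row per sequence (`id`, `seq`), all sequences the same
#' length, over the 20 standard amino-acid letters plus gap `-` and unknown
#' `X`. Input is case-folded to upper case.
#'
#' @param seqs Named character vector of aligned sequences (names are ids), or
#'   an unnamed vector plus `ids`.
#' @param ids Optional character vector of sequence identifiers.
#' @return An `aa_alignment` tibble with columns `id` and `seq`.
#' @export
aa_alignment <- function(seqs, ids = names(seqs)) {
  if (length(seqs) == 0) abort("alignment is empty")
  if (is.null(ids)) abort("sequence ids are required")
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (anyDuplicated(ids)) {
    abort(paste0(
      "duplicate sequence ids: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) {
    bad <- ids[which(lens != lens[1])[1]]
    abort(paste0(
      "alignment is ragged: sequence '", bad, "' has length ",
      lens[which(lens != lens[1])[1]], ", expected ", lens[1]
    ))
  }
  if (lens[1] < 1) abort("alignment has zero columns")
  chars <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  bad_chars <- setdiff(chars, ALN_ALPHABET)
  if (length(bad_chars) > 0) {
    abort(paste0(
      "invalid residue letters: ", paste(bad_chars, collapse = ", "),
      " (allowed: the 20 standard amino acids, '-', 'X';",
      " 'U'/'O' and ambiguity codes are rejected)"
    ))
  }
  new_alignment(ids, seqs)
}

#' Read an aligned protein FASTA file
#'
#' Parses an aligned FASTA file with [Biostrings::readAAStringSet()] and
#' validates it: equal lengths, unique ids, alphabet restricted to the 20
#' amino-acid letters plus `-` and `X` (lower case is folded). FASTA ids are
#' truncated at the first whitespace.
#'
#' @param path Path to an aligned FASTA file.
#' @return An `aa_alignment` tibble; input record order is preserved.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) abort(paste0("no FASTA records in ", path))
  ids <- sub("\\s.*$", "", names(set))
  aa_alignment(as.character(set), ids = ids)
}

#' Write an alignment to FASTA
#'
#' @param aln An `aa_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "aa_alignment"))
  set <- Biostrings::AAStringSet(setNames(aln$seq, aln$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Alignment length (number of columns)
#' @param aln An `aa_alignment`.
#' @return Integer number of sites.
#' @export
alignment_length <- function(aln) nchar(aln$seq[1])

# character matrix view, n_seq x L, rownames = ids
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seq, ""))
  rownames(m) <- aln$id
  m
}

#' Define the two paralog clusters
#'
#' A cluster pair assigns sequence ids to the two ortholog clusters flanking
#' the duplication (for example the GCGR orthologs vs the GLP-1R orthologs).
#' Members must be disjoint and each cluster needs at least three members so
#' that within-cluster substitution counts are defined.
#'
#' @param members1,members2 Character vectors of sequence ids.
#' @param name1,name2 Cluster display names.
#' @return A `cluster_pair` object.
#' @export
cluster_pair <- function(members1, members2,
                         name1 = "cluster1", name2 = "cluster2") {
  members1 <- unique(as.character(members1))
  members2 <- unique(as.character(members2))
  both <- intersect(members1, members2)
  if (length(both) > 0) {
    abort(paste0("clusters overlap: ", paste(both, collapse = ", ")))
  }
  if (length(members1) < 3 || length(members2) < 3) {
    abort("each cluster needs at least 3 members for substitution counting")
  }
  structure(
    list(name1 = name1, name2 = name2,
         members1 = members1, members2 = members2),
    class = "cluster_pair"
  )
}

#' @export
print.cluster_pair <- function(x, ...) {
  cat("<cluster_pair> ", x$name1, " (", length(x$members1), ") vs ",
      x$name2, " (", length(x$members2), ")\n", sep = "")
  invisible(x)
}

#' Read a cluster assignment table
#'
#' Reads a two-column TSV (`sequence_id`, `cluster_label`) with exactly two
#' distinct labels and returns the corresponding [cluster_pair()]. Cluster 1
#' is the label that appears first in the file.
#'
#' @param path Path to a headerless or headered two-column TSV.
#' @param header Does the file have a header row? Default `TRUE`.
#' @return A `cluster_pair`.
#' @export
read_clusters <- function(path, header = TRUE) {
  df <- read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(df) < 2) abort("cluster file needs two columns: id, label")
  ids <- as.character(df[[1]])
  labels <- as.character(df[[2]])
  labs <- unique(labels)
  if (length(labs) != 2) {
    abort(paste0("expected exactly 2 cluster labels, found ", length(labs)))
  }
  cluster_pair(ids[labels == labs[1]], ids[labels == labs[2]],
               name1 = labs[1], name2 = labs[2])
}

check_clusters <- function(aln, clusters) {
  stopifnot(inherits(clusters, "cluster_pair"))
  missing <- setdiff(c(clusters$members1, clusters$members2), aln$id)
  if (length(missing) > 0) {
    abort(paste0(
      "cluster members absent from alignment: ",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(TRUE)
}

#' Build the usable-site mask for a cluster pair
#'
#' Complete deletion with respect to cluster members: a column is usable only
#' if no member of either cluster carries a gap or an `X` there. Gaps in
#' sequences outside the clusters (e.g. outgroups) do not exclude a column.
#'
#' @param aln An `aa_alignment`.
#' @param clusters A `cluster_pair` whose members are all present in `aln`.
#' @return A tibble with columns `site` (1-based alignment column), `usable`
#'   (logical) and `reason` (`NA`, `"gap"` or `"unknown"`; gap wins when a
#'   column has both).
#' @export
build_site_mask <- function(aln, clusters) {
  check_clusters(aln, clusters)
  m <- aln_matrix(aln)[c(clusters$members1, clusters$members2), , drop = FALSE]
  has_gap <- colSums(m == "-") > 0
  has_x <- colSums(m == "X") > 0
  usable <- !(has_gap | has_x)
  if (!any(usable)) abort("no usable columns after gap/unknown exclusion")
  tibble::tibble(
    site = seq_len(ncol(m)),
    usable = usable,
    reason = dplyr::case_when(has_gap ~ "gap", has_x ~ "unknown",
                              TRUE ~ NA_character_)
  )
}

#' Bootstrap alignment columns
#'
#' Draws alignment columns with replacement to produce replicate alignments
#' of the original length, the standard alignment bootstrap (e.g. 500
#' replicates for tree support or estimator uncertainty).
#'
#' @param aln An `aa_alignment`.
#' @param n_reps Number of replicates (>= 1).
#' @param seed Integer seed; the replicate series is reproducible.
#' @return A list of `n_reps` `aa_alignment` objects.
#' @export
bootstrap_columns <- function(aln, n_reps, seed = 1L) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (!is.numeric(n_reps) || n_reps < 1) abort("n_reps must be >= 1")
  n_reps <- as.integer(n_reps)
  L <- alignment_length(aln)
  m <- aln_matrix(aln)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))
  lapply(seq_len(n_reps), function(i) {
    cols <- sample.int(L, L, replace = TRUE)
    new_alignment(aln$id,
                  unname(apply(m[, cols, drop = FALSE], 1, paste, collapse = "")))
  })
}

# save/restore global RNG state so seeded helpers don't disturb callers
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(state) {
  if (is.null(state)) return(invisible())
  assign(".Random.seed", state, envir = globalenv())
}

#' Map alignment columns to reference-sequence positions
#'
#' Site indices are reported as 1-based positions on a named reference
#' sequence (e.g. human GCGR), counted over its ungapped residues, matching
#' the usual "F345" residue-numbering convention.
#'
#' @param aln An `aa_alignment`.
#' @param reference_id Id of the reference sequence in `aln`.
#' @return Integer vector of length L: reference position per alignment
#'   column, `NA` where the reference has a gap.
#' @export
reference_positions <- function(aln, reference_id) {
  if (!reference_id %in% aln$id) {
    abort(paste0("reference sequence '", reference_id, "' not in alignment"))
  }
  ref <- strsplit(aln$seq[aln$id == reference_id], "")[[1]]
  pos <- cumsum(ref != "-")
  pos[ref == "-"] <- NA_integer_
  as.integer(pos)
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("<aa_alignment> ", nrow(x), " sequences x ", alignment_length(x),
      " columns\n", sep = "")
  NextMethod()
}
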