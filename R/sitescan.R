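# Divergent-site calling, per-cluster conservation summaries, the type-II
# conservation-pattern check, and binding-site enrichment tests.

#' Call divergent sites from a posterior profile
#'
#' Sites whose posterior probability exceeds the cutoff (strict inequality),
#' the empirical rule Q(k) > 0.67, i.e. posterior ratio R(k) > 2. The cutoff
#' may equivalently be given as a posterior-ratio threshold.
#'
#' @param profile A `site_posterior_profile`.
#' @param cutoff Posterior-probability cutoff in (0, 1); default 0.67.
#' @param ratio_cutoff Optional posterior-ratio cutoff r; overrides `cutoff`
#'   with r/(1+r).
#' @return The profile rows with Q > cutoff, ordered by decreasing Q.
#' @export
call_divergent_sites <- function(profile, cutoff = 0.67, ratio_cutoff = NULL) {
  if (!is.null(ratio_cutoff)) {
    if (ratio_cutoff <= 0) abort("ratio_cutoff must be > 0")
    cutoff <- ratio_cutoff / (1 + ratio_cutoff)
  }
  if (cutoff <= 0 || cutoff >= 1) abort("cutoff must be inside (0, 1)")
  out <- dplyr::arrange(dplyr::filter(profile, .data$Q > cutoff),
                        dplyr::desc(.data$Q))
  tibble::as_tibble(out)
}

#' Per-cluster conservation summary
#'
#' For each requested site and each cluster: the modal residue, its
#' frequency among cluster members, and the full residue tally — the inputs
#' for logo-style conservation reporting.
#'
#' @param aln An `aa_alignment`.
#' @param clusters A `cluster_pair`.
#' @param sites Alignment column indices; default all columns.
#' @return A tibble with columns `site`, `cluster`, `modal_residue`,
#'   `modal_fraction`, and `residues` (list column of named frequency
#'   tables over non-gap residues).
#' @export
conservation_summary <- function(aln, clusters, sites = NULL) {
  check_clusters(aln, clusters)
  if (is.null(sites)) sites <- seq_len(alignment_length(aln))
  m <- aln_matrix(aln)
  one <- function(members, name) {
    sub <- m[members, sites, drop = FALSE]
    purrr::map_dfr(seq_along(sites), function(j) {
      col <- sub[, j]
      col <- col[col != "-" & col != "X"]
      tab <- if (length(col)) sort(table(col), decreasing = TRUE) else table(col)
      tibble::tibble(
        site = sites[j], cluster = name,
        modal_residue = if (length(tab)) names(tab)[1] else NA_character_,
        modal_fraction = if (length(tab)) unname(tab[1]) / sum(tab) else NA_real_,
        residues = list(tab / max(sum(tab), 1))
      )
    })
  }
  dplyr::arrange(
    dplyr::bind_rows(one(clusters$members1, clusters$name1),
                     one(clusters$members2, clusters$name2)),
    .data$site
  )
}

#' Check the canonical type-II conservation pattern at sites
#'
#' A site shows the canonical type-II pattern when it is conserved within
#' each cluster (modal-residue fraction >= `tau` in both) while the two
#' modal residues differ radically in physicochemical group — e.g. a site
#' fixed hydrophobic in one paralog's orthologs and hydrophilic in the
#' other's.
#'
#' @param sites Alignment column indices to check.
#' @param aln An `aa_alignment`.
#' @param clusters A `cluster_pair`.
#' @param scheme An [aa_group_scheme()].
#' @param tau Within-cluster conservation threshold (default 0.8).
#' @return A tibble: `site`, `modal1`, `fraction1`, `modal2`, `fraction2`,
#'   `change_class`, `pattern` (logical).
#' @export
type2_pattern_check <- function(sites, aln, clusters,
                                scheme = aa_group_scheme(), tau = 0.8) {
  cons <- conservation_summary(aln, clusters, sites)
  c1 <- dplyr::filter(cons, .data$cluster == clusters$name1)
  c2 <- dplyr::filter(cons, .data$cluster == clusters$name2)
  cls <- ifelse(
    is.na(c1$modal_residue) | is.na(c2$modal_residue), NA_character_,
    classify_change(c1$modal_residue, c2$modal_residue, scheme)
  )
  tibble::tibble(
    site = c1$site,
    modal1 = c1$modal_residue, fraction1 = c1$modal_fraction,
    modal2 = c2$modal_residue, fraction2 = c2$modal_fraction,
    change_class = cls,
    pattern = !is.na(cls) & cls == "radical" &
      c1$modal_fraction >= tau & c2$modal_fraction >= tau
  )
}

#' Read a binding-site residue list
#'
#' TSV with columns `position` (1-based on the reference sequence),
#' `residue` (expected letter) and optionally `label`.
#'
#' @param path File path.
#' @param header Header row present? Default `TRUE`.
#' @return A `binding_site_list` tibble.
#' @export
read_binding_sites <- function(path, header = TRUE) {
  df <- read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(df) < 2) abort("binding-site file needs columns: position, residue")
  names(df)[1:2] <- c("position", "residue")
  if (ncol(df) < 3) df$label <- NA_character_ else names(df)[3] <- "label"
  out <- tibble::as_tibble(df[c("position", "residue", "label")])
  out$position <- as.integer(out$position)
  out$residue <- toupper(out$residue)
  class(out) <- c("binding_site_list", class(out))
  out
}

#' Validate binding-site letters against the reference sequence
#'
#' Each stated residue letter must match the reference residue at that
#' 1-based ungapped position; a mismatch is a hard error, catching
#' coordinate-system mistakes before any enrichment arithmetic.
#'
#' @param binding A `binding_site_list` (or tibble with `position`,
#'   `residue`).
#' @param aln An `aa_alignment` containing the reference.
#' @param reference_id Reference sequence id.
#' @return `binding`, invisibly, if valid.
#' @export
validate_binding_sites <- function(binding, aln, reference_id) {
  ref <- gsub("-", "", aln$seq[aln$id == reference_id])
  if (length(ref) == 0) {
    abort(paste0("reference '", reference_id, "' not in alignment"))
  }
  if (any(binding$position < 1 | binding$position > nchar(ref))) {
    abort("binding-site positions outside the reference sequence")
  }
  found <- strsplit(ref, "")[[1]][binding$position]
  bad <- which(found != binding$residue)
  if (length(bad) > 0) {
    abort(paste0(
      "binding-site residue mismatch at position ",
      paste0(binding$position[bad], " (stated ", binding$residue[bad],
             ", reference ", found[bad], ")", collapse = "; ")
    ))
  }
  invisible(binding)
}

#' Enrichment of divergent sites within a binding-site set
#'
#' Builds the 2x2 table (divergent x binding) over `total_length` scanned
#' residues and tests association with Pearson's chi-square (1 df, no
#' continuity correction) or Fisher's exact test. When any expected cell is
#' below 5 the chi-square result carries a note suggesting the exact test.
#'
#' @param divergent Integer positions called divergent (deduplicated).
#' @param binding Integer positions of the binding site, or a
#'   `binding_site_list`.
#' @param total_length Total residues scanned (e.g. the reference's ungapped
#'   length).
#' @param method `"chisq"` (default) or `"fisher"`.
#' @return An `enrichment_result` with the 2x2 table, statistic, p-value,
#'   odds ratio, and (when computed) the Fisher exact p-value. See
#'   [glance.enrichment_result()].
#' @export
enrichment_test <- function(divergent, binding, total_length,
                            method = c("chisq", "fisher")) {
  method <- match.arg(method)
  if (inherits(binding, "binding_site_list") || is.data.frame(binding)) {
    binding <- binding$position
  }
  divergent <- unique(as.integer(divergent))
  binding <- unique(as.integer(binding))
  if (length(binding) > 0 && max(binding) > total_length ||
      length(divergent) > 0 && max(divergent) > total_length ||
      total_length < length(union(divergent, binding))) {
    abort("total_length smaller than the site sets it must contain")
  }
  a <- length(intersect(divergent, binding))   # divergent & binding
  b <- length(setdiff(divergent, binding))     # divergent only
  cc <- length(setdiff(binding, divergent))    # binding only
  d <- total_length - a - b - cc
  tab <- matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE,
                dimnames = list(divergent = c("yes", "no"),
                                binding = c("yes", "no")))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  fisher_p <- NA_real_
  note <- NA_character_
  if (method == "chisq") {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    statistic <- unname(ct$statistic)
    p <- unname(ct$p.value)
    if (any(expected < 5)) {
      note <- "expected cell count < 5; consider the Fisher exact test"
      fisher_p <- fisher.test(tab)$p.value
    }
  } else {
    ft <- fisher.test(tab)
    statistic <- NA_real_
    p <- ft$p.value
    fisher_p <- p
  }
  or <- (a * d) / (b * cc)
  structure(
    list(table = tab, method = method, statistic = statistic, p_value = p,
         fisher_p = fisher_p, odds_ratio = or, total_length = total_length,
         expected = expected, note = note),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result> ", x$method, " test\n", sep = "")
  print(x$table)
  if (is.finite(x$statistic)) {
    cat(sprintf("  chi-square = %.4g, p = %.4g\n", x$statistic, x$p_value))
  } else {
    cat(sprintf("  p = %.4g\n", x$p_value))
  }
  cat(sprintf("  odds ratio = %.4g\n", x$odds_ratio))
  if (is.finite(x$fisher_p) && x$method != "fisher") {
    cat(sprintf("  Fisher exact p = %.4g\n", x$fisher_p))
  }
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Tidy the 2x2 enrichment table
#'
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @return A four-row tibble: `divergent`, `binding`, `n`, `expected`.
#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble::tibble(
    divergent = rep(c("yes", "no"), each = 2),
    binding = rep(c("yes", "no"), 2),
    n = as.vector(t(x$table)),
    expected = as.vector(t(x$expected))
  )
}

#' One-row summary of an enrichment test
#'
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @return A one-row tibble with the statistic, p-values and odds ratio.
#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    statistic = x$statistic,
    p.value = x$p_value,
    fisher.p.value = x$fisher_p,
    odds_ratio = x$odds_ratio,
    n_divergent = sum(x$table[1, ]),
    n_binding = sum(x$table[, 1]),
    total_length = x$total_length
  )
}
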