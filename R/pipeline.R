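# End-to-end analysis: alignment + clusters in, divergence report bundle out.

#' Run the full divergence analysis
#'
#' Orchestrates the whole analysis: read and mask the alignment, build (or
#' accept) the tree, count substitutions by Fitch parsimony on the two
#' cluster subtrees, fit the type-I and type-II mixtures, call divergent
#' sites at the Q cutoff, and (when a binding-site list is given) test
#' enrichment of the called type-II sites within it. All results are written
#' to `out_dir` as plain-text tables and JSON, together with the resolved
#' configuration and a run log; the full set of result objects is returned
#' invisibly.
#'
#' @param config Path to a YAML or JSON configuration file, or an equivalent
#'   named list. Recognised fields: `alignment` (aligned FASTA path; or pass
#'   `aln`), `clusters` (two-column TSV path; or pass a `cluster_pair` as
#'   `clusters`), `tree` (optional Newick path), `reference_id` (optional),
#'   `binding_sites` (optional TSV path), `q_cutoff` (default 0.67), `tau`
#'   (default 0.8), `epsilon` (default 0.1), `pi_r`
#'   (`NULL` = scheme neutral, or `"empirical"`), `total_length` (default:
#'   reference ungapped length), `enrichment_method` (`"chisq"`), `seed`
#'   (recorded), `out_dir` (default `"paradiv_run"`).
#' @param out_dir Output directory; overrides the config field.
#' @return Invisibly, a list with `mask`, `tree`, `counts`, `profile2`,
#'   `fit1`, `fit2`, `posterior1`, `posterior2`, `called`, `pattern`,
#'   `enrichment` (or `NULL`), and `config`.
#' @export
run_divergence <- function(config, out_dir = NULL) {
  cfg <- resolve_run_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
    cat(msg, "\n", file = log_path, append = TRUE)
    inform(msg)
  }
  fail_marker <- file.path(cfg$out_dir, "FAILED")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage: ", name, "\n", conditionMessage(e)), fail_marker)
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  logf("paradiv ", as.character(utils::packageVersion("paradiv")),
       " | seed ", cfg$seed %||% "none")

  aln <- stage("alignment", {
    if (inherits(cfg$aln, "aa_alignment")) cfg$aln else read_alignment(cfg$alignment)
  })
  clusters <- stage("clusters", {
    if (inherits(cfg$clusters, "cluster_pair")) cfg$clusters else
      read_clusters(cfg$clusters)
  })
  logf("alignment: ", nrow(aln), " sequences x ", alignment_length(aln),
       " columns")

  mask <- stage("mask", build_site_mask(aln, clusters))
  write.table(mask, file.path(cfg$out_dir, "site_mask.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  logf("mask: ", sum(mask$usable), " usable of ", nrow(mask), " columns")

  tree <- stage("tree", {
    if (!is.null(cfg$tree_obj)) cfg$tree_obj
    else if (!is.null(cfg$tree)) ape::read.tree(cfg$tree)
    else nj_tree(poisson_distance(aln, mask))
  })
  ape::write.tree(tree, file.path(cfg$out_dir, "tree.nwk"))

  counts <- stage("counts", build_count_table(aln, tree, clusters, mask,
                                              reference_id = cfg$reference_id))
  write.table(counts, file.path(cfg$out_dir, "site_counts.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)

  fit1 <- stage("type1_fit", fit_type1(counts))
  post1 <- type1_posteriors(counts, fit1)
  profile2 <- early_profile(counts, cfg$scheme)
  fit2 <- stage("type2_fit", fit_type2(profile2, pi_r = cfg$pi_r,
                                       epsilon = cfg$epsilon))
  post2 <- type2_posteriors(profile2, fit2)
  logf(sprintf("type-I theta = %.4f +/- %.4f (p = %.3g)",
               fit1$theta, fit1$se, fit1$p_value))
  logf(sprintf("type-II theta = %.4f +/- %.4f (p = %.3g)",
               fit2$theta, fit2$se, fit2$p_value))

  write_fit_json(fit1, file.path(cfg$out_dir, "type1_estimate.json"))
  write_fit_json(fit2, file.path(cfg$out_dir, "type2_estimate.json"))
  write.table(post1, file.path(cfg$out_dir, "type1_profile.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(post2[setdiff(names(post2), "residues")],
              file.path(cfg$out_dir, "type2_profile.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)

  called <- call_divergent_sites(post2, cutoff = cfg$q_cutoff)
  pattern <- if (nrow(called) > 0) {
    type2_pattern_check(called$site, aln, clusters, cfg$scheme, tau = cfg$tau)
  } else {
    NULL
  }
  write.table(called, file.path(cfg$out_dir, "called_sites.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  logf(nrow(called), " type-II sites called at Q > ", cfg$q_cutoff)

  enrichment <- NULL
  if (!is.null(cfg$binding_sites)) {
    enrichment <- stage("enrichment", {
      binding <- read_binding_sites(cfg$binding_sites)
      if (!is.null(cfg$reference_id)) {
        validate_binding_sites(binding, aln, cfg$reference_id)
      }
      total <- cfg$total_length %||% {
        if (is.null(cfg$reference_id)) {
          abort("total_length or reference_id needed for enrichment")
        }
        nchar(gsub("-", "", aln$seq[aln$id == cfg$reference_id]))
      }
      enrichment_test(called$ref_pos, binding, total,
                      method = cfg$enrichment_method)
    })
    jsonlite::write_json(glance(enrichment),
                         file.path(cfg$out_dir, "enrichment.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  echo <- cfg[setdiff(names(cfg), c("aln", "clusters", "tree_obj", "scheme"))]
  jsonlite::write_json(echo, file.path(cfg$out_dir, "run_config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  if (file.exists(fail_marker)) file.remove(fail_marker)
  logf("done")

  invisible(list(
    mask = mask, tree = tree, counts = counts, profile2 = profile2,
    fit1 = fit1, fit2 = fit2, posterior1 = post1, posterior2 = post2,
    called = called, pattern = pattern, enrichment = enrichment,
    config = cfg
  ))
}

resolve_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config) else
      jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) abort("config must be a list or a YAML/JSON path")
  defaults <- list(
    q_cutoff = 0.67, tau = 0.8, epsilon = 0.1, pi_r = NULL,
    enrichment_method = "chisq", out_dir = "paradiv_run", seed = NULL,
    reference_id = NULL, binding_sites = NULL, tree = NULL,
    total_length = NULL, scheme = aa_group_scheme()
  )
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  if (cfg$q_cutoff <= 0 || cfg$q_cutoff >= 1) {
    abort("q_cutoff must be inside (0, 1)")
  }
  for (f in c("alignment", "clusters", "tree", "binding_sites")) {
    v <- cfg[[f]]
    if (is.character(v) && length(v) == 1 && !file.exists(v)) {
      abort(paste0("config file not found: ", f, " = ", v))
    }
  }
  cfg
}

write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(model = fit$model, theta = fit$theta, se_theta = fit$se,
         params = fit$params, loglik = fit$loglik,
         loglik_null = fit$loglik_null, lrt = fit$lrt,
         p_value = fit$p_value, n_sites = fit$n_sites,
         boundary = fit$boundary, flags = as.list(fit$flags),
         extra = fit$extra),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
}
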