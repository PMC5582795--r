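# Type-II functional divergence: a radical physicochemical shift on the
# inter-cluster branch followed by conservation within each cluster.
#
# Observables per site: the early-phase change class c in {N, C, R} (the two
# cluster-root residues identical / changed within a physicochemical group /
# changed across groups) and the late-phase within-cluster substitution
# counts (x1, x2). Under F0 a shared gamma site rate drives both phases:
# an early change fires with probability 1 - exp(-lambda d_e) and is radical
# with the scheme's neutral probability pi_R; late counts are
# Poisson(lambda m_i). Under F1 (type-II divergent, weight theta_II) the
# early change is radical with probability one and the late-phase rates are
# shrunk by the conservation factor epsilon.
#
# The gamma rate integrates in closed form: each class/count cell is a
# difference of bivariate negative-binomial-type terms, since
# integral lambda^x e^(-lambda s) dGamma(alpha, alpha) is analytic and
# 1 - exp(-lambda d_e) splits the class probability into two such terms.
# No rate-discretization error enters the likelihood.

#' Physicochemical amino-acid group scheme
#'
#' The four-group partition used to label a replacement radical (across
#' groups) or conserved (within a group): positively-charged \{K, R, H\},
#' negatively-charged \{D, E\}, hydrophilic \{S, T, N, Q, C, G, P\},
#' hydrophobic \{A, I, L, M, F, W, V, Y\}. A custom scheme may be supplied
#' as a named list of letter vectors; it must partition the 20 letters.
#'
#' @param groups Named list of character vectors partitioning the 20
#'   amino-acid letters. Default: the four physicochemical groups above.
#' @return An `aa_group_scheme`: named character vector letter -> group.
#' @export
aa_group_scheme <- function(groups = list(
  positive = c("K", "R", "H"),
  negative = c("D", "E"),
  hydrophilic = c("S", "T", "N", "Q", "C", "G", "P"),
  hydrophobic = c("A", "I", "L", "M", "F", "W", "V", "Y")
)) {
  all_letters <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_letters)) abort("scheme groups overlap")
  if (!setequal(all_letters, AA_LETTERS)) {
    abort("scheme must partition the 20 standard amino-acid letters")
  }
  map <- character(0)
  for (g in names(groups)) map[groups[[g]]] <- g
  structure(map[AA_LETTERS], names = AA_LETTERS, class = "aa_group_scheme")
}

#' Classify an amino-acid replacement
#'
#' `identical` if the two letters agree, `radical` if they fall in different
#' physicochemical groups, `conserved` otherwise. Vectorised and symmetric
#' in its two arguments.
#'
#' @param a,b Single amino-acid letters (vectors recycle).
#' @param scheme An [aa_group_scheme()].
#' @return Character vector in \{"identical", "conserved", "radical"\}.
#' @export
classify_change <- function(a, b, scheme = aa_group_scheme()) {
  a <- toupper(a); b <- toupper(b)
  bad <- setdiff(unique(c(a, b)), AA_LETTERS)
  if (length(bad) > 0) {
    abort(paste0("letters outside the 20-letter alphabet: ",
                 paste(bad, collapse = ", ")))
  }
  ifelse(a == b, "identical",
         ifelse(scheme[a] != scheme[b], "radical", "conserved"))
}

#' Neutral radical fraction of a group scheme
#'
#' The fraction of the 190 unordered heterotypic residue pairs that are
#' radical under the scheme — the probability that a random substitution is
#' radical when all replacements are equally likely, used as the default
#' early-phase radical probability `pi_r` in the type-II likelihood.
#'
#' @param scheme An [aa_group_scheme()].
#' @return A probability in \[0, 1\].
#' @export
scheme_radical_fraction <- function(scheme = aa_group_scheme()) {
  pairs <- combn(AA_LETTERS, 2)
  mean(scheme[pairs[1, ]] != scheme[pairs[2, ]])
}

#' Early-phase change profile from ancestral states
#'
#' Classifies the inter-cluster change at each usable site from the two
#' cluster-root residues: `N` (identical ancestors), `C` (conserved change)
#' or `R` (radical change). Ancestral-state ambiguity flags are propagated
#' (`tie = tie1 | tie2`).
#'
#' @param table A `site_count_table` from [build_count_table()].
#' @param scheme An [aa_group_scheme()].
#' @return The table with added columns `class` and `tie`, classed
#'   `early_change_profile`.
#' @export
early_profile <- function(table, scheme = aa_group_scheme()) {
  cls <- classify_change(table$a1, table$a2, scheme)
  out <- dplyr::mutate(
    table,
    class = dplyr::recode(cls, identical = "N", conserved = "C", radical = "R"),
    tie = table$tie1 | table$tie2
  )
  class(out) <- unique(c("early_change_profile", class(table)))
  attr(out, "scheme") <- scheme
  out
}

check_type2_params <- function(params) {
  need <- c("alpha", "m1", "m2", "d_e", "pi_r", "epsilon")
  miss <- setdiff(need, names(params))
  if (length(miss) > 0) {
    abort(paste0("type-II params missing: ", paste(miss, collapse = ", ")))
  }
  if (params$alpha <= 0 || params$m1 <= 0 || params$m2 <= 0 ||
      params$d_e <= 0) {
    abort("alpha, m1, m2, d_e must be > 0")
  }
  if (params$pi_r <= 0 || params$pi_r >= 1) abort("pi_r must be in (0, 1)")
  if (params$epsilon < 0) abort("epsilon must be >= 0")
  params
}

# per-site f0, f1 with the gamma rate integrated exactly; vectorised.
# base(s, mm1, mm2) = integral e^(-lambda s) Pois(x1; lambda mm1)
#                     Pois(x2; lambda mm2) dGamma(lambda; alpha, alpha)
type2_f0_f1 <- function(cls, x1, x2, params) {
  bad <- setdiff(unique(cls), c("N", "C", "R"))
  if (length(bad) > 0) {
    abort(paste0("invalid early-change class: ", paste(bad, collapse = ", ")))
  }
  alpha <- params$alpha
  x <- x1 + x2
  lbase <- function(s, mm1, mm2) {
    lgamma(alpha + x) - lgamma(alpha) - lfactorial(x1) - lfactorial(x2) +
      x1 * log(mm1) + x2 * log(mm2) + alpha * log(alpha) -
      (alpha + x) * log(s + mm1 + mm2 + alpha)
  }
  b0 <- exp(lbase(0, params$m1, params$m2))
  bd <- exp(lbase(params$d_e, params$m1, params$m2))
  changed <- pmax(b0 - bd, 0)  # integral of (1 - e^(-lambda d_e)) term
  f0 <- ifelse(cls == "N", bd,
               ifelse(cls == "R", params$pi_r * changed,
                      (1 - params$pi_r) * changed))
  f1 <- ifelse(cls == "R",
               exp(lbase(0, params$epsilon * params$m1,
                         params$epsilon * params$m2)), 0)
  list(f0 = f0, f1 = f1)
}

#' Site likelihoods under the type-II model
#'
#' Evaluates the no-divergence density `f0` and the type-II density `f1` for
#' each site's (class, x1, x2) triple; see the model sketch in
#' [fit_type2()]. `f1` is zero for any site whose early-phase class is not
#' radical.
#'
#' @param cls Character vector of early-phase classes, in \{"N","C","R"\}.
#' @param x1,x2 Non-negative integer late-phase substitution counts.
#' @param params List with `alpha`, `m1`, `m2`, `d_e`, `pi_r`, `epsilon`.
#' @return A tibble with columns `f0`, `f1`.
#' @export
type2_site_likelihoods <- function(cls, x1, x2, params) {
  check_counts(x1, "x1"); check_counts(x2, "x2")
  params <- check_type2_params(params)
  ff <- type2_f0_f1(cls, x1, x2, params)
  tibble::tibble(f0 = ff$f0, f1 = ff$f1)
}

type2_nll_factory <- function(cls, x1, x2, pi_r, epsilon) {
  key <- paste(cls, x1, x2)
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- do.call(rbind, strsplit(agg$key, " "))
  ucls <- parts[, 1]
  u1 <- as.numeric(parts[, 2]); u2 <- as.numeric(parts[, 3])
  w <- agg$Freq
  function(theta, alpha, m1, m2, d_e) {
    ff <- type2_f0_f1(ucls, u1, u2, list(
      alpha = alpha, m1 = m1, m2 = m2, d_e = d_e,
      pi_r = pi_r, epsilon = epsilon
    ))
    -sum(w * log((1 - theta) * ff$f0 + theta * ff$f1 + 1e-300))
  }
}

#' Fit the type-II divergence coefficient by maximum likelihood
#'
#' Maximises the mixture log-likelihood sum_k log\[(1-theta) f0_k + theta
#' f1_k\] over (theta, alpha, m1, m2, d_e), with the early-phase radical
#' probability `pi_r` held at the scheme's neutral value (137/190 for the
#' default four-group scheme) and the type-II late-phase conservation factor
#' `epsilon` fixed; both are exposed as arguments. Optimisation, standard
#' error and the boundary-corrected LRT follow [fit_type1()]. A profile with
#' no radical sites carries no type-II signal: theta is reported as 0 with a
#' flag.
#'
#' @param profile An `early_change_profile` from [early_profile()] (columns
#'   `class`, `x1`, `x2`).
#' @param pi_r Early-phase radical probability; default
#'   [scheme_radical_fraction()] of the profile's scheme. May also be set to
#'   `"empirical"` to use the observed R/(R+C) ratio.
#' @param epsilon Type-II late-phase conservation factor (default 0.1).
#' @return A `divergence_fit`; `epsilon` and `pi_r` are recorded in
#'   `$extra`.
#' @export
fit_type2 <- function(profile, pi_r = NULL, epsilon = 0.1) {
  if (is.null(profile[["class"]])) {
    abort("profile must carry an early-change `class` column; see early_profile()")
  }
  check_counts(profile$x1, "x1"); check_counts(profile$x2, "x2")
  n <- nrow(profile)
  check_site_count(n)
  scheme <- attr(profile, "scheme") %||% aa_group_scheme()
  if (is.null(pi_r)) {
    pi_r <- scheme_radical_fraction(scheme)
  } else if (identical(pi_r, "empirical")) {
    n_r <- sum(profile$class == "R"); n_c <- sum(profile$class == "C")
    if (n_r + n_c == 0) abort("no changed sites; cannot estimate pi_r empirically")
    pi_r <- min(max(n_r / (n_r + n_c), 1e-3), 1 - 1e-3)
  }

  frac_n <- mean(profile$class == "N")
  d0 <- -log(min(max(frac_n, 0.02), 0.98))
  mm1 <- max(mean(profile$x1), 1e-3)
  mm2 <- max(mean(profile$x2), 1e-3)

  if (!any(profile$class == "R")) {
    # no radical early changes: f1 = 0 everywhere, theta is 0 by construction
    nll <- type2_nll_factory(profile$class, profile$x1, profile$x2,
                             pi_r, epsilon)
    obj0 <- function(p) nll(0, exp(p[1]), exp(p[2]), exp(p[3]), exp(p[4]))
    opt0 <- optim(c(0, log(mm1), log(mm2), log(d0)), obj0,
                  method = "L-BFGS-B",
                  lower = c(log(0.05), -9, -9, -7),
                  upper = c(log(99), 5, 5, 3), control = list(maxit = 500))
    ll0 <- -opt0$value
    p0 <- exp(opt0$par)
    return(new_divergence_fit(
      model = "type2", theta = 0, se = NA_real_, se_method = "none",
      params = list(alpha = p0[1], m1 = p0[2], m2 = p0[3], d_e = p0[4]),
      loglik = ll0, loglik_null = ll0, n_sites = n, convergence = 0,
      flags = c("no_radical_sites", "theta_boundary"),
      extra = list(pi_r = pi_r, epsilon = epsilon)
    ))
  }

  nll <- type2_nll_factory(profile$class, profile$x1, profile$x2,
                           pi_r, epsilon)
  grid <- expand.grid(theta = seq(0, 0.9, by = 0.1),
                      alpha = c(0.25, 0.5, 1, 2, 4))
  grid_nll <- mapply(function(t, a) nll(t, a, mm1, mm2, d0),
                     grid$theta, grid$alpha)
  best <- grid[which.min(grid_nll), ]

  obj <- function(p) nll(p[1], exp(p[2]), exp(p[3]), exp(p[4]), exp(p[5]))
  start <- c(best$theta, log(best$alpha), log(mm1), log(mm2), log(d0))
  opt <- optim(start, obj, method = "L-BFGS-B",
               lower = c(0, log(0.05), -9, -9, -7),
               upper = c(0.999, log(99), 5, 5, 3),
               control = list(maxit = 500))
  if (opt$convergence != 0 && opt$convergence != 52) {
    abort(paste0("type-II optimiser failed to converge (code ",
                 opt$convergence, "): ", opt$message))
  }
  theta_hat <- opt$par[1]
  alpha_hat <- exp(opt$par[2])
  m1_hat <- exp(opt$par[3]); m2_hat <- exp(opt$par[4])
  de_hat <- exp(opt$par[5])
  ll <- -opt$value

  # null fit from several starts so the nested maximum is not
  # under-estimated (which would inflate the LRT)
  obj0 <- function(p) nll(0, exp(p[1]), exp(p[2]), exp(p[3]), exp(p[4]))
  starts0 <- list(
    c(log(alpha_hat), log(m1_hat), log(m2_hat), log(de_hat)),
    c(log(best$alpha), log(mm1), log(mm2), log(d0)),
    c(0, log(mm1), log(mm2), log(d0))
  )
  ll0 <- max(vapply(starts0, function(s) {
    -optim(s, obj0, method = "L-BFGS-B",
           lower = c(log(0.05), -9, -9, -7),
           upper = c(log(99), 5, 5, 3), control = list(maxit = 500))$value
  }, numeric(1)))

  se <- theta_se(function(q) nll(q[1], q[2], q[3], q[4], q[5]),
                 c(theta_hat, alpha_hat, m1_hat, m2_hat, de_hat))
  flags <- character(0)
  if (theta_hat < 1e-4) flags <- c(flags, "theta_boundary")
  new_divergence_fit(
    model = "type2", theta = theta_hat, se = se$se, se_method = se$method,
    params = list(alpha = alpha_hat, m1 = m1_hat, m2 = m2_hat, d_e = de_hat),
    loglik = ll, loglik_null = ll0, n_sites = n,
    convergence = opt$convergence, flags = flags,
    extra = list(pi_r = pi_r, epsilon = epsilon)
  )
}

#' Site posteriors for type-II divergence
#'
#' Posterior probability per site of the type-II divergent class:
#' Q_II(k) = theta f1_k / \[(1-theta) f0_k + theta f1_k\], with posterior
#' ratio R_II(k) = Q_II(k)/(1 - Q_II(k)). Sites whose early-phase class is
#' `N` or `C` have Q_II = 0 exactly.
#'
#' @param profile An `early_change_profile`.
#' @param fit A type-II `divergence_fit`, or a list with `theta` plus the
#'   model parameters (`alpha`, `m1`, `m2`, `d_e`, `pi_r`, `epsilon`).
#' @return A `site_posterior_profile` tibble: `site`, `ref_pos`, `x1`, `x2`,
#'   `Q`, `R`, `class`.
#' @export
type2_posteriors <- function(profile, fit) {
  if (inherits(fit, "divergence_fit")) {
    p <- c(list(theta = fit$theta), fit$params, fit$extra)
  } else {
    p <- fit
  }
  p2 <- check_type2_params(p[setdiff(names(p), "theta")])
  ff <- type2_f0_f1(profile$class, profile$x1, profile$x2, p2)
  build_profile(profile, p$theta, log(ff$f0), log(ff$f1), model = "type2")
}
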