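# Type-I functional divergence: rate decoupling between duplicate clusters.
#
# Model: site rate lambda ~ gamma(shape alpha, rate alpha), substitution
# counts x_i | lambda ~ Poisson(lambda * m_i) in cluster i. Under F0 (no
# divergence) the two clusters share one lambda, giving a bivariate negative
# binomial; under F1 (type-I divergent) the rates are independent, giving a
# product of two univariate negative binomials. A site is F1 with probability
# theta_I, and the mixture is maximised over (theta, alpha, m1, m2).

check_counts <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x != floor(x))) {
    abort(paste0(name, " must be non-negative integer substitution counts"))
  }
}

# log joint probability of (x1, x2) under a shared gamma rate
log_f0_type1 <- function(x1, x2, alpha, m1, m2) {
  s <- m1 + m2 + alpha
  lgamma(alpha + x1 + x2) - lgamma(alpha) - lfactorial(x1) - lfactorial(x2) +
    x1 * log(m1 / s) + x2 * log(m2 / s) + alpha * log(alpha / s)
}

log_f1_type1 <- function(x1, x2, alpha, m1, m2) {
  dnbinom(x1, size = alpha, mu = m1, log = TRUE) +
    dnbinom(x2, size = alpha, mu = m2, log = TRUE)
}

#' Site likelihoods under the type-I model
#'
#' Evaluates, for each site's substitution-count pair, the probability under
#' the shared-rate model `f0` (bivariate negative binomial) and under the
#' independent-rates model `f1` (product of negative binomial marginals),
#' sharing the gamma shape `alpha` and cluster depths `m1`, `m2`.
#'
#' @param x1,x2 Non-negative integer substitution counts per site.
#' @param params List with elements `alpha` (> 0), `m1`, `m2` (> 0).
#' @return A tibble with columns `f0` and `f1`.
#' @export
type1_site_likelihoods <- function(x1, x2, params) {
  check_counts(x1, "x1"); check_counts(x2, "x2")
  if (!is.list(params) || is.null(params$alpha)) abort("params must list alpha, m1, m2")
  if (params$alpha <= 0) abort("alpha must be > 0")
  if (params$m1 <= 0 || params$m2 <= 0) abort("m1 and m2 must be > 0")
  tibble::tibble(
    f0 = exp(log_f0_type1(x1, x2, params$alpha, params$m1, params$m2)),
    f1 = exp(log_f1_type1(x1, x2, params$alpha, params$m1, params$m2))
  )
}

# negative log-likelihood over aggregated unique count pairs
type1_nll_factory <- function(x1, x2) {
  key <- paste(x1, x2)
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- do.call(rbind, strsplit(agg$key, " "))
  u1 <- as.numeric(parts[, 1]); u2 <- as.numeric(parts[, 2])
  w <- agg$Freq
  function(theta, alpha, m1, m2) {
    lf0 <- log_f0_type1(u1, u2, alpha, m1, m2)
    lf1 <- log_f1_type1(u1, u2, alpha, m1, m2)
    -sum(w * log_mix(theta, lf0, lf1))
  }
}

#' Fit the type-I divergence coefficient by maximum likelihood
#'
#' Maximises the mixture log-likelihood sum_k log\[(1-theta) f0_k + theta
#' f1_k\] over (theta, alpha, m1, m2), seeding a bounded quasi-Newton search
#' (`optim` L-BFGS-B on log-scale nuisance parameters) from a coarse
#' (theta, alpha) grid with moment-matched depths. The standard error of
#' theta comes from the observed information; the likelihood-ratio test
#' against theta = 0 uses the boundary-corrected 50:50 chi-square mixture
#' null.
#'
#' @param table A `site_count_table` from [build_count_table()], or any data
#'   frame with integer columns `x1`, `x2`.
#' @return A `divergence_fit` (see [tidy.divergence_fit()],
#'   [glance.divergence_fit()]).
#' @export
fit_type1 <- function(table) {
  check_counts(table$x1, "x1"); check_counts(table$x2, "x2")
  n <- nrow(table)
  check_site_count(n)
  nll <- type1_nll_factory(table$x1, table$x2)
  mm1 <- max(mean(table$x1), 1e-3)
  mm2 <- max(mean(table$x2), 1e-3)

  grid <- expand.grid(theta = seq(0, 0.9, by = 0.1),
                      alpha = c(0.25, 0.5, 1, 2, 4))
  grid_nll <- mapply(function(t, a) nll(t, a, mm1, mm2),
                     grid$theta, grid$alpha)
  best <- grid[which.min(grid_nll), ]

  obj <- function(p) nll(p[1], exp(p[2]), exp(p[3]), exp(p[4]))
  start <- c(best$theta, log(best$alpha), log(mm1), log(mm2))
  opt <- optim(start, obj, method = "L-BFGS-B",
               lower = c(0, log(0.05), -9, -9),
               upper = c(0.999, log(99), 5, 5),
               control = list(maxit = 500))
  if (opt$convergence != 0 && opt$convergence != 52) {
    abort(paste0("type-I optimiser failed to converge (code ",
                 opt$convergence, "): ", opt$message))
  }
  theta_hat <- opt$par[1]
  alpha_hat <- exp(opt$par[2])
  m1_hat <- exp(opt$par[3]); m2_hat <- exp(opt$par[4])
  ll <- -opt$value

  # null fit: theta = 0, from several starts so the nested maximum is not
  # under-estimated (which would inflate the LRT)
  obj0 <- function(p) nll(0, exp(p[1]), exp(p[2]), exp(p[3]))
  starts0 <- list(c(log(alpha_hat), log(m1_hat), log(m2_hat)),
                  c(log(best$alpha), log(mm1), log(mm2)),
                  c(0, log(mm1), log(mm2)))
  ll0 <- max(vapply(starts0, function(s) {
    -optim(s, obj0, method = "L-BFGS-B",
           lower = c(log(0.05), -9, -9), upper = c(log(99), 5, 5),
           control = list(maxit = 500))$value
  }, numeric(1)))

  se <- theta_se(function(q) nll(q[1], q[2], q[3], q[4]),
                 c(theta_hat, alpha_hat, m1_hat, m2_hat))
  flags <- character(0)
  if (theta_hat < 1e-4) flags <- c(flags, "theta_boundary")
  new_divergence_fit(
    model = "type1", theta = theta_hat, se = se$se, se_method = se$method,
    params = list(alpha = alpha_hat, m1 = m1_hat, m2 = m2_hat),
    loglik = ll, loglik_null = ll0, n_sites = n,
    convergence = opt$convergence, flags = flags
  )
}

#' Site posteriors for type-I divergence
#'
#' Posterior probability per site of belonging to the rate-decoupled class:
#' Q_I(k) = theta f1_k / \[(1-theta) f0_k + theta f1_k\], with posterior
#' ratio R_I(k) = Q_I(k) / (1 - Q_I(k)).
#'
#' @param table A `site_count_table` (columns `x1`, `x2`, and `site`/`ref_pos`
#'   if present).
#' @param fit A type-I `divergence_fit`, or a list with `theta`, `alpha`,
#'   `m1`, `m2`.
#' @return A `site_posterior_profile` tibble: `site`, `ref_pos`, `x1`, `x2`,
#'   `Q`, `R`.
#' @export
type1_posteriors <- function(table, fit) {
  p <- posterior_params(fit, c("alpha", "m1", "m2"))
  lf0 <- log_f0_type1(table$x1, table$x2, p$alpha, p$m1, p$m2)
  lf1 <- log_f1_type1(table$x1, table$x2, p$alpha, p$m1, p$m2)
  build_profile(table, p$theta, lf0, lf1, model = "type1")
}

posterior_params <- function(fit, nuisance) {
  if (inherits(fit, "divergence_fit")) {
    c(list(theta = fit$theta), fit$params)
  } else {
    if (!all(c("theta", nuisance) %in% names(fit))) {
      abort(paste0("fit must provide theta, ", paste(nuisance, collapse = ", ")))
    }
    fit
  }
}

build_profile <- function(table, theta, lf0, lf1, model) {
  if (theta <= 0) {
    Q <- rep(0, length(lf0))
  } else {
    la <- log1p(-theta) + lf0
    lb <- log(theta) + lf1
    Q <- ifelse(is.infinite(lb) & lb < 0, 0, 1 / (1 + exp(la - lb)))
  }
  site <- table[["site"]] %||% seq_along(Q)
  out <- tibble::tibble(
    site = site,
    ref_pos = table[["ref_pos"]] %||% site,
    x1 = table$x1, x2 = table$x2,
    Q = Q, R = Q / (1 - Q)
  )
  if (!is.null(table[["class"]])) out$class <- table[["class"]]
  class(out) <- c("site_posterior_profile", class(out))
  attr(out, "model") <- model
  attr(out, "theta") <- theta
  out
}
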