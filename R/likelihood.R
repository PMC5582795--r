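# Shared machinery for the two mixture likelihoods: discrete-gamma rates,
# fit container, standard errors and the boundary-corrected LRT.

# log((1-theta) f0 + theta f1) from log f0, log f1, numerically stable.
log_mix <- function(theta, lf0, lf1) {
  if (theta <= 0) return(lf0)
  if (theta >= 1) return(lf1)
  a <- log1p(-theta) + lf0
  b <- log(theta) + lf1
  m <- pmax(a, b)
  m[!is.finite(m)] <- -745  # both terms underflow
  m + log(exp(a - m) + exp(b - m))
}

# p-value for H0: theta = 0 with theta on the boundary of the parameter
# space: 50:50 mixture of a point mass at 0 and chi-square(1).
boundary_lrt_p <- function(lrt) {
  if (lrt <= 1e-10) return(1)
  0.5 * pchisq(lrt, df = 1, lower.tail = FALSE)
}

# Observed-information SE for theta: numerical Hessian of the joint negative
# log-likelihood over the natural parameters at the MLE, inverted. Falls back
# to the conditional curvature in theta if the full Hessian is unusable.
theta_se <- function(nll_natural, mle) {
  se <- NA_real_
  method <- "observed_information"
  H <- try(pracma::hessian(nll_natural, mle), silent = TRUE)
  if (!inherits(H, "try-error") && all(is.finite(H))) {
    V <- try(solve(H), silent = TRUE)
    if (!inherits(V, "try-error") && is.finite(V[1, 1]) && V[1, 1] > 0) {
      se <- sqrt(V[1, 1])
    }
  }
  if (!is.finite(se)) {
    method <- "conditional_curvature"
    h <- 1e-4
    f <- function(t) nll_natural(replace(mle, 1, t))
    d2 <- (f(mle[1] + h) - 2 * f(mle[1]) + f(mle[1] - h)) / h^2
    if (is.finite(d2) && d2 > 0) se <- sqrt(1 / d2)
  }
  list(se = se, method = method)
}

new_divergence_fit <- function(model, theta, se, se_method, params, loglik,
                               loglik_null, n_sites, convergence,
                               flags = character(0), extra = list()) {
  lrt <- max(0, 2 * (loglik - loglik_null))
  structure(
    list(
      model = model,
      theta = theta,
      se = se,
      se_method = se_method,
      params = params,
      loglik = loglik,
      loglik_null = loglik_null,
      lrt = lrt,
      p_value = boundary_lrt_p(lrt),
      n_sites = n_sites,
      convergence = convergence,
      boundary = theta < 1e-4,
      flags = flags,
      extra = extra
    ),
    class = "divergence_fit"
  )
}

#' @export
print.divergence_fit <- function(x, ...) {
  label <- if (x$model == "type1") "Type-I (rate shift)" else
    "Type-II (property shift)"
  cat("<divergence_fit> ", label, "\n", sep = "")
  cat(sprintf("  theta = %.4f +/- %s  (n = %d sites)\n", x$theta,
              ifelse(is.finite(x$se), sprintf("%.4f", x$se), "NA"), x$n_sites))
  cat(sprintf("  logL = %.3f  (null %.3f)  LRT = %.3f  p = %.3g\n",
              x$loglik, x$loglik_null, x$lrt, x$p_value))
  cat("  nuisance:", paste(sprintf("%s = %.4g", names(x$params), unlist(x$params)),
                           collapse = ", "), "\n")
  if (x$boundary) cat("  note: theta on the boundary; SE one-sided\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a divergence fit
#'
#' @param x A `divergence_fit` from [fit_type1()] or [fit_type2()].
#' @param ... Unused.
#' @return A tibble with one row per estimated parameter (`term`, `estimate`,
#'   `std.error`; the standard error is reported for theta only).
#' @method tidy divergence_fit
#' @export
tidy.divergence_fit <- function(x, ...) {
  tibble::tibble(
    term = c("theta", names(x$params)),
    estimate = c(x$theta, unlist(x$params, use.names = FALSE)),
    std.error = c(x$se, rep(NA_real_, length(x$params)))
  )
}

#' One-row summary of a divergence fit
#'
#' @param x A `divergence_fit`.
#' @param ... Unused.
#' @return A one-row tibble: model, theta, SE, log-likelihoods, LRT statistic
#'   and boundary-corrected p-value, number of sites.
#' @method glance divergence_fit
#' @export
glance.divergence_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    theta = x$theta,
    se_theta = x$se,
    logLik = x$loglik,
    logLik_null = x$loglik_null,
    statistic = x$lrt,
    p.value = x$p_value,
    n_sites = x$n_sites,
    boundary = x$boundary
  )
}

# fit-time guard shared by both models
check_site_count <- function(n) {
  if (n < 50) {
    warn(paste0("only ", n, " usable sites; theta estimates are unstable ",
                "below ~50 sites"))
  }
}
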