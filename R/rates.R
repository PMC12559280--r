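# --- neutral two-state epimutation model and rate estimation ------------

#' Parameters of the neutral divergence model
#'
#' @param alpha Gain rate (per site per haploid genome per year).
#' @param beta Loss rate (same units).
#' @param c Residual divergence intercept in `[0, 0.5)`; absorbs
#'   divergence that cannot be dated past the earliest branch point.
#' @param p0 Ancestral methylated proportion; `NULL` means the steady
#'   state `alpha / (alpha + beta)`.
#' @return An object of class `neutral_params` with derived `gamma`
#'   (per-year retention factor `1 - alpha - beta`) and `pi` (steady-state
#'   methylated fraction `alpha / (alpha + beta)`).
#' @export
#' @examples
#' neutral_params(alpha = 4.69e-6, beta = 6.50e-6)
neutral_params <- function(alpha, beta, c = 0, p0 = NULL) {
  stopifnot(alpha >= 0, beta >= 0, alpha + beta <= 1, c >= 0, c < 0.5)
  pi_ss <- if (alpha + beta > 0) alpha / (alpha + beta) else NA_real_
  p0 <- p0 %||% pi_ss
  structure(list(alpha = alpha, beta = beta, c = c, p0 = p0,
                 gamma = 1 - alpha - beta, pi = pi_ss),
            class = "neutral_params")
}

#' Expected methylation divergence under the neutral model
#'
#' With per-year retention factor \eqn{\gamma = 1 - \alpha - \beta} and
#' steady state \eqn{\pi = \alpha/(\alpha+\beta)}, the probability a tip
#' is methylated given a methylated ancestor \eqn{\tau} years back is
#' \eqn{a(\tau) = \pi + (1-\pi)\gamma^\tau}, and given an unmethylated
#' ancestor \eqn{b(\tau) = \pi(1 - \gamma^\tau)}. Two tips descending
#' from a common ancestor with methylated proportion `p0` then differ
#' with probability
#' \deqn{D = c + p_0 [a_i(1-a_j) + a_j(1-a_i)] +
#'   (1-p_0) [b_i(1-b_j) + b_j(1-b_i)],}
#' which at \eqn{p_0 = \pi} reduces to
#' \eqn{c + 2\pi(1-\pi)(1 - \gamma^{\tau_i+\tau_j})}.
#'
#' @param params A [neutral_params()].
#' @param tau_i,tau_j Years from the common branch point to each tip
#'   (vectorised).
#' @return Expected divergence, same length as `tau_i`.
#' @export
model_divergence <- function(params, tau_i, tau_j = tau_i) {
  stopifnot(inherits(params, "neutral_params"),
            all(tau_i >= 0), all(tau_j >= 0))
  al <- params$alpha; be <- params$beta
  if (al + be == 0) return(rep(params$c, length(tau_i)))
  pi_ss <- params$pi; g <- params$gamma
  a_i <- pi_ss + (1 - pi_ss) * g^tau_i
  a_j <- pi_ss + (1 - pi_ss) * g^tau_j
  b_i <- pi_ss * (1 - g^tau_i)
  b_j <- pi_ss * (1 - g^tau_j)
  params$c + params$p0 * (a_i * (1 - a_j) + a_j * (1 - a_i)) +
    (1 - params$p0) * (b_i * (1 - b_j) + b_j * (1 - b_i))
}

#' Steady-state methylation under the neutral model
#'
#' \eqn{\pi = \alpha / (\alpha + \beta)}: the equilibrium methylated
#' fraction, invariant under proportional scaling of both rates — which is
#' why trees with proportionally elevated gain and loss rates show
#' unchanged steady-state methylation levels.
#'
#' @param params A [neutral_params()] (or any list with `alpha`, `beta`).
#' @return A one-row tibble with `pi` and `defined` (`FALSE` when
#'   `alpha + beta = 0`).
#' @export
steady_state <- function(params) {
  al <- params$alpha; be <- params$beta
  if (al + be == 0) {
    return(tibble::tibble(pi = NA_real_, defined = FALSE))
  }
  tibble::tibble(pi = al / (al + be), defined = TRUE)
}

# residuals on the internal scale th = (log10 alpha, log10 beta, c);
# numeric differentiation may probe just outside the box, so clamp
.fit_residuals <- function(th, D, tau_i, tau_j, p0) {
  pr <- neutral_params(min(10^th[1], 0.5), min(10^th[2], 0.5),
                       min(max(th[3], 0), 0.499), p0 = p0)
  D - model_divergence(pr, tau_i, tau_j)
}

.fit_bounds <- list(lower = c(log10(1e-12), log10(1e-12), 0),
                    upper = c(log10(1e-2), log10(1e-2), 0.4))

# Levenberg-Marquardt with box projection; small fixed-size problem
.lm_minimize <- function(th0, D, tau_i, tau_j, p0,
                         max_iter = 300L, tol = 1e-12) {
  lo <- .fit_bounds$lower; up <- .fit_bounds$upper
  th <- pmin(pmax(th0, lo), up)
  r <- .fit_residuals(th, D, tau_i, tau_j, p0)
  rss <- sum(r^2)
  lambda <- 1e-3
  jac <- function(th) {
    J <- matrix(0, length(D), 3)
    for (k in 1:3) {
      h <- max(1e-7, abs(th[k]) * 1e-7)
      tp <- th; tp[k] <- th[k] + h
      tm <- th; tm[k] <- th[k] - h
      J[, k] <- (.fit_residuals(tp, D, tau_i, tau_j, p0) -
                   .fit_residuals(tm, D, tau_i, tau_j, p0)) / (2 * h)
    }
    J
  }
  converged <- FALSE; iter <- 0L
  if (max_iter < 1L) {
    return(list(theta = th, rss = rss, iterations = 0L, converged = TRUE))
  }
  for (iter in seq_len(max_iter)) {
    J <- jac(th)
    g <- crossprod(J, r)
    H <- crossprod(J)
    step_ok <- FALSE
    for (tries in 1:30) {
      A <- H + lambda * diag(pmax(diag(H), 1e-12))
      delta <- tryCatch(solve(A, -g), error = function(e) NULL)
      if (is.null(delta)) { lambda <- lambda * 10; next }
      th_new <- pmin(pmax(th + as.vector(delta), lo), up)
      r_new <- .fit_residuals(th_new, D, tau_i, tau_j, p0)
      rss_new <- sum(r_new^2)
      if (rss_new <= rss) {
        improve <- rss - rss_new
        th <- th_new; r <- r_new; rss <- rss_new
        lambda <- max(lambda / 3, 1e-12)
        step_ok <- TRUE
        if (improve < tol * max(rss, 1e-300) ||
            sqrt(sum(delta^2)) < 1e-10) converged <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!step_ok) { converged <- TRUE; break } # no further descent possible
    if (converged) break
  }
  list(theta = th, rss = rss, iterations = iter, converged = converged)
}

# primary minimizer: nl2sol ("port") on the log-rate scale, followed by a
# short Levenberg-Marquardt polish; falls back to LM alone if nls errors.
# nl2sol's "singular convergence" is expected here: at realistic rates the
# least-squares surface is a ridge in (alpha, beta).
.nls_minimize <- function(th0, D, tau_i, tau_j, p0) {
  lo <- .fit_bounds$lower; up <- .fit_bounds$upper
  th0 <- pmin(pmax(th0, lo), up)
  mfun <- function(la, lb, cc) {
    -.fit_residuals(c(la, lb, cc), 0, tau_i, tau_j, p0)
  }
  fit <- tryCatch(
    suppressWarnings(stats::nls(
      D ~ mfun(la, lb, cc),
      data = data.frame(D = D),
      start = list(la = th0[1], lb = th0[2], cc = th0[3]),
      algorithm = "port", lower = lo, upper = up,
      control = stats::nls.control(maxiter = 500, warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(.lm_minimize(th0, D, tau_i, tau_j, p0))
  }
  th <- unname(coef(fit))
  # nl2sol codes 3-7 all leave us at (or on a flat of) a local minimum
  ok <- isTRUE(fit$convInfo$isConv) ||
    (!is.null(fit$convInfo$stopCode) && fit$convInfo$stopCode %in% 3:7)
  polish <- .lm_minimize(th, D, tau_i, tau_j, p0, max_iter = 50L)
  if (polish$rss <= sum(.fit_residuals(th, D, tau_i, tau_j, p0)^2)) {
    th <- polish$theta
  }
  r <- .fit_residuals(th, D, tau_i, tau_j, p0)
  list(theta = th, rss = sum(r^2),
       iterations = fit$convInfo$finIter %||% NA_integer_,
       converged = ok || polish$converged)
}

#' Fit the neutral epimutation model to divergence data
#'
#' Estimates the per-year gain rate \eqn{\alpha}, loss rate \eqn{\beta}
#' and residual intercept \eqn{c} by bounded numerical nonlinear least
#' squares on pairwise divergences versus divergence times, under the
#' neutral two-state model ([model_divergence()]). Rates are
#' log-parameterised internally for conditioning and optimised by
#' Levenberg-Marquardt from a multi-start grid (three decades around a
#' moment-based slope guess for each rate, crossed with
#' `c in {0, min(D)}`). `p0` is fixed, not fitted: supply the mean
#' observed methylated fraction across samples. Standard errors come from
#' the Jacobian-based asymptotic covariance on the natural scale at the
#' optimum; when the Jacobian is rank-deficient they are flagged
#' unreliable.
#'
#' @param pairs A tibble with columns `D` and either `tau_i` + `tau_j`
#'   or `delta_t` (then `tau_i = tau_j = delta_t / 2`). An optional
#'   `root_censored` column is honoured via `exclude_root_censored`.
#' @param p0 Ancestral methylated proportion (fixed). Defaults to the
#'   attribute `p0` of `pairs` if present, else errors.
#' @param exclude_root_censored Drop pairs flagged `root_censored`
#'   (default `TRUE`: their divergence time is only a lower bound).
#' @param weights Optional per-pair weights.
#' @return An object of class `neutral_fit`; see [tidy.neutral_fit()] and
#'   [glance.neutral_fit()].
#' @export
fit_neutral_model <- function(pairs, p0 = attr(pairs, "p0"),
                              exclude_root_censored = TRUE,
                              weights = NULL) {
  pairs <- tibble::as_tibble(pairs)
  assert_columns(pairs, "D", "pair table")
  if (is.null(p0)) abort("p0 (mean observed methylated fraction) is required")
  if (exclude_root_censored && "root_censored" %in% names(pairs)) {
    pairs <- dplyr::filter(pairs, !.data$root_censored)
  }
  if (!all(c("tau_i", "tau_j") %in% names(pairs))) {
    assert_columns(pairs, "delta_t", "pair table")
    pairs$tau_i <- pairs$tau_j <- pairs$delta_t / 2
  }
  if (nrow(pairs) < 4) abort("need at least 4 pairs")
  dts <- pairs$tau_i + pairs$tau_j
  if (length(unique(round(dts, 9))) < 2) {
    abort("pairs must span at least 2 distinct divergence times")
  }
  D <- pairs$D; tau_i <- pairs$tau_i; tau_j <- pairs$tau_j

  # moment-based scale guess: slope of D on delta_t as a combined rate
  slope <- unname(coef(lm(D ~ dts))[2])
  g0 <- max(min(abs(slope), 1e-3), 1e-9)
  starts <- expand.grid(a = g0 * c(0.1, 1, 10), b = g0 * c(0.1, 1, 10),
                        c = c(0, max(min(D), 0)))
  fits <- purrr::pmap(starts, function(a, b, c) {
    .nls_minimize(c(log10(a), log10(b), c), D, tau_i, tau_j, p0)
  })
  if (!any(purrr::map_lgl(fits, "converged"))) {
    abort("nonlinear least squares failed to converge from all starts")
  }
  # starts whose RSS is indistinguishable sit on the same flat ridge; pick
  # the most interior solution (closest to equal rates) rather than a
  # bound-hitting ridge endpoint
  rsss <- purrr::map_dbl(fits, "rss")
  cand <- which(rsss <= min(rsss) * (1 + 1e-6) + 1e-300)
  asym <- purrr::map_dbl(fits[cand], ~abs(.x$theta[1] - .x$theta[2]))
  best <- fits[[cand[which.min(asym)]]]
  th <- best$theta
  est <- c(alpha = 10^th[1], beta = 10^th[2], c = th[3])

  # natural-scale Jacobian of the model at the optimum
  n <- length(D)
  J <- matrix(0, n, 3, dimnames = list(NULL, names(est)))
  f_nat <- function(v) model_divergence(
    neutral_params(v[1], v[2], max(v[3], 0), p0 = p0), tau_i, tau_j)
  for (k in 1:3) {
    h <- max(abs(est[k]) * 1e-6, 1e-12)
    vp <- est; vp[k] <- est[k] + h
    vm <- est; vm[k] <- max(est[k] - h, 0)
    J[, k] <- (f_nat(vp) - f_nat(vm)) / (vp[k] - vm[k])
  }
  sigma2 <- best$rss / max(n - 3, 1)
  # column-equilibrated inversion: the alpha and beta columns are nearly
  # collinear at small rate-by-time products, so the covariance is large
  # along the ridge -- that is the honest uncertainty, not a defect
  scl <- apply(J, 2, function(cl) max(sqrt(sum(cl^2)), 1e-300))
  Js <- sweep(J, 2, scl, "/")
  G <- crossprod(Js)
  inv <- tryCatch(solve(G), error = function(e) NULL)
  se_unreliable <- FALSE
  if (is.null(inv) || any(diag(inv) < 0)) {
    se_unreliable <- TRUE
    sv <- svd(G)
    dinv <- ifelse(sv$d > max(sv$d) * .Machine$double.eps, 1 / sv$d, Inf)
    inv <- sv$v %*% diag(dinv) %*% t(sv$u)
  }
  cov_nat <- sigma2 * sweep(sweep(inv, 1, scl, "/"), 2, scl, "/")
  dimnames(cov_nat) <- list(names(est), names(est))
  se <- sqrt(pmax(diag(cov_nat), 0))
  names(se) <- names(est)

  structure(list(
    estimates = est, se = se, cov = cov_nat, p0 = p0,
    rss = best$rss, sigma2 = sigma2, n_pairs = n,
    iterations = best$iterations, converged = best$converged,
    se_unreliable = se_unreliable,
    data = tibble::tibble(D = D, tau_i = tau_i, tau_j = tau_j),
    params = neutral_params(est[["alpha"]], est[["beta"]], est[["c"]],
                            p0 = p0)
  ), class = "neutral_fit")
}

#' @export
print.neutral_fit <- function(x, ...) {
  cat("<neutral_fit> neutral gain/loss epimutation model\n")
  cat(sprintf("  alpha = %.4g (SE %.3g) per site per haploid genome per year\n",
              x$estimates[["alpha"]], x$se[["alpha"]]))
  cat(sprintf("  beta  = %.4g (SE %.3g)\n",
              x$estimates[["beta"]], x$se[["beta"]]))
  cat(sprintf("  c = %.4g, p0 = %.4g (fixed), steady state pi = %.4g\n",
              x$estimates[["c"]], x$p0, x$params$pi))
  cat(sprintf("  RSS %.4g over %d pairs; %s in %d iterations\n",
              x$rss, x$n_pairs,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  if (x$se_unreliable) cat("  note: SEs from a rank-deficient Jacobian (flagged unreliable)\n")
  invisible(x)
}

#' Tidy a neutral model fit
#'
#' @param x A `neutral_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @method tidy neutral_fit
#' @export
tidy.neutral_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimates),
                 estimate = unname(x$estimates),
                 std.error = unname(x$se))
}

#' One-line summary of a neutral model fit
#'
#' @param x A `neutral_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `alpha`, `beta`, `c`, `pi`, `p0`, `rss`,
#'   `n_pairs`, `converged`, `se_unreliable`.
#' @method glance neutral_fit
#' @export
glance.neutral_fit <- function(x, ...) {
  tibble::tibble(alpha = x$estimates[["alpha"]], beta = x$estimates[["beta"]],
                 c = x$estimates[["c"]], pi = x$params$pi, p0 = x$p0,
                 rss = x$rss, n_pairs = x$n_pairs,
                 converged = x$converged, se_unreliable = x$se_unreliable)
}

#' Compare two neutral model fits
#'
#' Reports per-parameter rate ratios (fit A over fit B), the average ratio
#' across the gain and loss rates, and one-sided Welch tests per parameter
#' computed from the (estimate, standard error) pairs — the alternative
#' being that fit A's rate is greater.
#'
#' @param fit_a,fit_b `neutral_fit` objects, or lightweight stand-ins
#'   built with [rate_estimates()] from published point estimates.
#' @return A list with `by_parameter` (tibble: `term`, `estimate_a`,
#'   `estimate_b`, `ratio`, `statistic`, `p_value`) and `average_ratio`
#'   (mean of the alpha and beta ratios).
#' @export
#' @examples
#' pr <- published_rates()
#' gw <- dplyr::filter(pr, scale == "genome-wide")
#' a <- rate_estimates(gw$alpha[1], gw$beta[1], gw$se_alpha[1], gw$se_beta[1])
#' b <- rate_estimates(gw$alpha[2], gw$beta[2], gw$se_alpha[2], gw$se_beta[2])
#' compare_fits(a, b)$average_ratio # ~1.22
compare_fits <- function(fit_a, fit_b) {
  if (!is.null(fit_a$converged) && !fit_a$converged ||
      !is.null(fit_b$converged) && !fit_b$converged) {
    abort("both fits must have converged")
  }
  terms <- c("alpha", "beta")
  rows <- purrr::map_dfr(terms, function(tm) {
    ea <- fit_a$estimates[[tm]]; eb <- fit_b$estimates[[tm]]
    sa <- fit_a$se[[tm]]; sb <- fit_b$se[[tm]]
    if (sa == 0 || sb == 0) abort("zero standard error in a compared parameter")
    stat <- (ea - eb) / sqrt(sa^2 + sb^2)
    df <- welch_df(fit_a, fit_b, sa, sb)
    p <- if (is.finite(df)) pt(stat, df, lower.tail = FALSE)
         else pnorm(stat, lower.tail = FALSE)
    tibble::tibble(term = tm, estimate_a = ea, estimate_b = eb,
                   ratio = ea / eb, statistic = stat, p_value = p)
  })
  list(by_parameter = rows, average_ratio = mean(rows$ratio))
}

# Welch-Satterthwaite df when pair counts are known; otherwise a normal
# reference (the published comparison is based on estimates and SEs only)
welch_df <- function(fit_a, fit_b, sa, sb) {
  na <- fit_a$n_pairs; nb <- fit_b$n_pairs
  if (is.null(na) || is.null(nb)) return(Inf)
  (sa^2 + sb^2)^2 / (sa^4 / max(na - 3, 1) + sb^4 / max(nb - 3, 1))
}

#' Wrap published rate estimates for comparison
#'
#' Builds a minimal object usable by [compare_fits()] from point estimates
#' and standard errors of the gain and loss rates (e.g. published values).
#'
#' @param alpha,beta Point estimates.
#' @param se_alpha,se_beta Standard errors.
#' @return A list shaped like a `neutral_fit` (estimates, se, converged).
#' @export
rate_estimates <- function(alpha, beta, se_alpha, se_beta) {
  structure(list(estimates = c(alpha = alpha, beta = beta),
                 se = c(alpha = se_alpha, beta = se_beta),
                 converged = TRUE, n_pairs = NULL),
            class = "rate_estimates")
}

#' Bootstrap standard errors for a neutral model fit
#'
#' Resamples pairs with replacement, refits, and summarises the spread of
#' the estimates. An alternative to the Jacobian-based asymptotic SEs,
#' useful when the Jacobian is rank-deficient.
#'
#' @param pairs Pair tibble as for [fit_neutral_model()].
#' @param p0 Fixed ancestral methylated proportion.
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed (deterministic intervals under a fixed seed).
#' @param ... Passed to [fit_neutral_model()].
#' @return A list with `se` (tibble: `term`, `se_boot`, `ci_lo`, `ci_hi`
#'   2.5/97.5 percentiles), `n_failed`, `flagged` (`TRUE` when more than
#'   20% of refits failed).
#' @export
bootstrap_se <- function(pairs, p0, n_boot = 200L, seed = 1L, ...) {
  stopifnot(n_boot >= 100)
  withr::local_seed(seed)
  pairs <- tibble::as_tibble(pairs)
  ests <- matrix(NA_real_, n_boot, 3,
                 dimnames = list(NULL, c("alpha", "beta", "c")))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(pairs), replace = TRUE)
    fit <- tryCatch(
      fit_neutral_model(pairs[idx, ], p0 = p0, ...),
      error = function(e) NULL)
    if (!is.null(fit)) ests[b, ] <- fit$estimates
  }
  ok <- complete.cases(ests)
  n_failed <- sum(!ok)
  se_tbl <- tibble::tibble(
    term = colnames(ests),
    se_boot = apply(ests[ok, , drop = FALSE], 2, sd),
    ci_lo = apply(ests[ok, , drop = FALSE], 2, quantile, 0.025),
    ci_hi = apply(ests[ok, , drop = FALSE], 2, quantile, 0.975))
  list(se = se_tbl, n_failed = n_failed,
       flagged = n_failed > 0.2 * n_boot)
}
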