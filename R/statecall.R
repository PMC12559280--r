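# --- methylation state calling ------------------------------------------
# Three components with binomial emissions at success probabilities
# (p_u, p_i, p_m), p_u < p_i < p_m, estimated by EM. "independent" mode is
# a mixture; "chain" mode is a first-order chain along genome order with
# posteriors from the forward-backward recursion.

logsumexp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# emission parameter M-step with identifiability floors/ceilings;
# p_i is kept midway between p_u and p_m
update_emissions <- function(x, n, resp) {
  num <- colSums(resp * x); den <- colSums(resp * n)
  p_u <- if (den[1] > 0) num[1] / den[1] else 0.01
  p_m <- if (den[3] > 0) num[3] / den[3] else 0.95
  p_u <- min(max(p_u, 0.001), 0.15)
  p_m <- min(max(p_m, 0.6), 0.999)
  c(u = p_u, i = (p_u + p_m) / 2, m = p_m)
}

emission_loglik <- function(x, n, p) {
  vapply(p, function(pk) dbinom(x, n, pk, log = TRUE), numeric(length(x)))
}

em_mixture <- function(x, n, max_iter, tol) {
  p <- c(u = 0.01, i = 0.5, m = 0.95)
  w <- rep(1 / 3, 3)
  ll_old <- -Inf; converged <- FALSE; iter <- 0L
  for (iter in seq_len(max_iter)) {
    le <- emission_loglik(x, n, p)
    lj <- sweep(le, 2, log(w), "+")
    ll <- sum(logsumexp(lj))
    resp <- exp(lj - logsumexp(lj))
    p <- update_emissions(x, n, resp)
    w <- pmax(colMeans(resp), 1e-12); w <- w / sum(w)
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  le <- emission_loglik(x, n, p)
  lj <- sweep(le, 2, log(w), "+")
  post <- exp(lj - logsumexp(lj))
  list(posterior = post, p = p, weights = w, loglik = sum(logsumexp(lj)),
       iterations = iter, converged = converged)
}

forward_backward <- function(le, A, init) {
  n <- nrow(le); K <- ncol(le)
  la <- matrix(-Inf, n, K); lb <- matrix(0, n, K)
  lA <- log(A)
  la[1, ] <- log(init) + le[1, ]
  for (t in 2:n) {
    for (k in seq_len(K)) {
      v <- la[t - 1, ] + lA[, k]
      la[t, k] <- le[t, k] + max(v) + log(sum(exp(v - max(v))))
    }
  }
  for (t in (n - 1):1) {
    for (k in seq_len(K)) {
      v <- lA[k, ] + le[t + 1, ] + lb[t + 1, ]
      lb[t, k] <- max(v) + log(sum(exp(v - max(v))))
    }
  }
  lg <- la + lb
  post <- exp(lg - logsumexp(lg))
  ll <- logsumexp(la)[n]
  list(posterior = post, loglik = ll, la = la, lb = lb)
}

em_chain <- function(x, n, max_iter, tol) {
  p <- c(u = 0.01, i = 0.5, m = 0.95)
  A <- matrix(0.05, 3, 3); diag(A) <- 0.9
  init <- rep(1 / 3, 3)
  ll_old <- -Inf; converged <- FALSE; iter <- 0L
  N <- length(x)
  for (iter in seq_len(max_iter)) {
    le <- emission_loglik(x, n, p)
    fb <- forward_backward(le, A, init)
    ll <- fb$loglik
    resp <- fb$posterior
    # transition expected counts
    lA <- log(A)
    xi <- matrix(0, 3, 3)
    for (t in seq_len(N - 1)) {
      m <- outer(fb$la[t, ], le[t + 1, ] + fb$lb[t + 1, ], "+") + lA
      m <- exp(m - max(m)); m <- m / sum(m)
      xi <- xi + m
    }
    A <- xi / pmax(rowSums(xi), 1e-300)
    A <- pmax(A, 1e-8); A <- A / rowSums(A)
    init <- pmax(resp[1, ], 1e-8); init <- init / sum(init)
    p <- update_emissions(x, n, resp)
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  le <- emission_loglik(x, n, p)
  fb <- forward_backward(le, A, init)
  list(posterior = fb$posterior, p = p, transitions = A, init = init,
       loglik = fb$loglik, iterations = iter, converged = converged)
}

# argmax with ties broken toward the intermediate state
argmax_state <- function(post) {
  apply(post, 1, function(r) {
    mx <- max(r)
    tied <- which(r >= mx - 1e-12)
    if (2L %in% tied) return("i")
    STATES[tied[1]]
  })
}

#' Call methylation states from count data
#'
#' Assigns each unit (a cytosine site or a 100-bp window) one of three
#' methylation states — unmethylated (`u`), intermediate (`i`, capturing
#' somatic epiheterozygotes), methylated (`m`) — with posterior
#' probabilities. Emissions are binomial with success probabilities
#' `(p_u, p_i, p_m)` estimated by expectation-maximisation under the
#' ordering constraint `p_u < p_i < p_m` (initialised at 0.01, 0.5, 0.95;
#' `p_u` bounded to `[0.001, 0.15]`, `p_m` to `[0.6, 0.999]`, `p_i` fixed
#' midway). `"independent"` mode fits a mixture; `"chain"` mode fits a
#' first-order hidden Markov chain along genome order, with posteriors
#' from the forward-backward recursion. The state is the posterior argmax
#' (ties broken toward `i`).
#'
#' @param counts A tibble with columns `count_methylated` and
#'   `count_total` (plus any unit-identifying columns such as
#'   `chrom`/`pos` or `chrom`/`start`/`end`, carried through), in genome
#'   order for `"chain"` mode.
#' @param mode `"independent"` or `"chain"`.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return The input tibble with added columns `state`, `posterior_u`,
#'   `posterior_i`, `posterior_m`, `posterior_max`. Attributes:
#'   `statecall` (list with `p`, `weights`/`transitions`, `loglik`,
#'   `iterations`, `converged`). Non-convergence is flagged in the
#'   attribute and via a warning, never silently.
#' @export
#' @examples
#' counts <- tibble::tibble(pos = 1:3 * 10,
#'                          count_methylated = c(0L, 10L, 20L),
#'                          count_total = c(20L, 20L, 20L))
#' call_states(counts)
call_states <- function(counts, mode = c("independent", "chain"),
                        max_iter = 200L, tol = 1e-6) {
  mode <- match.arg(mode)
  assert_columns(counts, c("count_methylated", "count_total"), "counts")
  x <- counts$count_methylated; n <- counts$count_total
  if (length(x) < 10) abort("need at least 10 units to estimate emission parameters")
  if (any(x > n)) abort("count_methylated exceeds count_total")
  fit <- if (mode == "independent") em_mixture(x, n, max_iter, tol)
         else em_chain(x, n, max_iter, tol)
  if (!fit$converged) {
    warn(sprintf("state-calling EM did not converge in %d iterations", fit$iterations))
  }
  post <- fit$posterior
  out <- dplyr::mutate(tibble::as_tibble(counts),
    state = argmax_state(post),
    posterior_u = post[, 1], posterior_i = post[, 2], posterior_m = post[, 3],
    posterior_max = pmax(post[, 1], post[, 2], post[, 3]))
  attr(out, "statecall") <- fit[setdiff(names(fit), "posterior")]
  attr(out, "mode") <- mode
  out
}

# --- windows ------------------------------------------------------------

#' Bin a methylome into fixed windows
#'
#' Divides the genome into non-overlapping windows (default 100 bp,
#' 1-based closed intervals on a fixed grid) and counts, per window, the
#' total number of cytosines of the chosen context and how many of them
#' are methylated. A cytosine counts as methylated according to its
#' per-site `state` if present (`m` = 1, `i` = 0.5, `u` = 0; the half
#' weights are rounded half-up per window); without a `state` column a
#' site counts as methylated when more than half of its reads are
#' methylated.
#'
#' @param methylome A methylome tibble, optionally with a `state` column.
#' @param window_size Window span in bp (default 100).
#' @param context Optional single context to keep (`"CG"`, `"CHG"`,
#'   `"CHH"`).
#' @return A tibble with columns `chrom`, `start`, `end`, `context`,
#'   `count_methylated`, `count_total`; windows containing no cytosines
#'   are omitted.
#' @export
bin_to_windows <- function(methylome, window_size = 100L, context = NULL) {
  assert_columns(methylome, c("chrom", "pos"), "methylome")
  df <- tibble::as_tibble(methylome)
  if (!is.null(context)) {
    stopifnot(length(context) == 1, context %in% CONTEXTS)
    df <- dplyr::filter(df, .data$context == !!context)
  }
  if (nrow(df) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), context = character(),
                          count_methylated = integer(),
                          count_total = integer()))
  }
  w <- if ("state" %in% names(df)) {
    state_to_level(df$state)
  } else {
    as.numeric(df$count_methylated > df$count_total / 2)
  }
  ctx_label <- if (is.null(context)) "all" else context
  df$._w <- w
  df$._win <- (df$pos - 1L) %/% window_size
  out <- df |>
    dplyr::group_by(.data$chrom, .data$._win) |>
    dplyr::summarise(
      context = .env$ctx_label,
      count_methylated = as.integer(floor(sum(.data$._w) + 0.5)),
      count_total = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(start = as.integer(.data$._win * window_size + 1L),
                  end = as.integer(.data$._win * window_size + window_size)) |>
    dplyr::select("chrom", "start", "end", "context",
                  "count_methylated", "count_total") |>
    dplyr::arrange(.data$chrom, .data$start)
  out
}

# --- state switches (SMPs / DMRs) ---------------------------------------

unit_key_cols <- function(calls) {
  for (key in list(c("chrom", "start", "end"), c("chrom", "pos"),
                   "unit", "pos", "site")) {
    if (all(key %in% names(calls))) return(key)
  }
  abort("cannot identify unit key columns (need chrom/pos, chrom/start/end, or unit)")
}

switch_calls <- function(calls_a, calls_b, min_posterior, what) {
  key <- unit_key_cols(calls_a)
  if (!identical(key, unit_key_cols(calls_b))) {
    abort("the two samples use different unit identifiers")
  }
  a <- tibble::as_tibble(calls_a); b <- tibble::as_tibble(calls_b)
  ka <- do.call(paste, c(a[key], sep = "\r"))
  kb <- do.call(paste, c(b[key], sep = "\r"))
  if (!setequal(ka, kb)) {
    abort(sprintf("%s calling requires a shared unit universe", what))
  }
  b <- b[match(ka, kb), ]
  pass <- a$posterior_max >= min_posterior & b$posterior_max >= min_posterior
  out <- a[key]
  out$state_a <- a$state; out$state_b <- b$state
  out$pass <- pass
  switches <- out[pass & out$state_a != out$state_b, ]
  attr(switches, "n_eligible") <- sum(pass)
  attr(switches, "n_total") <- nrow(out)
  attr(switches, "min_posterior") <- min_posterior
  switches[setdiff(names(switches), "pass")]
}

#' Call single methylation polymorphisms between two samples
#'
#' A single methylation polymorphism (SMP) is a cytosine site whose called
#' methylation state differs between two samples, with both samples
#' passing the posterior confidence filter at that site. Sites failing the
#' filter in either sample are excluded from the eligible denominator
#' (reported in the `n_eligible` attribute).
#'
#' @param calls_a,calls_b Per-site state calls from [call_states()] on a
#'   shared site universe.
#' @param min_posterior Minimum `posterior_max` required in both samples
#'   (default 0.99).
#' @return A tibble of SMPs (unit columns, `state_a`, `state_b`), with
#'   attributes `n_eligible`, `n_total`, `min_posterior`.
#' @export
call_smps <- function(calls_a, calls_b, min_posterior = 0.99) {
  switch_calls(calls_a, calls_b, min_posterior, "SMP")
}

#' Call differentially methylated regions between two samples
#'
#' A differentially methylated region (DMR) is a fixed-width window
#' (typically 100 bp) whose called methylation state switches between two
#' samples, e.g. unmethylated to intermediate. Same filtering semantics as
#' [call_smps()], at window resolution.
#'
#' @inheritParams call_smps
#' @param calls_a,calls_b Per-window state calls ([call_states()] on
#'   [bin_to_windows()] output).
#' @return A tibble of DMRs with the same structure as [call_smps()].
#' @export
call_dmrs <- function(calls_a, calls_b, min_posterior = 0.99) {
  switch_calls(calls_a, calls_b, min_posterior, "DMR")
}
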