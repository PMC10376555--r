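#' Collect field values inside a mask
#'
#' Values at all true cells in row-major order; the sample that the
#' mixture decomposition of a factor's within-range distribution is
#' fitted to. Cells carry equal weight, matching the point-count area
#' convention.
#'
#' @param factor_field an [new_field()].
#' @param mask an [new_mask()] on the same grid.
#' @return numeric vector of length `mask_area(mask)`.
#' @export
collect_in_range_values <- function(factor_field, mask) {
  stopifnot(inherits(factor_field, "mr_field"), inherits(mask, "mr_mask"))
  if (!same_grid(factor_field$grid, mask$grid))
    stop("field and mask are on different grids")
  if (!any(mask$membership)) stop("mask is empty; no values to collect")
  factor_field$values[mask$membership]
}

#' Mixed normal density
#'
#' Density of the k-component normal mixture
#' `g(x) = sum_k pi_k * dnorm(x, mu_k, sigma_k)`.
#'
#' @param x evaluation points.
#' @param prop,mean,sd component parameter vectors.
#' @return density values.
#' @export
dmixnorm <- function(x, prop, mean, sd) {
  out <- 0
  for (k in seq_along(prop)) out <- out + prop[k] * stats::dnorm(x, mean[k], sd[k])
  out
}

mixture_loglik <- function(x, prop, mean, sd) {
  sum(log(dmixnorm(x, prop, mean, sd)))
}

em_once <- function(x, prop, mean, sd, tol, max_iter, sd_floor) {
  n <- length(x)
  k <- length(prop)
  ll_old <- -Inf
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    # E step: responsibilities
    dens <- vapply(seq_len(k),
                   function(j) prop[j] * stats::dnorm(x, mean[j], sd[j]),
                   numeric(n))
    dens <- matrix(dens, nrow = n)
    rowsum_ <- rowSums(dens)
    rowsum_[rowsum_ == 0] <- .Machine$double.xmin
    r <- dens / rowsum_
    ll <- sum(log(rowsum_))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
    # M step
    nk <- colSums(r)
    nk[nk == 0] <- .Machine$double.xmin
    prop <- nk / n
    mean <- colSums(r * x) / nk
    sd <- sqrt(colSums(r * (outer(x, mean, "-"))^2) / nk)
    sd <- pmax(sd, sd_floor)
  }
  list(prop = prop, mean = mean, sd = sd, loglik = ll, ll_trace = ll_trace)
}

#' Fit a univariate normal mixture by EM
#'
#' Maximum-likelihood decomposition of a factor's distribution into k
#' normal components. Initialization: component means at k evenly spaced
#' sample quantiles, pooled SD, uniform proportions, plus four seeded
#' random restarts; the best log-likelihood wins. Component SDs are
#' floored at 1e-3 times the sample SD to prevent degenerate collapse.
#' Components are returned sorted by mean.
#'
#' @param values numeric sample (n >= 10 * k).
#' @param k number of components.
#' @param seed integer seed for the random restarts.
#' @param tol EM convergence tolerance on the log-likelihood.
#' @param max_iter maximum EM iterations per start.
#' @return an object of class `mixture_fit` with `prop`, `mean`, `sd`,
#'   `k`, `loglik`, `bic`, `n`, and the log-likelihood trace of the
#'   winning start (`ll_trace`).
#' @export
fit_mixture_em <- function(values, k, seed = 1L, tol = 1e-8, max_iter = 1000) {
  x <- as.numeric(values)
  if (!all(is.finite(x))) stop("non-finite values in mixture input")
  n <- length(x)
  if (k < 1) stop("k must be >= 1")
  if (n < 10 * k) stop("need at least 10*k = ", 10 * k, " values, got ", n)

  if (k == 1) {
    mu <- mean(x)
    sigma <- sqrt(sum((x - mu)^2) / n)  # MLE (1/n) SD
    ll <- sum(stats::dnorm(x, mu, sigma, log = TRUE))
    fit <- list(prop = 1, mean = mu, sd = sigma, loglik = ll,
                ll_trace = ll)
  } else {
    sx <- stats::sd(x)
    sd_floor <- max(1e-3 * sx, .Machine$double.eps)
    qs <- stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
    starts <- list(list(prop = rep(1 / k, k), mean = qs, sd = rep(sx, k)))
    rand <- with_seed(seed, lapply(1:4, function(i) {
      list(prop = rep(1 / k, k),
           mean = sort(sample(x, k)),
           sd = rep(sx * stats::runif(1, 0.3, 1.5), k))
    }))
    starts <- c(starts, rand)
    fits <- lapply(starts, function(s0) {
      em_once(x, s0$prop, s0$mean, s0$sd, tol, max_iter, sd_floor)
    })
    fit <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
    ord <- order(fit$mean)
    fit$prop <- fit$prop[ord]; fit$mean <- fit$mean[ord]; fit$sd <- fit$sd[ord]
  }

  n_par <- 3 * k - 1  # k means, k sds, k-1 free proportions
  structure(
    list(prop = fit$prop, mean = fit$mean, sd = fit$sd, k = as.integer(k),
         loglik = fit$loglik, bic = n_par * log(n) - 2 * fit$loglik,
         n = n, ll_trace = fit$ll_trace),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("normal mixture, k = %d, n = %d, loglik = %.3f, BIC = %.3f\n",
              x$k, x$n, x$loglik, x$bic))
  for (j in seq_len(x$k)) {
    cat(sprintf("  pi = %.3f  mean = %.4g  sd = %.4g\n",
                x$prop[j], x$mean[j], x$sd[j]))
  }
  invisible(x)
}

#' Select the number of mixture components by BIC
#'
#' Fits k = 1..k_max and returns the minimum-BIC fit; ties go to the
#' smaller k. When the sample is small, k_max is capped at floor(n/10).
#'
#' @param values numeric sample.
#' @param k_max largest component count tried (default 4).
#' @param seed integer seed passed to each fit.
#' @return the selected `mixture_fit`.
#' @export
select_k <- function(values, k_max = 4, seed = 1L) {
  n <- length(values)
  k_max <- min(k_max, floor(n / 10))
  if (k_max < 1) stop("sample too small for any mixture fit (n = ", n, ")")
  fits <- lapply(seq_len(k_max), function(k) fit_mixture_em(values, k, seed))
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  fits[[which.min(bics)]]  # which.min takes the first (smallest k) on ties
}

#' Main interval of one mixture component
#'
#' The interval `mean +/- multiplier * sd` (default one SD), the rule
#' behind the printed per-component factor ranges. Endpoints are kept at
#' full precision; rounding to 2 decimals happens only in rendered
#' reports.
#'
#' @param mu component mean.
#' @param sigma component SD (> 0).
#' @param multiplier half-width in SDs.
#' @return list with `lower`, `upper`.
#' @export
component_interval <- function(mu, sigma, multiplier = 1) {
  stopifnot(sigma > 0, multiplier > 0)
  list(lower = mu - multiplier * sigma, upper = mu + multiplier * sigma)
}

#' Main intervals of a mixture fit
#'
#' One interval per component with proportion >= `min_proportion`
#' (default 0: every component is retained, including minor peaks).
#'
#' @param fit a `mixture_fit`.
#' @param min_proportion smallest retained component proportion.
#' @param multiplier interval half-width in SDs.
#' @return data.frame with `component`, `prop`, `mean`, `sd`, `lower`,
#'   `upper`.
#' @export
main_intervals <- function(fit, min_proportion = 0, multiplier = 1) {
  stopifnot(inherits(fit, "mixture_fit"))
  keep <- which(fit$prop >= min_proportion)
  out <- lapply(keep, function(j) {
    iv <- component_interval(fit$mean[j], fit$sd[j], multiplier)
    data.frame(component = j, prop = fit$prop[j], mean = fit$mean[j],
               sd = fit$sd[j], lower = iv$lower, upper = iv$upper)
  })
  do.call(rbind, out)
}
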