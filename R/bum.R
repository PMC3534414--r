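# Beta-uniform mixture (BUM) modelling of p-value distributions.
#
# f(x) = lambda + (1 - lambda) * a * x^(a - 1),  0 < x <= 1, 0 < a < 1.
# The uniform component models noise, the Beta(a, 1) component signal.
# pi_upper = f(1) = lambda + (1 - lambda) * a is an upper bound on the
# fraction of noise p-values.

#' BUM density, distribution and quantile functions
#'
#' @param x,q,p numeric vectors in (0, 1].
#' @param lambda uniform mixture weight in [0, 1].
#' @param a beta shape parameter in (0, 1).
#' @return Numeric vector.
#' @export
dbum <- function(x, lambda, a) lambda + (1 - lambda) * a * x^(a - 1)

#' @rdname dbum
#' @export
pbum <- function(q, lambda, a) lambda * q + (1 - lambda) * q^a

#' @rdname dbum
#' @export
qbum <- function(p, lambda, a) {
  vapply(p, function(pp) {
    if (pp <= 0) return(0)
    if (pp >= 1) return(1)
    stats::uniroot(function(x) pbum(x, lambda, a) - pp,
                   lower = .Machine$double.xmin, upper = 1,
                   tol = 1e-12)$root
  }, numeric(1))
}

#' Fit a beta-uniform mixture model to p-values
#'
#' Maximum-likelihood fit of the two-parameter BUM model by box-constrained
#' optimization (\code{L-BFGS-B}) from a deterministic grid of starting
#' values; the best of all converged fits is kept. p-values of exactly zero
#' are clamped to \code{1e-12} (reported in the result).
#'
#' @param pvalues numeric vector of at least 20 p-values in [0, 1].
#' @return Object of class \code{bum_model}: \code{lambda}, \code{a},
#'   \code{pi_upper}, \code{n}, \code{loglik}, \code{convergence},
#'   \code{n_clamped}.
#' @export
fit_bum <- function(pvalues) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (length(pvalues) < 20)
    stop_usage("need at least 20 p-values to fit a BUM model, got ",
               length(pvalues))
  if (any(pvalues < 0 | pvalues > 1))
    stop_usage("p-values must lie in [0, 1]")
  n_clamped <- sum(pvalues == 0)
  pvalues[pvalues == 0] <- 1e-12
  nll <- function(par) {
    d <- dbum(pvalues, par[1], par[2])
    if (any(!is.finite(d)) || any(d <= 0)) return(1e10)
    -sum(log(d))
  }
  eps <- 1e-6
  starts <- expand.grid(lambda = c(0.1, 0.3, 0.5, 0.7, 0.9),
                        a = c(0.05, 0.2, 0.4, 0.6, 0.8))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), nll, method = "L-BFGS-B",
                   lower = c(eps, eps), upper = c(1 - eps, 1 - eps)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || !is.finite(best$value))
    stop_usage("BUM fit failed: non-finite likelihood for all starting values")
  lambda <- best$par[1]; a <- best$par[2]
  structure(list(lambda = lambda, a = a,
                 pi_upper = lambda + (1 - lambda) * a,
                 n = length(pvalues), loglik = -best$value,
                 convergence = best$convergence, n_clamped = n_clamped),
            class = "bum_model")
}

#' @export
print.bum_model <- function(x, ...) {
  cat(sprintf(paste0("beta-uniform mixture: lambda = %.4f, a = %.4f, ",
                     "pi_upper = %.4f (n = %d, loglik = %.2f)\n"),
              x$lambda, x$a, x$pi_upper, x$n, x$loglik))
  invisible(x)
}

#' Quantile-quantile table for a fitted BUM model
#'
#' Empirical quantiles of the observed p-values against the quantiles of the
#' fitted BUM distribution, for goodness-of-fit assessment.
#'
#' @param model a [fit_bum()] result.
#' @param pvalues observed p-values.
#' @return Data frame with columns \code{observed} and \code{fitted}.
#' @export
qq_bum <- function(model, pvalues) {
  pvalues <- sort(pvalues[!is.na(pvalues)])
  n <- length(pvalues)
  probs <- (seq_len(n) - 0.5) / n
  data.frame(observed = pvalues,
             fitted = qbum(probs, model$lambda, model$a))
}

#' FDR-controlled p-value threshold from a BUM model
#'
#' The p-value threshold tau below which a node receives a positive score,
#' for a pre-selected false discovery rate:
#' \deqn{\tau = \left(\frac{\pi - FDR \cdot \pi}{FDR - FDR \cdot \pi}\right)^{1/(a-1)}}
#' with \eqn{\pi} the model's pi-upper. tau is clipped into (0, 1].
#'
#' @param model a [fit_bum()] result.
#' @param fdr false discovery rate in (0, 1).
#' @return Threshold tau.
#' @export
fdr_threshold <- function(model, fdr) {
  assert_scalar_number(fdr, "fdr")
  if (fdr <= 0 || fdr >= 1) stop_usage("fdr must lie strictly in (0, 1)")
  if (model$a >= 1) stop_usage("fitted a >= 1: no signal component to threshold")
  pi_u <- model$pi_upper
  if (pi_u >= 1) stop_usage("pi_upper >= 1: degenerate all-noise fit")
  arg <- (pi_u - fdr * pi_u) / (fdr - fdr * pi_u)
  tau <- arg^(1 / (model$a - 1))
  if (!is.finite(tau)) stop_usage("degenerate fdr/pi_upper combination")
  min(max(tau, .Machine$double.xmin), 1)
}

#' Score network nodes from p-values under a BUM model
#'
#' Log-likelihood-ratio node score with FDR calibration:
#' \eqn{S(x) = (a - 1)(\log x - \log \tau)} (natural logarithm), positive
#' exactly when \eqn{x < \tau}. Nodes without a p-value (unmeasured
#' metabolites) all receive the mean of the negative measured scores, a
#' score drawn from the noise level of the data.
#'
#' @param model a [fit_bum()] result.
#' @param pvalues named numeric vector of p-values (names = node IDs).
#' @param fdr false discovery rate (the module search default is 0.2).
#' @param nodes optional character vector of all network node IDs; nodes
#'   absent from \code{pvalues} are scored as unmeasured.
#' @return Data frame of class \code{node_score_table} with columns
#'   \code{node}, \code{p_value}, \code{score}, \code{measured}; attributes
#'   \code{fdr}, \code{tau}, \code{unmeasured_score}, \code{model}.
#' @export
score_nodes <- function(model, pvalues, fdr = 0.2, nodes = NULL) {
  if (is.null(names(pvalues)) && !is.null(nodes) &&
      length(pvalues) == length(nodes)) names(pvalues) <- nodes
  if (is.null(names(pvalues)))
    stop_usage("pvalues must be named by node ID")
  pvalues <- pvalues[!is.na(pvalues)]
  n_clamped <- sum(pvalues <= 0)
  pvalues[pvalues <= 0] <- 1e-12
  pvalues[pvalues > 1] <- 1
  tau <- fdr_threshold(model, fdr)
  measured_score <- (model$a - 1) * (log(pvalues) - log(tau))
  neg <- measured_score[measured_score < 0]
  unmeasured_score <- if (length(neg) > 0) mean(neg) else 0
  all_nodes <- union(names(pvalues), nodes %||% character(0))
  p_col <- unname(pvalues[all_nodes])
  measured <- all_nodes %in% names(pvalues)
  score <- ifelse(measured, unname(measured_score[all_nodes]),
                  unmeasured_score)
  out <- data.frame(node = all_nodes, p_value = p_col, score = score,
                    measured = measured, stringsAsFactors = FALSE)
  structure(out, class = c("node_score_table", "data.frame"),
            fdr = fdr, tau = tau, unmeasured_score = unmeasured_score,
            n_clamped = n_clamped, model = model)
}
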