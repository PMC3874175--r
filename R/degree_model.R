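# Exponential and hypo-exponential models of regulatory in-degree.
#
# The in-degree (number of distinct TFs bound) of a regulatory region is
# modeled with the continuous exponential density f(x) = lambda exp(-lambda
# x), whose MLE is lambda-hat = n / sum(x); 1/lambda is the average number
# of interactions. The per-gene sum over regions (promoter + first intron)
# is then modeled with the hypo-exponential distribution, i.e. the law of a
# sum of independent exponentials with distinct rates. Counts are integers,
# so model comparison uses the rounding-aware discretised likelihood
# P(k) = F(k + 1/2) - F(max(k - 1/2, 0)).

#' Fit an exponential in-degree model
#'
#' @param values Non-negative interaction counts (one per region).
#' @return Object of class `degree_fit`: `rates` (length 1), `mean`
#'   (`1/rate`), `n`, `log_likelihood` (continuous exponential density).
#' @export
fit_exponential <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1L, all(values >= 0))
  s <- sum(values)
  if (s <= 0) stop("all-zero sample: exponential rate is not identifiable")
  n <- length(values)
  rate <- n / s
  structure(list(rates = rate, mean = 1 / rate, n = n,
                 log_likelihood = n * log(rate) - rate * s),
            class = "degree_fit")
}

#' @export
print.degree_fit <- function(x, ...) {
  cat(sprintf("degree_fit: rate(s) %s, n = %d, logLik = %.3f\n",
              paste(signif(x$rates, 4), collapse = ", "), x$n,
              x$log_likelihood))
  invisible(x)
}

hypoexp_coefs <- function(rates) {
  vapply(seq_along(rates), function(i)
    prod(rates[-i] / (rates[-i] - rates[i])), numeric(1))
}

dispatch_rates <- function(rates) {
  stopifnot(all(rates > 0), length(rates) >= 1L)
  if (length(rates) == 1L) return("single")
  rel <- abs(outer(rates, rates, "-")) / pmin(outer(rates, rates, pmax), Inf)
  near <- rel < 1e-9 & upper.tri(rel)
  if (!any(near)) return("distinct")
  if (all(rel[upper.tri(rel)] < 1e-9)) return("erlang")
  stop("mixed nearly-equal and distinct rates are not supported; ",
       "merge the equal rates explicitly")
}

#' Hypo-exponential density
#'
#' Density of a sum of independent exponential variables. Distinct rates
#' use the standard mixture-coefficient form (for two rates,
#' `l1 l2 / (l2 - l1) * (exp(-l1 x) - exp(-l2 x))`); equal rates are
#' dispatched to the Erlang/gamma closed form, which is the numerically
#' stable limit; a single rate reduces to the exponential density.
#'
#' @param x Non-negative quantiles (density is 0 for x < 0).
#' @param rates Positive rates, one per summed exponential.
#' @return Density values.
#' @export
hypoexp_density <- function(x, rates) {
  mode <- dispatch_rates(rates)
  out <- switch(mode,
    single = stats::dexp(x, rates),
    erlang = stats::dgamma(x, shape = length(rates), rate = mean(rates)),
    distinct = {
      cf <- hypoexp_coefs(rates)
      v <- as.vector(exp(-outer(pmax(x, 0), rates)) %*% (cf * rates))
      pmax(v, 0)   # clip tiny negative round-off
    })
  out[x < 0] <- 0
  out
}

#' Hypo-exponential cumulative distribution function
#' @inheritParams hypoexp_density
#' @return CDF values.
#' @export
hypoexp_cdf <- function(x, rates) {
  mode <- dispatch_rates(rates)
  out <- switch(mode,
    single = stats::pexp(x, rates),
    erlang = stats::pgamma(x, shape = length(rates), rate = mean(rates)),
    distinct = {
      cf <- hypoexp_coefs(rates)
      v <- 1 - as.vector(exp(-outer(pmax(x, 0), rates)) %*% cf)
      pmin(pmax(v, 0), 1)
    })
  out[x < 0] <- 0
  out
}

# log-likelihood of integer counts under a continuous CDF, discretised to
# the rounding cell [k - 1/2, k + 1/2)
discretised_loglik <- function(counts, cdf) {
  lo <- cdf(pmax(counts - 0.5, 0))
  hi <- cdf(counts + 0.5)
  sum(log(pmax(hi - lo, .Machine$double.xmin)))
}

ks_distance <- function(x, cdf) {
  xs <- sort(x)
  n <- length(xs)
  Fx <- cdf(xs)
  max(abs(Fx - seq_len(n) / n), abs(Fx - (seq_len(n) - 1L) / n))
}

#' Compare exponential vs hypo-exponential models of gene in-degree
#'
#' Fits an exponential to each region's in-degree sample, predicts the
#' combined (promoter + first intron) in-degree as the hypo-exponential
#' with the two fitted rates, and compares that prediction with a single
#' exponential fitted directly to the combined counts, by discretised
#' log-likelihood and Kolmogorov-Smirnov distance.
#'
#' @param promoter,intron Per-gene in-degree counts, aligned by gene.
#' @param combined Optional combined counts (default `promoter + intron`).
#' @return List of class `degree_comparison` with the per-region fits, the
#'   hypo-exponential prediction (`rates`, `predicted_mean`), log-likelihoods
#'   and KS distances of both models on the combined counts, and `winner`.
#'   Degenerate samples are flagged in `error` instead of fitting.
#' @export
compare_degree_models <- function(promoter, intron,
                                  combined = promoter + intron) {
  res <- try({
    fit_p <- fit_exponential(promoter)
    fit_i <- fit_exponential(intron)
    fit_c <- fit_exponential(combined)
    rates <- c(fit_p$rates, fit_i$rates)
    ll_hypo <- discretised_loglik(combined,
                                  function(q) hypoexp_cdf(q, rates))
    ll_exp <- discretised_loglik(combined,
                                 function(q) stats::pexp(q, fit_c$rates))
    list(fit_promoter = fit_p, fit_intron = fit_i,
         fit_combined_exponential = fit_c,
         hypoexp_rates = rates,
         predicted_mean = sum(1 / rates),
         observed_mean = mean(combined),
         loglik_hypoexp = ll_hypo,
         loglik_exponential = ll_exp,
         ks_hypoexp = ks_distance(combined,
                                  function(q) hypoexp_cdf(q, rates)),
         ks_exponential = ks_distance(combined,
                                      function(q) stats::pexp(q, fit_c$rates)),
         winner = if (ll_hypo > ll_exp) "hypoexponential" else "exponential",
         error = NULL)
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    res <- list(error = paste("degree model fit failed:",
                              attr(res, "condition")$message))
  structure(res, class = "degree_comparison")
}

#' Read a single-column in-degree sample from TSV
#' @param path File with one count per line (header optional).
#' @return Numeric vector.
#' @export
read_degree_sample <- function(path) {
  x <- readLines(path)
  x <- x[nzchar(trimws(x))]
  suppressWarnings({
    v <- as.numeric(x)
    if (is.na(v[1])) v <- v[-1]   # tolerate a header line
  })
  if (anyNA(v)) stop("non-numeric entries in ", path)
  v
}
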