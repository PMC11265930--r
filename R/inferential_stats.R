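# Inferential layer: chi-squared goodness of fit against uniform latch
# use, Mann-Whitney comparisons, binomial GLM fitting with AICc, greedy
# forward model building, likelihood-ratio tests and Akaike weights.

#' Chi-squared goodness of fit against uniform category use
#'
#' Tests observed category counts against the uniform expectation
#' \eqn{E = \sum O_i / k}, giving \eqn{\chi^2 = \sum (O_i - E)^2 / E} on
#' \eqn{k - 1} degrees of freedom (no continuity correction).
#'
#' @param counts non-negative integer counts, length >= 2.
#' @return List of class \code{"latch_test"} with \code{statistic},
#'   \code{df}, \code{p_value}, \code{expected}, \code{method}.
#' @examples
#' chisq_uniform_gof(c(21, 11, 3, 0))
#' @export
chisq_uniform_gof <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L) stop("need at least two categories", call. = FALSE)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (sum(counts) == 0) stop("all counts are zero", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(counts))
  structure(list(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = unname(ct$p.value),
                 n = sum(counts),
                 expected = unname(ct$expected),
                 method = "chi-squared goodness of fit vs uniform",
                 tie_correction_applied = FALSE),
            class = "latch_test")
}

#' Mann-Whitney U test (W convention)
#'
#' Rank-sum comparison of two samples on pooled mid-ranks. The statistic
#' is reported in the W convention used by R: the sum of the first
#' sample's ranks minus \eqn{n_1(n_1+1)/2} (identical to the
#' Mann-Whitney U of the first sample). The p-value is exact (by
#' enumeration of rank assignments) when \eqn{n_1 + n_2 \le 12} and
#' there are no ties; otherwise a normal approximation with tie and
#' continuity corrections is used.
#'
#' @param x,y numeric samples.
#' @param alternative \code{"two.sided"} (default), \code{"less"} or
#'   \code{"greater"}.
#' @return List of class \code{"latch_test"} with \code{statistic} (W),
#'   \code{n1}, \code{n2}, \code{p_value}, \code{exact},
#'   \code{tie_correction_applied}, \code{method}.
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "less",
                                               "greater")) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 12L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE)
  )
  structure(list(statistic = unname(wt$statistic),
                 n1 = length(x), n2 = length(y),
                 p_value = unname(wt$p.value),
                 exact = exact,
                 tie_correction_applied = ties && !exact,
                 alternative = alternative,
                 method = "Mann-Whitney U (rank-sum W convention)"),
            class = "latch_test")
}

#' @export
print.latch_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.null(x$df)) {
    cat(sprintf("  statistic = %.4f, df = %d, p = %.4g\n",
                x$statistic, x$df, x$p_value))
  } else {
    cat(sprintf("  W = %.1f (n1 = %d, n2 = %d), p = %.4g%s\n",
                x$statistic, x$n1, x$n2, x$p_value,
                if (isTRUE(x$exact)) " [exact]" else ""))
  }
  invisible(x)
}

#' Fit a binomial (logistic) GLM with AICc
#'
#' Wraps [stats::glm()] with a logit link and augments the fit with Wald
#' 95\% confidence intervals, AICc (the small-sample AIC correction
#' \eqn{AICc = AIC + 2k(k+1)/(n-k-1)}) and a separation diagnostic.
#' Fitted probabilities numerically at 0/1 or runaway coefficients
#' (perfect separation) raise a warning and set \code{separation = TRUE}.
#'
#' @param formula model formula with a 0/1 (or logical/factor) response.
#' @param data data frame of response and predictors.
#' @return List of class \code{"binom_glm"} with elements \code{fit},
#'   \code{coefficients}, \code{ci} (matrix with lower/upper),
#'   \code{loglik}, \code{deviance}, \code{k}, \code{n}, \code{AIC},
#'   \code{AICc}, \code{separation}, \code{formula}.
#' @export
fit_binomial_glm <- function(formula, data) {
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(formula, family = stats::binomial(), data = data,
               control = stats::glm.control(epsilon = 1e-8, maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  co <- stats::coef(fit)
  co <- co[!is.na(co)]  # drop aliased (rank-deficient) terms
  se <- sqrt(diag(stats::vcov(fit)))[names(co)]
  if (!sep && any(abs(co) > 15)) sep <- TRUE
  if (sep) {
    warning("possible complete separation: coefficient estimates may be ",
            "diverging", call. = FALSE)
  }
  k <- length(co)
  n <- stats::nobs(fit)
  if (n <= k + 1L) {
    stop("AICc undefined: n must exceed k + 1 (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  }
  aic <- stats::AIC(fit)
  structure(list(fit = fit,
                 coefficients = co,
                 se = se,
                 ci = cbind(lower = co - 1.96 * se, upper = co + 1.96 * se),
                 loglik = as.numeric(stats::logLik(fit)),
                 deviance = stats::deviance(fit),
                 k = k, n = n,
                 AIC = aic,
                 AICc = aic + 2 * k * (k + 1) / (n - k - 1),
                 separation = sep,
                 formula = stats::formula(fit)),
            class = "binom_glm")
}

#' @export
print.binom_glm <- function(x, ...) {
  cat("binomial GLM:", deparse(x$formula), "\n")
  tab <- cbind(beta = x$coefficients, x$ci)
  print(round(tab, 4))
  cat(sprintf("  logLik = %.3f, deviance = %.3f, AIC = %.3f, AICc = %.3f (k = %d, n = %d)\n",
              x$loglik, x$deviance, x$AIC, x$AICc, x$k, x$n))
  invisible(x)
}

#' Likelihood-ratio test between nested binomial GLMs
#'
#' \eqn{LRT = 2(\ell_{full} - \ell_{null})} on
#' \eqn{k_{full} - k_{null}} degrees of freedom, with an upper-tail
#' chi-squared p-value.
#'
#' @param fit_null,fit_full nested \code{"binom_glm"} fits with
#'   \code{fit_full} having strictly more parameters.
#' @return List of class \code{"latch_test"}.
#' @export
lrt <- function(fit_null, fit_full) {
  stopifnot(inherits(fit_null, "binom_glm"), inherits(fit_full, "binom_glm"))
  df <- fit_full$k - fit_null$k
  stat <- max(0, 2 * (fit_full$loglik - fit_null$loglik))
  # equal parameter counts are only admissible for the degenerate case
  # of comparing a model with itself (LRT = 0, p = 1)
  if (df < 0L || (df == 0L && stat > 1e-8)) {
    stop("models are not nested with k_full >= k_null", call. = FALSE)
  }
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat,
                 df = df,
                 p_value = p,
                 method = "likelihood-ratio test",
                 tie_correction_applied = FALSE),
            class = "latch_test")
}

#' Akaike weights from AICc values
#'
#' \eqn{\Delta_m = AICc_m - \min AICc}; \eqn{w_m =
#' \exp(-\Delta_m/2) / \sum_j \exp(-\Delta_j/2)}. Weights sum to 1 and
#' are invariant to adding a constant to every AICc.
#'
#' @param aicc numeric vector of AICc values.
#' @return Numeric weights of the same length.
#' @export
akaike_weights <- function(aicc) {
  aicc <- as.numeric(aicc)
  if (length(aicc) == 0L) stop("need at least one AICc value", call. = FALSE)
  delta <- aicc - min(aicc)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Greedy forward stepwise binomial model building
#'
#' Starts from the intercept-only (null) model and, at each step, fits
#' the current model plus each remaining candidate, picks the candidate
#' with the largest deviance reduction (ties broken by input order), and
#' retains the step only if it lowers the selection criterion (AICc by
#' default). The full path of retained models is returned with delta
#' criterion values, Akaike weights over the path and a likelihood-ratio
#' test of the final model against the null.
#'
#' @param data data frame holding the response and candidate predictors.
#' @param response name of the 0/1 response column.
#' @param candidates character vector of candidate predictor terms.
#' @param criterion \code{"AICc"} (default) or \code{"AIC"}.
#' @return List of class \code{"model_comparison"} with \code{models}
#'   (data frame: formula, k, loglik, deviance, AICc, dAICc, weight),
#'   \code{fits} (the path fits), \code{best} (fit with lowest
#'   criterion), \code{lrt_vs_null}, \code{trace} (every model tried).
#' @export
forward_stepwise <- function(data, response, candidates,
                             criterion = c("AICc", "AIC")) {
  criterion <- match.arg(criterion)
  if (length(candidates) < 1L) stop("need at least one candidate", call. = FALSE)
  crit <- function(f) if (criterion == "AICc") f$AICc else f$AIC
  null_formula <- stats::as.formula(paste(response, "~ 1"))
  current <- fit_binomial_glm(null_formula, data)
  path <- list(null = current)
  trace <- data.frame(step = 0L, model = paste(response, "~ 1"),
                      deviance = current$deviance, AICc = current$AICc,
                      retained = TRUE, stringsAsFactors = FALSE)
  in_model <- character(0)
  remaining <- candidates
  step <- 0L
  while (length(remaining) > 0L) {
    step <- step + 1L
    fits <- vector("list", length(remaining))
    for (i in seq_along(remaining)) {
      terms_i <- c(in_model, remaining[i])
      f <- stats::as.formula(paste(response, "~", paste(terms_i, collapse = " + ")))
      fits[[i]] <- suppressWarnings(fit_binomial_glm(f, data))
      trace <- rbind(trace, data.frame(
        step = step, model = paste(response, "~", paste(terms_i, collapse = " + ")),
        deviance = fits[[i]]$deviance, AICc = fits[[i]]$AICc,
        retained = FALSE, stringsAsFactors = FALSE))
    }
    dev_red <- current$deviance - vapply(fits, `[[`, numeric(1), "deviance")
    best_i <- which.max(dev_red)  # which.max takes the first on ties
    cand_fit <- fits[[best_i]]
    if (crit(cand_fit) < crit(current)) {
      current <- cand_fit
      in_model <- c(in_model, remaining[best_i])
      remaining <- remaining[-best_i]
      path[[paste(in_model, collapse = "+")]] <- current
      trace$retained[nrow(trace) - length(fits) + best_i] <- TRUE
    } else {
      break
    }
  }
  aiccs <- vapply(path, crit, numeric(1))
  w <- akaike_weights(aiccs)
  models <- data.frame(
    model = vapply(path, function(f) paste(deparse(f$formula), collapse = ""),
                   character(1)),
    k = vapply(path, `[[`, numeric(1), "k"),
    loglik = vapply(path, `[[`, numeric(1), "loglik"),
    deviance = vapply(path, `[[`, numeric(1), "deviance"),
    AICc = vapply(path, `[[`, numeric(1), "AICc"),
    stringsAsFactors = FALSE)
  models$dAICc <- models$AICc - min(models$AICc)
  models$weight <- w
  best <- path[[which.min(aiccs)]]
  comparison <- list(models = models, fits = path, best = best,
                     criterion = criterion, trace = trace)
  comparison$lrt_vs_null <- if (best$k > path[[1L]]$k) {
    lrt(path[[1L]], best)
  } else NULL
  structure(comparison, class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("forward stepwise binomial GLM (criterion:", x$criterion, ")\n")
  print(cbind(x$models[, c("model", "k")],
              round(x$models[, c("deviance", "AICc", "dAICc", "weight")], 3)),
        row.names = FALSE)
  if (!is.null(x$lrt_vs_null)) {
    cat(sprintf("best vs null: LRT = %.3f (df %d), p = %.4g\n",
                x$lrt_vs_null$statistic, x$lrt_vs_null$df,
                x$lrt_vs_null$p_value))
  }
  invisible(x)
}
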