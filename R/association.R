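## Genotype-phenotype association. 2x2 exact tests and Woolf odds ratios
## for single variants; binomial GLMs (logit link) for copy-number dosage
## predictors; backward BIC elimination for the minimal model.

#' Two-sided Fisher exact test on a 2x2 table
#'
#' The two-sided p sums hypergeometric probabilities of all tables sharing
#' the observed margins whose probability does not exceed that of the
#' observed table (the conventional rule).
#'
#' @param tab 2x2 matrix of non-negative counts (rows = exposure groups,
#'   columns = outcome).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return The p-value.
#' @export
fisherExact <- function(tab, alternative = "two.sided") {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  if (any(rowSums(tab) == 0) && any(colSums(tab) == 0))
    stop("empty margin in 2x2 table")
  stats::fisher.test(tab, alternative = alternative)$p.value
}

#' Woolf odds ratio with optional Haldane-Anscombe correction
#'
#' With the correction, 0.5 is added to every cell (whether or not a zero
#' is present) before the cross-product ratio; the 95% CI uses the Woolf
#' log-scale standard error `sqrt(sum(1/cells))`.
#'
#' @param tab 2x2 count matrix `[[a, b], [c, d]]`; OR = (a d)/(b c).
#' @param correction Apply the Haldane-Anscombe 0.5 correction (default
#'   `TRUE`).
#' @param conf Confidence level.
#' @return List with `or`, `ci_low`, `ci_high`, `se_log`. Without the
#'   correction a zero cell yields an explicit `Inf` or 0 odds ratio and
#'   infinite CI bounds rather than an error.
#' @export
woolfOr <- function(tab, correction = TRUE, conf = 0.95) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  x <- tab + if (correction) 0.5 else 0
  or <- (x[1, 1] * x[2, 2]) / (x[1, 2] * x[2, 1])
  se <- sqrt(sum(1 / x))
  z <- qnorm(1 - (1 - conf) / 2)
  ci <- if (is.finite(or) && or > 0) exp(log(or) + c(-1, 1) * z * se) else c(0, Inf)
  list(or = or, ci_low = ci[1], ci_high = ci[2], se_log = se)
}

#' Fit a binomial (logit) GLM and summarise as odds ratios
#'
#' Thin wrapper over [stats::glm()] that packages coefficients, Wald 95%
#' CIs on the odds-ratio scale, deviances, BIC and a separation flag.
#' Complete separation inflates coefficients without bound; any
#' |coefficient| above `separationBound` on the logit scale flags the fit
#' rather than clipping it (such odds ratios print as astronomically large
#' numbers, which is faithful to the unpenalised likelihood).
#'
#' @param y Binary 0/1 response vector.
#' @param X data.frame of predictors (continuous and/or factor columns).
#' @param separationBound Logit-scale |coefficient| threshold for the
#'   separation flag.
#' @return Object of class `glmFit`: list with `coefficients` (data.frame
#'   of term, beta, se, or, ci_low, ci_high, p), `deviance`,
#'   `null_deviance`, `df_residual`, `bic`, `n`, `converged`, `separation`,
#'   `model` (the underlying `glm` object).
#' @export
fitBinomialGlm <- function(y, X, separationBound = 15) {
  stopifnot(all(y %in% c(0, 1)))
  X <- as.data.frame(X)
  if (length(y) != nrow(X)) stop("response and design lengths differ")
  if (length(y) < ncol(X) + 1L) stop("more parameters than observations")
  dat <- cbind(.y = y, X)
  fit <- suppressWarnings(glm(.y ~ ., data = dat, family = binomial(),
    control = list(epsilon = 1e-10, maxit = 100L)))
  cf <- summary(fit)$coefficients
  kept <- rownames(cf)
  beta <- cf[, 1]; se <- cf[, 2]
  z <- qnorm(0.975)
  co <- data.frame(
    term = kept, beta = beta, se = se,
    or = exp(beta), ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
    p = cf[, 4], row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(
    coefficients = co,
    deviance = fit$deviance,
    null_deviance = fit$null.deviance,
    df_residual = fit$df.residual,
    bic = stats::BIC(fit),
    n = length(y),
    converged = fit$converged,
    separation = any(abs(beta[-1]) > separationBound),
    degenerate = length(unique(y)) < 2L,
    model = fit
  ), class = "glmFit")
}

#' @export
print.glmFit <- function(x, ...) {
  cat(sprintf("Binomial GLM: n = %d, deviance = %.3f (null %.3f), BIC = %.2f%s\n",
    x$n, x$deviance, x$null_deviance, x$bic,
    if (x$separation) " [separation]" else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Likelihood-ratio test of a fitted GLM against the intercept-only null
#'
#' Chi-square test on the deviance drop, with degrees of freedom equal to
#' the number of non-intercept parameters (an analysis-of-deviance
#' comparison to the null model).
#'
#' @param fit A `glmFit` from [fitBinomialGlm()].
#' @return Two-sided p-value (1 for the null model itself).
#' @export
lrTestVsNull <- function(fit) {
  stopifnot(inherits(fit, "glmFit"))
  df <- (fit$n - 1L) - fit$df_residual
  if (df < 0L) stop("model is not a superset of the intercept-only null")
  if (df == 0L) return(1.0)
  stat <- fit$null_deviance - fit$deviance
  pchisq(max(stat, 0), df = df, lower.tail = FALSE)
}

#' Backward stepwise model reduction under BIC
#'
#' Starting from the full design, repeatedly refits with each remaining
#' column removed and drops the one whose removal most decreases BIC,
#' stopping when no removal decreases it. Ties break by column order, so
#' the procedure is deterministic; aliased (perfectly collinear) columns
#' are dropped first since they contribute parameters without likelihood.
#'
#' @inheritParams fitBinomialGlm
#' @return `glmFit` of the minimal model, with a `kept` attribute listing
#'   the retained column names (possibly none: intercept-only).
#' @export
stepwiseBic <- function(y, X, separationBound = 15) {
  X <- as.data.frame(X)
  cols <- names(X)
  ## drop aliased duplicates (NA coefficients) up front
  fit <- fitBinomialGlm(y, X, separationBound)
  alias <- is.na(coef(fit$model))
  if (any(alias)) {
    mm_names <- names(coef(fit$model))[alias]
    drop <- cols[vapply(cols, function(cn) {
      if (is.factor(X[[cn]]) || is.character(X[[cn]]))
        any(startsWith(mm_names, cn) & nchar(mm_names) > nchar(cn))
      else cn %in% mm_names
    }, logical(1))]
    cols <- setdiff(cols, drop)
  }
  repeat {
    cur <- if (length(cols)) fitBinomialGlm(y, X[, cols, drop = FALSE], separationBound)
           else nullGlm(y)
    if (!length(cols)) break
    bics <- vapply(seq_along(cols), function(i) {
      rest <- cols[-i]
      if (length(rest)) fitBinomialGlm(y, X[, rest, drop = FALSE], separationBound)$bic
      else nullGlm(y)$bic
    }, numeric(1))
    best <- which.min(bics)  # first minimum: ties break by column order
    if (bics[best] < cur$bic) cols <- cols[-best] else break
  }
  attr(cur, "kept") <- cols
  cur
}

nullGlm <- function(y) fitBinomialGlm(y, data.frame(row.names = seq_along(y)))
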