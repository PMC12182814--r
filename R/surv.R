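# Progression-free survival of contraction phenotypes: Kaplan-Meier
# estimates, pairwise log-rank tests, and a multivariable Cox proportional
# hazards model with Breslow tie handling. Model fitting is delegated to
# the survival package; this module fixes the study's conventions (time in
# months from the index examination, 95% CIs, per-SD covariate scaling by
# default) and the table shapes.

#' Kaplan-Meier product-limit estimate with risk table
#'
#' @param records data frame with columns `time_months` and `event`
#'   (1 = event, 0 = right-censored).
#' @param group optional vector splitting the records into groups (e.g.
#'   cluster labels).
#' @return data frame of class `km_estimate`: `group`, `time`, `surv`
#'   (S(t)), `n_risk`, `n_event`, `n_censor`, with one block per group.
#'   `S(0) = 1` and the estimate drops only at event times.
#' @export
km_estimate <- function(records, group = NULL) {
  .check_surv(records)
  if (is.null(group)) group <- rep("all", nrow(records))
  fit <- survival::survfit(
    survival::Surv(records$time_months, records$event) ~ grp,
    data = data.frame(grp = factor(group)))
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(levels(factor(group)), length(s$time))
         else sub("^grp=", "", as.character(s$strata))
  out <- data.frame(group = grp, time = s$time, surv = s$surv,
                    n_risk = s$n.risk, n_event = s$n.event,
                    n_censor = s$n.censor)
  class(out) <- c("km_estimate", "data.frame")
  out
}

#' Pairwise log-rank tests between groups
#'
#' Standard two-group log-rank chi-square for every unordered pair of
#' groups; the returned matrix of p-values is symmetric with an empty
#' diagonal.
#'
#' @inheritParams km_estimate
#' @param labels group labels (cluster assignments).
#' @return list of class `logrank_pairwise`: symmetric matrices `p_value`
#'   and `chisq`.
#' @export
logrank_pairwise <- function(records, labels) {
  .check_surv(records)
  ks <- sort(unique(labels))
  p <- chi <- matrix(NA_real_, length(ks), length(ks),
                     dimnames = list(ks, ks))
  for (i in seq_along(ks)) for (j in seq_along(ks)) if (j > i) {
    sel <- labels %in% ks[c(i, j)]
    sd <- survival::survdiff(
      survival::Surv(time_months, event) ~ grp,
      data = data.frame(records[sel, c("time_months", "event")],
                        grp = factor(labels[sel])))
    chi[i, j] <- chi[j, i] <- sd$chisq
    p[i, j] <- p[j, i] <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  }
  structure(list(p_value = p, chisq = chi), class = "logrank_pairwise")
}

#' Multivariable Cox proportional hazards fit (Breslow ties)
#'
#' Fits a Cox model by partial-likelihood maximization with Breslow's
#' approximation for tied event times. Continuous covariates are
#' standardized to unit (population) SD by default, so hazard ratios are
#' per-SD; binary 0/1 covariates (such as the phenotype flag) are never
#' rescaled. `scaling = "unit"` fits on the raw scale instead. Confidence
#' intervals are 95% (`exp(coef +/- 1.96 SE)`).
#'
#' @param records data frame with `time_months`, `event`, and the covariate
#'   columns.
#' @param covariates character vector of covariate column names.
#' @param scaling `"sd"` (default) or `"unit"`.
#' @return object of class `cox_fit`: data frame `table` (covariate, coef,
#'   se, HR, CI bounds, p), `loglik`, `iter`, `flags` (separation warnings),
#'   and the underlying `coxph` fit.
#' @export
cox_fit <- function(records, covariates, scaling = c("sd", "unit")) {
  scaling <- match.arg(scaling)
  .check_surv(records)
  if (sum(records$event) < 1L) .stopf("no events in the survival records")
  miss <- setdiff(covariates, names(records))
  if (length(miss)) .stopf("missing covariates: %s", paste(miss, collapse = ", "))
  X <- as.matrix(records[, covariates, drop = FALSE])
  binary <- apply(X, 2, function(v) all(v %in% c(0, 1)))
  scale_used <- rep(1, ncol(X))
  if (scaling == "sd") {
    scale_used <- ifelse(binary, 1, apply(X, 2, .sd_pop))
    X <- sweep(X, 2, scale_used, "/")
  }
  if (qr(cbind(1, X))$rank < ncol(X) + 1)
    .stopf("covariates are collinear; drop or combine: %s",
           paste(covariates, collapse = ", "))
  dat <- data.frame(time = records$time_months, event = records$event, X)
  colnames(dat)[-(1:2)] <- covariates
  flags <- character()
  fit <- withCallingHandlers(
    survival::coxph(
      stats::as.formula(paste("survival::Surv(time, event) ~",
                              paste(sprintf("`%s`", covariates), collapse = "+"))),
      data = dat, ties = "breslow",
      control = survival::coxph.control(eps = 1e-10, iter.max = 100)),
    warning = function(w) {
      flags <<- c(flags, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  co <- sm$coefficients
  tab <- data.frame(
    covariate = covariates,
    coef = co[, "coef"],
    se = co[, "se(coef)"],
    hr = exp(co[, "coef"]),
    ci_low = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
    ci_high = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
    p_value = co[, "Pr(>|z|)"],
    scale = scale_used,
    row.names = NULL
  )
  structure(list(table = tab, loglik = fit$loglik[2], iter = fit$iter,
                 flags = flags, scaling = scaling, fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit (Breslow ties, %s scaling), loglik = %.3f, %d iter\n",
              x$scaling, x$loglik, x$iter))
  print(forest_table(x), row.names = FALSE)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Hazard-ratio table ordered for a forest plot
#'
#' @param fit a [cox_fit()].
#' @return data frame with the fit's covariates sorted by hazard ratio,
#'   descending: `covariate`, `hr`, `ci_low`, `ci_high`, `p_value`.
#' @export
forest_table <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  tab <- fit$table[order(-fit$table$hr),
                   c("covariate", "hr", "ci_low", "ci_high", "p_value")]
  rownames(tab) <- NULL
  tab
}

.check_surv <- function(records) {
  if (!all(c("time_months", "event") %in% names(records)))
    .stopf("survival records need 'time_months' and 'event' columns")
  if (any(records$time_months <= 0)) .stopf("all times must be > 0")
  if (!all(records$event %in% c(0, 1))) .stopf("event must be 0/1")
  invisible(records)
}
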