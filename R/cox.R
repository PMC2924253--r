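# Core Newton fit of the Cox partial likelihood via survival's workhorse.
# xmat: numeric model matrix (samples x terms), first column the predictor.
# Returns predictor coef, se (observed information), z, two-sided normal p.
cox_fit_core <- function(xmat, time, event, ties_method = "efron",
                         iter_max = 50, eps = 1e-9) {
  y <- survival::Surv(time, event)
  ctrl <- survival::coxph.control(iter.max = iter_max, eps = eps)
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph.fit(xmat, y, strata = NULL, offset = NULL, init = NULL,
                        control = ctrl, weights = NULL,
                        method = ties_method, rownames = NULL),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- fit$coefficients[1L]
  se <- sqrt(fit$var[1L, 1L])
  converged <- !warned && is.finite(co) && is.finite(se) &&
    fit$iter < iter_max
  list(coef = unname(co), se = unname(se), iter = fit$iter,
       converged = converged)
}

#' Fit a multivariate Cox model for a single methylation predictor
#'
#' Maximises the Cox partial likelihood (Efron tie handling by default,
#' Breslow selectable) over the methylation predictor jointly with all
#' covariates, and reports Wald inference for the predictor: coefficient
#' (log hazard ratio), standard error from the observed information,
#' z = coef/se and the two-sided normal p-value. Samples with a missing
#' predictor value are dropped (`n_used` records the remainder). A constant
#' predictor yields the degenerate row coef 0, se Inf, p 1.
#'
#' @param predictor Numeric per-sample methylation values (NAs allowed).
#' @param time,event Survival encoding: positive times, event 1 =
#'   nephropathy onset observed, 0 = censored.
#' @param covariates Optional data frame of per-sample covariates
#'   (factors dummy-coded; constant columns dropped with a warning).
#' @param ties_method `"efron"` (default) or `"breslow"`.
#' @param probe_id Optional identifier carried into the output row.
#' @return One-row `data.frame`: `probe_id`, `coef`, `hazard_ratio`, `se`,
#'   `z`, `p`, `n_used`, `converged`, `degenerate`.
#' @export
fit_cox_single <- function(predictor, time, event, covariates = NULL,
                           ties_method = c("efron", "breslow"),
                           probe_id = NA_character_) {
  ties_method <- match.arg(ties_method)
  X <- if (is.null(covariates)) NULL else covariate_matrix(covariates)
  keep <- !is.na(predictor)
  if (!is.null(X)) keep <- keep & complete.cases(X)
  predictor <- predictor[keep]; time <- time[keep]; event <- event[keep]
  if (!is.null(X)) X <- X[keep, , drop = FALSE]
  if (sum(event) == 0) stop("no events in the data; Cox fit impossible")
  n_used <- length(predictor)
  if (n_used < 2 || var(predictor) == 0 || !is.finite(var(predictor))) {
    return(cox_row(probe_id, coef = 0, se = Inf, n_used = n_used,
                   converged = TRUE, degenerate = TRUE))
  }
  xmat <- cbind(predictor = predictor, X)
  fit <- cox_fit_core(xmat, time, event, ties_method)
  cox_row(probe_id, coef = fit$coef, se = fit$se, n_used = n_used,
          converged = fit$converged, degenerate = FALSE)
}

cox_row <- function(probe_id, coef, se, n_used, converged, degenerate) {
  z <- if (is.infinite(se)) 0 else coef / se
  p <- if (is.infinite(se)) 1 else 2 * pnorm(-abs(z))
  data.frame(probe_id = probe_id, coef = coef, hazard_ratio = exp(coef),
             se = se, z = z, p = max(p, .Machine$double.xmin),
             n_used = n_used, converged = converged,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

# Dummy-code a covariate data frame into a numeric matrix (no intercept
# column); constant columns are dropped with a warning.
covariate_matrix <- function(covariates) {
  covariates <- as.data.frame(covariates)
  for (j in seq_along(covariates))
    if (is.character(covariates[[j]]) || is.logical(covariates[[j]]))
      covariates[[j]] <- factor(covariates[[j]])
  covariates <- droplevels(covariates)
  const <- vapply(covariates, function(v) {
    if (is.factor(v)) nlevels(v) < 2 else var(as.numeric(v), na.rm = TRUE) == 0
  }, logical(1))
  if (any(const)) {
    warning("dropping constant covariate(s): ",
            paste(names(covariates)[const], collapse = ", "))
    covariates <- covariates[!const]
  }
  if (ncol(covariates) == 0) return(NULL)
  X <- stats::model.matrix(~ ., data = covariates)
  X[, -1L, drop = FALSE]
}
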