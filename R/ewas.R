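#' Genome-wide per-CpG Cox proportional-hazards scan
#'
#' The central estimator of the package: fits, for every CpG, a
#' multivariate Cox regression of time-to-nephropathy on that CpG's
#' methylation jointly with the technical and phenotype covariates
#' (by default chip, the two bisulphite-conversion metrics, sex, cohort
#' and age at sample draw), and controls the false discovery rate with
#' Storey q-values. The per-CpG predictor is standardised to zero mean and
#' unit variance by default, so coefficients are log hazard ratios per SD
#' of methylation; raw-beta scaling is selectable.
#'
#' @param beta QC'd, normalised (and usually mean-profile-adjusted) matrix:
#'   an `adjusted_beta`, a [beta_matrix()] or a plain probes x samples
#'   matrix.
#' @param samples Sample table (see [read_sample_sheet()]); matched to the
#'   matrix columns by `sample_id`.
#' @param covariates Character vector of sample-table columns to adjust
#'   for; `NULL` for an unadjusted scan. Constant columns are dropped with
#'   a warning.
#' @param ties_method `"efron"` (default) or `"breslow"`.
#' @param predictor_scaling `"zscore"` (default: per-CpG standardisation)
#'   or `"raw"`.
#' @param pi0_method Passed to [estimate_qvalues()].
#' @return An object of class `ewas_scan`: list with `table` (one row per
#'   probe, in input probe order, columns `probe_id`, `coef`,
#'   `hazard_ratio`, `se`, `z`, `p`, `q`, `n_used`, `converged`,
#'   `degenerate`), `pi0`, and the configuration used. Methods: `print`,
#'   `summary`, `coef`, `plot`, `as.data.frame`.
#' @seealso [fit_cox_single()], [estimate_qvalues()], [count_directional()]
#' @export
run_ewas <- function(beta, samples,
                     covariates = c("chip", "bsce_c1", "bsce_c2", "sex",
                                    "cohort", "age_at_draw"),
                     ties_method = c("efron", "breslow"),
                     predictor_scaling = c("zscore", "raw"),
                     pi0_method = c("smoother", "fixed_1")) {
  ties_method <- match.arg(ties_method)
  predictor_scaling <- match.arg(predictor_scaling)
  pi0_method <- match.arg(pi0_method)
  x <- adjusted_values(beta)
  sid <- colnames(x)
  if (!is.null(sid) && all(sid %in% samples$sample_id))
    samples <- samples[match(sid, samples$sample_id), , drop = FALSE]
  else if (ncol(x) != nrow(samples))
    stop("beta matrix columns and sample table do not align")
  if (sum(samples$event) == 0) stop("no events among the samples")

  X <- if (length(covariates) > 0)
    covariate_matrix(samples[covariates]) else NULL
  time <- samples$time_to_event
  event <- samples$event

  rows <- vector("list", nrow(x))
  for (i in seq_len(nrow(x))) {
    v <- x[i, ]
    keep <- !is.na(v)
    n_used <- sum(keep)
    sdv <- if (n_used > 1) sd(v[keep]) else 0
    if (n_used < 2 || sdv == 0) {
      rows[[i]] <- cox_row(rownames(x)[i], 0, Inf, n_used,
                           converged = TRUE, degenerate = TRUE)
      next
    }
    pred <- if (predictor_scaling == "zscore")
      (v[keep] - mean(v[keep])) / sdv else v[keep]
    xmat <- cbind(predictor = pred,
                  if (!is.null(X)) X[keep, , drop = FALSE])
    fit <- cox_fit_core(xmat, time[keep], event[keep], ties_method)
    rows[[i]] <- cox_row(rownames(x)[i], fit$coef, fit$se, n_used,
                         fit$converged, degenerate = FALSE)
  }
  tab <- do.call(rbind, rows)
  qv <- estimate_qvalues(tab$p, pi0_method = pi0_method)
  tab$q <- qv$q
  tab <- tab[c("probe_id", "coef", "hazard_ratio", "se", "z", "p", "q",
               "n_used", "converged", "degenerate")]
  structure(list(table = tab, pi0 = qv$pi0,
                 covariates = if (is.null(X)) character(0) else colnames(X),
                 ties_method = ties_method,
                 predictor_scaling = predictor_scaling,
                 pi0_method = pi0_method,
                 n_samples = ncol(x)),
            class = "ewas_scan")
}

#' @export
as.data.frame.ewas_scan <- function(x, ...) x$table

#' @export
print.ewas_scan <- function(x, ...) {
  cat(sprintf("ewas_scan: %d CpGs x %d samples (Cox, %s ties, %s predictor)\n",
              nrow(x$table), x$n_samples, x$ties_method,
              x$predictor_scaling))
  cat(sprintf("  pi0 estimate: %.3f\n", x$pi0))
  top <- x$table[order(x$table$p), ][seq_len(min(5L, nrow(x$table))), ]
  cat("  top hits:\n")
  print(top[c("probe_id", "coef", "hazard_ratio", "se", "z", "p", "q")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.ewas_scan <- function(object, fdr_thresholds = c(0.05, 0.15), ...) {
  hits <- lapply(fdr_thresholds, function(th)
    count_directional(object, th))
  names(hits) <- paste0("q<", fdr_thresholds)
  out <- list(n_probes = nrow(object$table),
              n_samples = object$n_samples,
              pi0 = object$pi0,
              hits = hits)
  class(out) <- "summary.ewas_scan"
  out
}

#' @export
print.summary.ewas_scan <- function(x, ...) {
  cat(sprintf("EWAS of %d CpGs on %d samples; pi0 = %.3f\n",
              x$n_probes, x$n_samples, x$pi0))
  for (nm in names(x$hits))
    cat(sprintf("  %s: %d increased risk, %d decreased risk\n",
                nm, x$hits[[nm]]["increased"], x$hits[[nm]]["decreased"]))
  invisible(x)
}

#' @export
coef.ewas_scan <- function(object, ...) {
  setNames(object$table$coef, object$table$probe_id)
}

#' Histogram of EWAS p-values
#'
#' Under the global null this histogram is flat; an excess of p-values near
#' zero indicates CpGs associated with time to event.
#'
#' @param x An `ewas_scan`.
#' @param breaks Passed to [hist()].
#' @param ... Further arguments to [hist()].
#' @export
plot.ewas_scan <- function(x, breaks = seq(0, 1, 0.05), ...) {
  h <- hist(x$table$p, breaks = breaks, main = "EWAS p-values",
            xlab = "p", ...)
  abline(h = nrow(x$table) / (length(breaks) - 1), lty = 2)
  invisible(h)
}

#' Storey q-values
#'
#' Computes q-values from p-values:
#' \eqn{q_{(i)} = \hat\pi_0 \min_{j \ge i} m p_{(j)} / j} on the sorted
#' p-values, with the null proportion \eqn{\hat\pi_0} estimated by Storey's
#' smoother: \eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\}/(m(1-\lambda))}
#' over \eqn{\lambda = 0, 0.05, \ldots, 0.90}, smoothed with a cubic
#' spline and evaluated at the largest \eqn{\lambda}, clipped to (0, 1].
#' With `pi0_method = "fixed_1"` the estimate is forced to 1, which makes
#' the q-values identical to Benjamini-Hochberg adjusted p-values. Fewer
#' than 20 p-values triggers an automatic fallback to \eqn{\pi_0 = 1}
#' (with a message) since the smoother is unstable there.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param pi0_method `"smoother"` (default) or `"fixed_1"`.
#' @return List with `q` (same order as `p`) and `pi0`.
#' @export
estimate_qvalues <- function(p, pi0_method = c("smoother", "fixed_1")) {
  pi0_method <- match.arg(pi0_method)
  m <- length(p)
  if (m == 0) stop("empty p-value vector")
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  pi0 <- 1
  if (pi0_method == "smoother") {
    if (m < 20) {
      message("fewer than 20 p-values; falling back to pi0 = 1")
    } else {
      lambda <- seq(0, 0.90, 0.05)
      pi0_lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l),
                           numeric(1))
      fit <- smooth.spline(lambda, pi0_lambda, df = 3)
      pi0 <- predict(fit, x = max(lambda))$y
      pi0 <- min(max(pi0, .Machine$double.eps), 1)
    }
  }
  o <- order(p)
  ro <- order(o)
  q_sorted <- pi0 * pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  list(q = q_sorted[ro], pi0 = pi0)
}

#' Count directional hits at an FDR threshold
#'
#' Splits the CpGs called at `q < fdr_threshold` by the sign of their
#' coefficient: a positive log hazard ratio means higher methylation
#' confers increased risk of (earlier) nephropathy, a negative one
#' decreased risk.
#'
#' @param ewas An `ewas_scan` (or its table) with q-values filled.
#' @param fdr_threshold FDR level (e.g. 0.05 or 0.15).
#' @return Named integer vector `c(increased = , decreased = )`.
#' @export
count_directional <- function(ewas, fdr_threshold) {
  tab <- as.data.frame(ewas)
  hit <- tab$q < fdr_threshold
  c(increased = sum(hit & tab$coef > 0),
    decreased = sum(hit & tab$coef < 0))
}

#' Combine and test proximal CpG pairs
#'
#' Enumerates same-chromosome probe pairs at most `max_dist` bp apart
#' (default 1 kb, inclusive) and tests each pair for co-directional
#' association with time to event. The default combination takes the
#' per-sample mean of the two standardised probe vectors as the pair's
#' methylation score and fits the same multivariate Cox model as
#' [run_ewas()]; `combine = "stouffer"` instead combines the two single-CpG
#' Wald z-scores as \eqn{(z_a + z_b)/\sqrt{2}}.
#'
#' @inheritParams run_ewas
#' @param manifest Probe manifest (see [read_probe_manifest()]); probes
#'   missing from it are excluded with a warning.
#' @param max_dist Maximum pair distance in bp (default 1000).
#' @param combine `"mean"` (default) or `"stouffer"`.
#' @return An object of class `ewas_pairs`: data frame with
#'   `probe_id_a`, `probe_id_b`, `chromosome`, `distance` and the Cox
#'   columns, plus attributes `pi0` and `combine`.
#' @export
combine_proximal_pairs <- function(beta, manifest, samples,
                                   max_dist = 1000,
                                   covariates = c("chip", "bsce_c1",
                                                  "bsce_c2", "sex",
                                                  "cohort", "age_at_draw"),
                                   ties_method = c("efron", "breslow"),
                                   combine = c("mean", "stouffer"),
                                   pi0_method = c("smoother", "fixed_1")) {
  ties_method <- match.arg(ties_method)
  combine <- match.arg(combine)
  pi0_method <- match.arg(pi0_method)
  x <- adjusted_values(beta)
  ids <- rownames(x)
  absent <- setdiff(ids, manifest$probe_id)
  if (length(absent) > 0) {
    warning(length(absent), " probe(s) absent from manifest excluded, e.g. ",
            absent[1L])
    ids <- setdiff(ids, absent)
  }
  man <- manifest[match(ids, manifest$probe_id), ]
  pairs <- enumerate_pairs(man, max_dist)
  if (nrow(pairs) == 0) {
    out <- data.frame(probe_id_a = character(0), probe_id_b = character(0),
                      chromosome = character(0), distance = integer(0))
    return(structure(out, class = c("ewas_pairs", "data.frame"),
                     pi0 = 1, combine = combine))
  }
  sid <- colnames(x)
  if (!is.null(sid) && all(sid %in% samples$sample_id))
    samples <- samples[match(sid, samples$sample_id), , drop = FALSE]
  z <- t(apply(x[ids, , drop = FALSE], 1L, function(v) {
    s <- sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) rep(NA_real_, length(v))
    else (v - mean(v, na.rm = TRUE)) / s
  }))
  rownames(z) <- ids

  if (combine == "mean") {
    X <- if (length(covariates) > 0)
      covariate_matrix(samples[covariates]) else NULL
    rows <- lapply(seq_len(nrow(pairs)), function(k) {
      comb <- (z[pairs$probe_id_a[k], ] + z[pairs$probe_id_b[k], ]) / 2
      keep <- !is.na(comb)
      if (sum(keep) < 2 || sd(comb[keep]) == 0)
        return(cox_row(NA_character_, 0, Inf, sum(keep), TRUE, TRUE))
      xmat <- cbind(predictor = comb[keep],
                    if (!is.null(X)) X[keep, , drop = FALSE])
      fit <- cox_fit_core(xmat, samples$time_to_event[keep],
                          samples$event[keep], ties_method)
      cox_row(NA_character_, fit$coef, fit$se, sum(keep), fit$converged,
              FALSE)
    })
    stats_tab <- do.call(rbind, rows)[-1L]
  } else {
    single <- run_ewas(x[ids, , drop = FALSE], samples,
                       covariates = covariates, ties_method = ties_method,
                       pi0_method = pi0_method)$table
    za <- single$z[match(pairs$probe_id_a, single$probe_id)]
    zb <- single$z[match(pairs$probe_id_b, single$probe_id)]
    zc <- (za + zb) / sqrt(2)
    stats_tab <- data.frame(coef = NA_real_, hazard_ratio = NA_real_,
                            se = NA_real_, z = zc,
                            p = pmax(2 * pnorm(-abs(zc)),
                                     .Machine$double.xmin),
                            n_used = single$n_used[
                              match(pairs$probe_id_a, single$probe_id)],
                            converged = TRUE, degenerate = FALSE)
  }
  qv <- estimate_qvalues(stats_tab$p, pi0_method = pi0_method)
  out <- cbind(pairs, stats_tab)
  out$q <- qv$q
  structure(out, class = c("ewas_pairs", "data.frame"),
            pi0 = qv$pi0, combine = combine)
}

# same-chromosome pairs with |position difference| <= max_dist
enumerate_pairs <- function(man, max_dist) {
  res <- list()
  for (chr in unique(man$chromosome)) {
    sub <- man[man$chromosome == chr, ]
    sub <- sub[order(sub$position), ]
    n <- nrow(sub)
    if (n < 2) next
    for (i in seq_len(n - 1L)) {
      j <- i + 1L
      while (j <= n && sub$position[j] - sub$position[i] <= max_dist) {
        res[[length(res) + 1L]] <- data.frame(
          probe_id_a = sub$probe_id[i], probe_id_b = sub$probe_id[j],
          chromosome = chr,
          distance = sub$position[j] - sub$position[i],
          stringsAsFactors = FALSE)
        j <- j + 1L
      }
    }
  }
  if (length(res) == 0)
    data.frame(probe_id_a = character(0), probe_id_b = character(0),
               chromosome = character(0), distance = integer(0))
  else do.call(rbind, res)
}
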