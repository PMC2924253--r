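#' Singular value decomposition of the adjusted beta matrix
#'
#' Decomposes the mean-profile-adjusted matrix and reports, for the leading
#' `n_components` components, the singular values, the variance fractions
#' \eqn{f_k = \sigma_k^2 / \sum_j \sigma_j^2} (computed over the full
#' spectrum), and the per-sample component scores
#' \eqn{\sigma_k v_k} (right singular vectors scaled by their singular
#' value).
#'
#' @param adjusted An [adjust_top_component()] result (or numeric matrix,
#'   probes x samples).
#' @param n_components Number of leading components to keep; default
#'   `min(dim) - 1`.
#' @return An object of class `svd_screen` with `singular_values`,
#'   `variance_fractions` (full spectrum), `sample_scores`
#'   (components x samples), `n_components_evaluated` and an (initially
#'   empty) `significant_components` set.
#' @export
svd_decompose <- function(adjusted, n_components = NULL) {
  x <- adjusted_values(adjusted)
  kmax <- min(dim(x))
  if (is.null(n_components)) n_components <- kmax - 1L
  if (n_components < 1 || n_components > kmax)
    stop("n_components must be in 1..", kmax)
  s <- svd(x)
  frac <- s$d^2 / sum(s$d^2)
  scores <- t(s$v[, seq_len(n_components), drop = FALSE]) *
    s$d[seq_len(n_components)]
  colnames(scores) <- colnames(x)
  rownames(scores) <- paste0("PC", seq_len(n_components))
  structure(list(singular_values = s$d,
                 variance_fractions = frac,
                 sample_scores = scores,
                 n_components_evaluated = as.integer(n_components),
                 significant_components = integer(0)),
            class = "svd_screen")
}

#' @export
print.svd_screen <- function(x, ...) {
  k <- min(5L, x$n_components_evaluated)
  cat(sprintf("svd_screen: %d components evaluated\n",
              x$n_components_evaluated))
  cat(sprintf("  leading variance fractions: %s\n",
              paste(sprintf("%.4f", x$variance_fractions[seq_len(k)]),
                    collapse = " ")))
  if (length(x$significant_components) > 0)
    cat("  significant components: ",
        paste(x$significant_components, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Permutation null spectrum for singular values
#'
#' Builds the null distribution of SVD variance fractions by randomising
#' the adjusted matrix: in each replicate every sample's (column's) entries
#' are independently permuted across probes, with a distinct permutation
#' per sample, destroying inter-sample covariance while preserving each
#' sample's marginal distribution. The null spectrum is very tight because
#' null singular values are a global property of the randomised data.
#'
#' Each permuted replicate is processed exactly like the observed data:
#' its own leading component is removed before variance fractions are
#' computed (equivalently, its top singular value is dropped and the
#' fractions renormalised — the same spectrum, by the Eckart-Young
#' theorem). Permuting restores a chance top component that the observed,
#' already-adjusted matrix cannot have; without this step the observed
#' fractions would be inflated by ~n/(n-1) relative to the null and pure
#' noise would be called significant.
#'
#' @param adjusted An [adjust_top_component()] result or matrix.
#' @param n_permutations Number of randomisation replicates (default 10).
#' @param seed Integer seed; all replicate permutations derive from it.
#' @return An object of class `null_spectrum` with `null_fractions`
#'   (replicates x components), `n_permutations` and `seed`.
#' @export
permutation_null <- function(adjusted, n_permutations = 10, seed = 1) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  x <- adjusted_values(adjusted)
  p <- nrow(x)
  nf <- local_seed(seed, {
    t(vapply(seq_len(n_permutations), function(b) {
      xp <- apply(x, 2L, function(col) col[sample.int(p)])
      d <- svd(xp, nu = 0, nv = 0)$d[-1L]  # adjust the replicate too
      d^2 / sum(d^2)
    }, numeric(min(dim(x)) - 1L)))
  })
  structure(list(null_fractions = nf,
                 n_permutations = as.integer(n_permutations),
                 seed = seed),
            class = "null_spectrum")
}

#' Select components larger than the permutation null
#'
#' A component is called significant iff its observed variance fraction
#' exceeds the largest null variance fraction seen at that rank across all
#' randomisation replicates (a conservative reading of "larger than
#' expected under the null"; the null spectrum is tight, so the maximum is
#' close to the mean).
#'
#' @param result An [svd_decompose()] result.
#' @param null A [permutation_null()] result computed from the same matrix.
#' @return The `svd_screen` object with `significant_components` filled.
#' @export
select_significant_components <- function(result, null) {
  k <- result$n_components_evaluated
  if (ncol(null$null_fractions) < k)
    stop("null spectrum has fewer components than the observed screen")
  null_max <- apply(null$null_fractions[, seq_len(k), drop = FALSE], 2L, max)
  obs <- result$variance_fractions[seq_len(k)]
  result$significant_components <- which(obs > null_max)
  result
}

#' Associate components with phenotypes and technical factors
#'
#' For every evaluated (or significant) component, tests the per-sample
#' component scores against each declared factor: continuous (and ordinal)
#' factors by the slope test of a linear regression, categorical factors by
#' a Kruskal-Wallis test, and the survival outcome by the Wald test of the
#' score as sole covariate in a Cox proportional-hazards model on
#' (time_to_event, event). P-values are binned at the conventional
#' screening thresholds 1e-10, 1e-5, 1e-2 and 0.05.
#'
#' @param result An [svd_decompose()] result.
#' @param samples Sample table aligned (by `sample_id`) with the score
#'   columns.
#' @param factor_spec Named character vector mapping a factor name to
#'   `"continuous"`, `"categorical"` or `"survival"`. Continuous and
#'   categorical names must be sample-table columns; a survival factor uses
#'   the `time_to_event`/`event` columns. Default: the study screen
#'   (BSCE metrics, age at draw, age at diagnosis, T1D duration continuous;
#'   sex, cohort, chip, batch categorical; time-to-nephropathy survival).
#' @param components Which components to test; default all evaluated.
#' @return An object of class `component_assoc` with matrices `p_values`
#'   and `bins` (components x factors). A categorical factor with a single
#'   level yields `NA` in that cell with a warning, not an error.
#' @export
associate_components <- function(result, samples,
                                 factor_spec = default_factor_spec(),
                                 components = NULL) {
  scores <- result$sample_scores
  sid <- colnames(scores)
  if (!is.null(sid) && all(sid %in% samples$sample_id))
    samples <- samples[match(sid, samples$sample_id), , drop = FALSE]
  else if (ncol(scores) != nrow(samples))
    stop("sample scores and sample table do not align")
  if (is.null(components)) components <- seq_len(nrow(scores))

  types <- unlist(factor_spec)
  bad <- setdiff(types, c("continuous", "categorical", "survival"))
  if (length(bad) > 0) stop("unknown factor type: ", bad[1L])

  pmat <- matrix(NA_real_, length(components), length(types),
                 dimnames = list(rownames(scores)[components], names(types)))
  for (f in names(types)) {
    type <- types[[f]]
    if (type == "categorical" && nlevels(factor(samples[[f]])) < 2) {
      warning("factor '", f, "' has a single level; p set to NA")
      next
    }
    for (i in seq_along(components)) {
      s <- scores[components[i], ]
      pmat[i, f] <- switch(
        type,
        continuous = {
          x <- samples[[f]]
          summary(lm(s ~ x))$coefficients["x", "Pr(>|t|)"]
        },
        categorical = kruskal.test(s, factor(samples[[f]]))$p.value,
        survival = {
          fit <- coxph(Surv(samples$time_to_event, samples$event) ~ s)
          summary(fit)$coefficients["s", "Pr(>|z|)"]
        }
      )
    }
  }
  structure(list(p_values = pmat,
                 bins = bin_pvalues(pmat),
                 factor_types = types),
            class = "component_assoc")
}

#' @rdname associate_components
#' @export
default_factor_spec <- function() {
  c(bsce_c1 = "continuous", bsce_c2 = "continuous", sex = "categorical",
    cohort = "categorical", chip = "categorical", batch = "categorical",
    age_at_draw = "continuous", duration_t1d = "continuous",
    age_at_diagnosis = "continuous", cc = "survival")
}

ASSOC_THRESHOLDS <- c(1e-10, 1e-5, 1e-2, 0.05)
ASSOC_BIN_LABELS <- c("p<1e-10", "p<1e-5", "p<0.01", "p<0.05", "ns")

bin_pvalues <- function(p) {
  b <- matrix(ASSOC_BIN_LABELS[
    findInterval(p, ASSOC_THRESHOLDS, left.open = FALSE) + 1L],
    nrow(p), ncol(p), dimnames = dimnames(p))
  b[is.na(p)] <- NA_character_
  b
}

#' @export
print.component_assoc <- function(x, ...) {
  cat("component x factor association screen (bins):\n")
  print(as.data.frame(x$bins))
  invisible(x)
}
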