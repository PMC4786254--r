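#' Permutation estimate of the chance classification level
#'
#' Re-runs the full cross-validated pipeline on label-permuted copies of
#' the data and summarizes the resulting null accuracy distribution. The
#' reported bound is the 97.5th percentile (the upper limit of a two-sided
#' 95 percent confidence interval); set `one_sided = TRUE` for the 95th
#' percentile convention instead.
#'
#' @param fm a `feature_matrix`
#' @param config an [svm_config()]; keep `n_repeats` small here, every
#'   permutation re-runs the whole nested CV
#' @param n_perm number of label permutations (>= 20; >= 200 recommended)
#' @param seed seed controlling both the permutations and the CV partitions
#' @param sfs run forward selection inside each permutation (as in the
#'   observed pipeline, if it used SFS)
#' @param one_sided use the one-sided 95th-percentile convention
#' @return object of class `chance_estimate`: `point` (1/number of
#'   classes), `upper95`, `mean`, `accuracies`, `n_perm`, `n_trials`
#' @export
permutation_chance <- function(fm, config = svm_config(), n_perm = 200,
                               seed = 1, sfs = FALSE, one_sided = FALSE) {
  if (n_perm < 20) stop("n_perm must be at least 20")
  y <- droplevels(factor(fm$y))
  accs <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    set.seed(seed * 100003L + i)
    fm_i <- fm
    fm_i$y <- sample(y)
    cfg_i <- config
    cfg_i$seed <- seed * 1000L + i
    accs[i] <- nested_cv_svm(fm_i, cfg_i, sfs = sfs)$mean_accuracy
  }
  structure(list(point = 1 / nlevels(y),
                 upper95 = unname(stats::quantile(accs,
                                                  if (one_sided) 0.95
                                                  else 0.975)),
                 mean = mean(accs),
                 accuracies = accs,
                 n_perm = n_perm,
                 n_trials = length(y)),
            class = "chance_estimate")
}

#' @export
print.chance_estimate <- function(x, ...) {
  cat(sprintf(
    "<chance_estimate> point %.3f, permutation mean %.3f, upper 95%% bound %.3f (%d permutations, %d trials)\n",
    x$point, x$mean, x$upper95, x$n_perm, x$n_trials))
  invisible(x)
}

#' Exact binomial test for above-chance accuracy
#'
#' One-sided upper tail `P(X >= k)` for `k` correct classifications out of
#' `n` trials under a chance probability `chance_p` (0.5 for two states,
#' 1/3 for three).
#'
#' @param k_correct correct classifications
#' @param n trials
#' @param chance_p chance probability, in (0, 1)
#' @return p-value
#' @export
binomial_above_chance <- function(k_correct, n, chance_p) {
  stopifnot(k_correct >= 0, k_correct <= n, n >= 1,
            chance_p > 0, chance_p < 1)
  stats::pbinom(k_correct - 1, n, chance_p, lower.tail = FALSE)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure at level `q`: adjusted p-values are
#' `min_{j >= i} m * p_(j) / j` capped at 1, and hypotheses with adjusted
#' p <= q are rejected.
#'
#' @param pvalues vector of p-values in `[0, 1]`
#' @param q FDR level
#' @return data.frame with `p`, `p_adjusted`, `reject`
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0)
    return(data.frame(p = numeric(0), p_adjusted = numeric(0),
                      reject = logical(0)))
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  adj <- stats::p.adjust(pvalues, method = "BH")
  data.frame(p = pvalues, p_adjusted = adj,
             reject = !is.na(adj) & adj <= q)
}

#' Significance annotation for classification results
#'
#' Applies the exact binomial test against a chance reference and BH-FDR
#' correction to a set of accuracies measured on `n` trials each. Three-state
#' results are conventionally tested against both 1/3 (chance) and the
#' stricter 1/2 reference.
#'
#' @param accuracies vector of mean accuracies
#' @param n_trials trials behind each accuracy (scalar or vector); the
#'   number of unique trials, not trials times CV repeats
#' @param chance_p chance probability
#' @param q FDR level
#' @return data.frame with `accuracy`, `n`, `k`, `chance_ref`,
#'   `p_binomial`, `p_adjusted`, `reject_fdr`
#' @export
classification_significance <- function(accuracies, n_trials,
                                        chance_p = 0.5, q = 0.05) {
  n <- rep_len(n_trials, length(accuracies))
  k <- round(accuracies * n)
  p <- mapply(binomial_above_chance, k, n, MoreArgs = list(chance_p))
  fdr <- bh_fdr(p, q)
  data.frame(accuracy = accuracies, n = n, k = k, chance_ref = chance_p,
             p_binomial = p, p_adjusted = fdr$p_adjusted,
             reject_fdr = fdr$reject)
}
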