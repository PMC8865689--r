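#' Ordinary least squares on an explicit design matrix
#'
#' Thin, strict wrapper around R's QR least-squares solver that returns the
#' pieces the decay and fitness analyses need: coefficients, their scaled
#' covariance, residual degrees of freedom and residual sum of squares.
#' Rank-deficient designs are an error (naming the aliased columns) rather
#' than being silently pivoted away.
#'
#' @param design Numeric matrix, one column per coefficient, with column
#'   names.
#' @param response Numeric vector, `length(response) == nrow(design)`.
#' @return An object of class `ols_fit`: list with `coefficients`,
#'   `cov_matrix` (sigma^2 (X'X)^-1; zero matrix for a saturated fit),
#'   `cov_unscaled`, `residual_df`, `residual_ss`, `fitted`, `residuals`,
#'   `n`.
#' @export
fit_ols <- function(design, response) {
  design <- as.matrix(design)
  if (is.null(colnames(design))) {
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  }
  if (!all(is.finite(response))) {
    abort("response contains non-finite values",
          class = "phagestress_domain_error")
  }
  if (nrow(design) < ncol(design)) {
    abort("fewer rows than coefficients", class = "phagestress_domain_error")
  }
  qr_x <- qr(design)
  if (qr_x$rank < ncol(design)) {
    aliased <- colnames(design)[qr_x$pivot[(qr_x$rank + 1):ncol(design)]]
    abort(paste0("design is rank deficient; aliased column(s): ",
                 paste(aliased, collapse = ", ")),
          class = "phagestress_domain_error")
  }
  beta <- qr.coef(qr_x, response)
  fitted <- drop(design %*% beta)
  res <- response - fitted
  rss <- sum(res^2)
  rdf <- nrow(design) - ncol(design)
  xtx_inv <- chol2inv(qr.R(qr_x))
  dimnames(xtx_inv) <- list(colnames(design), colnames(design))
  sigma2 <- if (rdf > 0) rss / rdf else 0
  structure(
    list(coefficients = setNames(as.numeric(beta), colnames(design)),
         cov_matrix = sigma2 * xtx_inv,
         cov_unscaled = xtx_inv,
         residual_df = rdf,
         residual_ss = rss,
         fitted = fitted,
         residuals = res,
         n = nrow(design)),
    class = "ols_fit"
  )
}

#' Sequential (Type I) ANOVA from a nested sequence of fits
#'
#' Each term's sum of squares is the drop in residual sum of squares when
#' it enters the model, in the order given; F statistics use the final
#' model's residual mean square. This is the classical sequential
#' decomposition, so term order matters and is part of the analysis
#' definition.
#'
#' @param fits List of [fit_ols()] objects, strictly nested, from the
#'   baseline model (usually intercept-only) to the full model.
#' @param terms Character vector naming the term added at each step
#'   (`length(fits) - 1` entries).
#' @return Tibble with rows per term plus a `Residuals` row: `term`, `df`,
#'   `sumsq`, `meansq`, `statistic`, `p.value`.
#' @export
sequential_anova <- function(fits, terms) {
  if (length(fits) < 2) {
    abort("need a baseline fit and at least one term",
          class = "phagestress_domain_error")
  }
  if (length(terms) != length(fits) - 1) {
    abort("terms must name each step after the baseline",
          class = "phagestress_domain_error")
  }
  rss <- vapply(fits, function(f) f$residual_ss, numeric(1))
  rdf <- vapply(fits, function(f) f$residual_df, numeric(1))
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1) {
    abort("fits are on different data (row counts differ); not nested",
          class = "phagestress_domain_error")
  }
  if (any(diff(rdf) >= 0) || any(diff(rss) > 1e-8 * max(rss[1], 1))) {
    abort("fit sequence is not strictly nested",
          class = "phagestress_domain_error")
  }
  full <- fits[[length(fits)]]
  if (full$residual_df == 0) {
    abort("saturated full model: no residual degrees of freedom",
          class = "phagestress_domain_error")
  }
  ms_resid <- full$residual_ss / full$residual_df
  ss <- -diff(rss)
  term_df <- -diff(rdf)
  fstat <- (ss / term_df) / ms_resid
  pvals <- stats::pf(fstat, term_df, full$residual_df, lower.tail = FALSE)
  tibble::tibble(
    term = c(terms, "Residuals"),
    df = as.integer(c(term_df, full$residual_df)),
    sumsq = c(ss, full$residual_ss),
    meansq = c(ss / term_df, ms_resid),
    statistic = c(fstat, NA_real_),
    p.value = c(pvals, NA_real_)
  )
}

#' Tukey (Tukey-Kramer) honest significant differences
#'
#' All-pairs comparisons of group means using the studentized range
#' distribution, with the Tukey-Kramer standard error for unbalanced
#' groups: `q = |m_a - m_b| / sqrt(mse/2 * (1/n_a + 1/n_b))`, adjusted
#' p from the range distribution with `k` groups and `df_resid` error df.
#'
#' @param group_means Named numeric vector of group means.
#' @param group_ns Named integer vector of group sizes (same names).
#' @param mse Residual mean square of the model the groups came from.
#' @param df_resid Residual degrees of freedom of that model.
#' @param alpha Family-wise significance level for the `significant` flag.
#' @return Tibble: `level_a`, `level_b`, `diff` (a minus b), `se`,
#'   `q_stat`, `p_adj`, `significant`.
#' @seealso [compact_letters()] for the letter display.
#' @export
tukey_hsd <- function(group_means, group_ns, mse, df_resid, alpha = 0.05) {
  k <- length(group_means)
  if (k < 2) {
    abort("need at least two groups", class = "phagestress_domain_error")
  }
  if (!is.finite(mse) || mse <= 0) {
    abort("mse must be positive (zero residual variance makes the test undefined)",
          class = "phagestress_domain_error")
  }
  if (is.null(names(group_means)) ||
      !identical(sort(names(group_means)), sort(names(group_ns)))) {
    abort("group_means and group_ns must share names",
          class = "phagestress_domain_error")
  }
  group_ns <- group_ns[names(group_means)]
  pairs <- utils::combn(names(group_means), 2)
  a <- pairs[1, ]; b <- pairs[2, ]
  diff <- group_means[a] - group_means[b]
  se <- sqrt(mse / 2 * (1 / group_ns[a] + 1 / group_ns[b]))
  q <- abs(diff) / se
  # with two means the range distribution reduces exactly to |T|*sqrt(2);
  # the closed form is more accurate than the general ptukey quadrature
  p <- if (k == 2) {
    2 * pt(q / sqrt(2), df_resid, lower.tail = FALSE)
  } else {
    ptukey(q, nmeans = k, df = df_resid, lower.tail = FALSE)
  }
  tibble::tibble(
    level_a = a, level_b = b,
    diff = as.numeric(diff), se = as.numeric(se),
    q_stat = as.numeric(q), p_adj = as.numeric(p),
    significant = as.numeric(p) < alpha
  )
}

#' Compact letter display from pairwise comparisons
#'
#' Builds the familiar "groups sharing a letter do not differ" summary
#' from a table of pairwise adjusted p-values, by the insert-and-absorb
#' algorithm: start from one all-inclusive letter group, split it for each
#' significant pair, and drop letter groups contained in another. The
#' result guarantees that two levels share a letter if and only if their
#' comparison is not significant at `alpha`. Letter displays are not
#' unique; this one orders letters by the level order given.
#'
#' @param comparisons Tibble from [tukey_hsd()] (needs `level_a`,
#'   `level_b`, `p_adj`).
#' @param levels Character vector of all level names, in display order.
#' @param alpha Significance cutoff.
#' @return Named character vector: level -> letters.
#' @export
compact_letters <- function(comparisons, levels, alpha = 0.05) {
  groups <- list(levels)
  sig <- comparisons[comparisons$p_adj < alpha, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    a <- sig$level_a[i]; b <- sig$level_b[i]
    new_groups <- list()
    for (g in groups) {
      if (a %in% g && b %in% g) {
        new_groups <- c(new_groups, list(setdiff(g, a)), list(setdiff(g, b)))
      } else {
        new_groups <- c(new_groups, list(g))
      }
    }
    new_groups <- unique(lapply(new_groups, sort))
    new_groups <- new_groups[lengths(new_groups) > 0]
    # absorb: drop any group strictly contained in another
    absorbed <- vapply(seq_along(new_groups), function(j) {
      any(vapply(seq_along(new_groups), function(l) {
        l != j && all(new_groups[[j]] %in% new_groups[[l]]) &&
          length(new_groups[[j]]) < length(new_groups[[l]])
      }, logical(1)))
    }, logical(1))
    groups <- new_groups[!absorbed]
  }
  # order letter groups by their earliest level in display order
  first_pos <- vapply(groups, function(g) min(match(g, levels)), numeric(1))
  groups <- groups[order(first_pos)]
  out <- setNames(rep("", length(levels)), levels)
  for (i in seq_along(groups)) {
    ltr <- letters[(i - 1) %% 26 + 1]
    if (i > 26) ltr <- paste0(ltr, (i - 1) %/% 26)
    out[groups[[i]]] <- paste0(out[groups[[i]]], ltr)
  }
  out
}

#' Welch two-sample t-test
#'
#' Unequal-variance two-sample t statistic with Welch-Satterthwaite
#' degrees of freedom (non-integer) and a two-sided p-value.
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2.
#' @return One-row tibble: `t`, `df`, `p_two_sided`, `mean_a`, `mean_b`.
#' @export
welch_t <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    abort("each sample needs n >= 2", class = "phagestress_domain_error")
  }
  va <- var(sample_a); vb <- var(sample_b)
  na <- length(sample_a); nb <- length(sample_b)
  if (va + vb == 0) {
    abort("both samples are constant; Welch test undefined",
          class = "phagestress_domain_error")
  }
  se2 <- va / na + vb / nb
  t_stat <- (mean(sample_a) - mean(sample_b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  tibble::tibble(
    t = t_stat, df = df,
    p_two_sided = 2 * pt(abs(t_stat), df, lower.tail = FALSE),
    mean_a = mean(sample_a), mean_b = mean(sample_b)
  )
}

#' Bonferroni adjustment
#'
#' @param p Raw p-value(s) in (0, 1].
#' @param m Number of tests in the family (>= 1).
#' @return `min(1, m * p)`, vectorized over `p`.
#' @export
bonferroni <- function(p, m) {
  if (any(m < 1) || any(m != round(m))) {
    abort("m must be a positive integer", class = "phagestress_domain_error")
  }
  pmin(1, m * p)
}
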