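#' Two-group canonical variates analysis of shape scores
#'
#' Discriminates two groups (e.g. yellow- vs non-yellow-flowered orchids) in
#' retained eigenshape score space. With two groups the canonical variate is
#' the Fisher linear discriminant: the direction
#' \eqn{w = S_p^{-1} (\bar m_1 - \bar m_2)} maximising between-group relative
#' to pooled within-group variance, with \eqn{S_p} the pooled within-group
#' covariance. A specimen is assigned to group 1 when its discriminant score
#' exceeds the midpoint between the projected group means.
#'
#' Classification rates are reported under resubstitution (each specimen
#' classified by the rule fitted to all specimens) and leave-one-out
#' cross-validation (rule refitted without the specimen being classified).
#' When the pooled covariance is singular or near-singular (retained axes
#' approaching the specimen count), a small ridge penalty is added to its
#' diagonal and the fit is flagged as regularised.
#'
#' @param scores Tibble with `specimen_id` and numeric axis columns (from
#'   [es_scores()]), or a numeric matrix.
#' @param labels Vector (or factor) of group labels, two levels, aligned with
#'   the rows of `scores`; or the name of a column in a metadata tibble
#'   passed via `metadata`.
#' @param metadata Optional tibble with `specimen_id` and a `group` column;
#'   used when `labels` is a column name.
#' @param ridge Ridge coefficient added as `ridge * mean(diag(Sp))` to the
#'   diagonal when `Sp` is computationally singular; `NULL` (default) applies
#'   `1e-8` only on demand.
#' @return An object of class `"cva_fit"`: the canonical `axis` (unit
#'   vector), per-specimen discriminant `scores`, `rate_resubstitution`,
#'   `rate_loo`, confusion matrices for both validations, group `levels`,
#'   and a `regularized` flag.
#' @export
cva_two_group <- function(scores, labels, metadata = NULL, ridge = NULL) {
  if (is.character(labels) && length(labels) == 1 && !is.null(metadata)) {
    metadata <- as_tibble(metadata)
    sc <- as_tibble(scores)
    d <- inner_join(sc, metadata, by = "specimen_id")
    labels <- d[[labels]]
    scores <- d[, names(sc)[names(sc) != "specimen_id"], drop = FALSE]
    ids <- d$specimen_id
  } else if (is.data.frame(scores)) {
    ids <- if ("specimen_id" %in% names(scores)) scores$specimen_id else NULL
    scores <- scores[, vapply(scores, is.numeric, logical(1)), drop = FALSE]
  } else {
    ids <- rownames(scores)
  }
  x <- as.matrix(scores)
  g <- factor(labels)
  if (nlevels(g) != 2) abort("cva_two_group requires exactly two groups")
  if (min(table(g)) < 2) abort("size error: need at least 2 specimens per group")
  lev <- levels(g)

  fit_rule <- function(x, g) {
    i1 <- g == lev[1]
    m1 <- colMeans(x[i1, , drop = FALSE])
    m2 <- colMeans(x[!i1, , drop = FALSE])
    c1 <- if (sum(i1) > 1) stats::cov(x[i1, , drop = FALSE]) else 0 * diag(ncol(x))
    c2 <- if (sum(!i1) > 1) stats::cov(x[!i1, , drop = FALSE]) else 0 * diag(ncol(x))
    sp <- ((sum(i1) - 1) * c1 + (sum(!i1) - 1) * c2) / (nrow(x) - 2)
    reg <- FALSE
    w <- tryCatch(solve(sp, m1 - m2), error = function(e) NULL)
    if (is.null(w) || rcond(sp) < 1e-12) {
      lambda <- (ridge %||% 1e-8) * max(mean(diag(sp)), .Machine$double.eps)
      sp <- sp + diag(lambda, ncol(x))
      w <- solve(sp, m1 - m2)
      reg <- TRUE
    }
    list(w = w, cut = sum(w * (m1 + m2)) / 2, regularized = reg)
  }
  predict_rule <- function(rule, x) {
    ifelse(as.matrix(x) %*% rule$w > rule$cut, lev[1], lev[2])
  }

  rule <- fit_rule(x, g)
  pred_resub <- predict_rule(rule, x)
  pred_loo <- vapply(seq_len(nrow(x)), function(i) {
    r <- fit_rule(x[-i, , drop = FALSE], g[-i])
    predict_rule(r, x[i, , drop = FALSE])
  }, character(1))

  conf <- function(pred) table(truth = g, predicted = factor(pred, levels = lev))
  structure(
    list(axis = rule$w / sqrt(sum(rule$w^2)),
         cutpoint = rule$cut,
         scores = drop(x %*% rule$w),
         specimen_id = ids,
         levels = lev,
         rate_resubstitution = mean(pred_resub == as.character(g)),
         rate_loo = mean(pred_loo == as.character(g)),
         confusion_resubstitution = conf(pred_resub),
         confusion_loo = conf(pred_loo),
         regularized = rule$regularized,
         n = nrow(x)),
    class = "cva_fit"
  )
}

#' @export
print.cva_fit <- function(x, ...) {
  cat("Two-group canonical variates analysis\n")
  cat(sprintf("  groups: %s vs %s (n = %d)\n", x$levels[1], x$levels[2], x$n))
  cat(sprintf("  classification rate: %.1f%% (resubstitution), %.1f%% (leave-one-out)\n",
              100 * x$rate_resubstitution, 100 * x$rate_loo))
  if (x$regularized) cat("  note: pooled covariance was ridge-regularised\n")
  invisible(x)
}

#' @export
tidy.cva_fit <- function(x, ...) {
  tibble(axis = seq_along(x$axis), loading = as.numeric(x$axis))
}

#' @export
glance.cva_fit <- function(x, ...) {
  tibble(n = x$n,
         rate_resubstitution = x$rate_resubstitution,
         rate_loo = x$rate_loo,
         regularized = x$regularized)
}
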