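#' Pairwise hexagon distances within a community of colour loci
#'
#' @param loci Tibble with one row per species, columns `species`, `x`, `y`.
#' @return The symmetric distance matrix with species names on both margins.
#' @export
pairwise_hexagon_distances <- function(loci) {
  loci <- .check_loci(loci)
  m <- as.matrix(stats::dist(cbind(loci$x, loci$y)))
  dimnames(m) <- list(loci$species, loci$species)
  m
}

.check_loci <- function(loci, min_n = 1) {
  loci <- as_tibble(loci)
  needed <- c("species", "x", "y")
  if (!all(needed %in% names(loci))) {
    abort("loci table needs columns species, x, y")
  }
  if (anyDuplicated(loci$species)) {
    abort("data error: duplicate species labels in community")
  }
  if (nrow(loci) < min_n) {
    abort(paste0("size error: community has ", nrow(loci),
                 " species, need at least ", min_n))
  }
  loci
}

# T statistic from a full distance matrix given the focal index:
# median distance focal-to-others minus median of all other pairwise
# distances. Midpoint median throughout.
.distinctness_T <- function(dmat, focal_idx) {
  n <- nrow(dmat)
  others <- setdiff(seq_len(n), focal_idx)
  focal_d <- dmat[focal_idx, others]
  rest <- dmat[others, others]
  rest_d <- rest[upper.tri(rest)]
  median(focal_d) - median(rest_d)
}

#' Bootstrap test of colour distinctness for one focal species
#'
#' Tests whether a focal species (e.g. a putatively mimetic orchid) occupies
#' a distinct portion of bee colour space relative to its co-flowering
#' community. The statistic is
#' `T = median d(focal, others) - median d(other pairs)`: how much farther
#' the focal species sits from community members than community members
#' typically sit from one another, in hexagon units.
#'
#' Significance comes from a resampling null in which the focal role is
#' exchangeable with the community. Three schemes are available:
#'
#' * `"reassign"` (default): in each replicate the focal role is reassigned
#'   to a species drawn uniformly from the non-focal community, the observed
#'   focal is set aside, and `T*` is recomputed on the remaining loci. This
#'   scheme is near-nominally calibrated (Monte-Carlo rejection close to the
#'   significance level under an exchangeable focal) and its attainable
#'   p-value reaches 0 for a clearly distinct focal.
#' * `"resample"`: as above, but the non-focal set is additionally resampled
#'   with replacement to its original size. Resampling duplicates species
#'   and so injects zero distances into the community pairwise median (but
#'   not the focal median), which biases `T*` upwards; the scheme is
#'   conservative and kept as a robustness check.
#' * `"permute"`: the focal label is permuted over all species including the
#'   observed focal; the attainable p-value is floored near `1/n`.
#'
#' Setting the observed focal aside in the first two schemes is what gives
#' the test its power: were the focal kept in the replicate pool, a
#' genuinely distinct focal would keep re-entering the null distribution.
#' The one-sided p-value is always the fraction of replicates with
#' `T* >= T` (focal at least as distinct as observed).
#'
#' Because only pairwise distances enter, the test is invariant to rigid
#' rotation and translation of all loci.
#'
#' @param loci Community loci table (`species`, `x`, `y`), one row per
#'   species; at least 4 species.
#' @param focal Species label of the focal species.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; required for reproducibility.
#' @param null `"reassign"` (default), `"resample"` or `"permute"`; see
#'   Details.
#' @return An object of class `"distinctness_test"` with elements `statistic`
#'   (observed T), `p.value`, `n_boot`, `seed`, `focal`, `n_species`, `null`.
#' @export
focal_distinctness_test <- function(loci, focal, n_boot = 1000, seed,
                                    null = c("reassign", "resample",
                                             "permute")) {
  null <- match.arg(null)
  if (missing(seed)) abort("seed is required for the bootstrap")
  loci <- .check_loci(loci, min_n = 4)
  if (!focal %in% loci$species) {
    abort(paste0("key error: focal species '", focal, "' not in community"))
  }
  n <- nrow(loci)
  dmat <- pairwise_hexagon_distances(loci)
  focal_idx <- match(focal, loci$species)
  t_obs <- .distinctness_T(dmat, focal_idx)
  others <- setdiff(seq_len(n), focal_idx)
  dmat_others <- dmat[others, others, drop = FALSE]
  t_star <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      switch(null,
        reassign = .distinctness_T(dmat_others, sample.int(n - 1, 1)),
        resample = {
          f <- others[sample.int(n - 1, 1)]
          pool <- setdiff(others, f)
          idx <- c(f, sample(pool, n - 1, replace = TRUE))
          .distinctness_T(dmat[idx, idx, drop = FALSE], 1L)
        },
        permute = .distinctness_T(dmat, sample.int(n, 1))
      )
    }, numeric(1))
  })
  structure(
    list(statistic = t_obs,
         p.value = mean(t_star >= t_obs),
         n_boot = n_boot, seed = seed, focal = focal,
         n_species = n, null = null),
    class = "distinctness_test"
  )
}

#' @export
print.distinctness_test <- function(x, ...) {
  cat("Focal colour-distinctness bootstrap test\n")
  cat(sprintf("  focal: %s (community of %d species)\n", x$focal, x$n_species))
  cat(sprintf("  T = %.4f hexagon units, p = %.4g (%d replicates, null = %s, seed = %d)\n",
              x$statistic, x$p.value, x$n_boot, x$null, x$seed))
  invisible(x)
}

#' @export
tidy.distinctness_test <- function(x, ...) {
  tibble(focal = x$focal, statistic = x$statistic, p.value = x$p.value,
         n_boot = x$n_boot, seed = x$seed, n_species = x$n_species,
         null = x$null)
}

#' @export
glance.distinctness_test <- function(x, ...) tidy(x)

#' Do UV-green species cluster in colour space more than other species?
#'
#' Tests whether species in the bee-UV-green sector (putative mimics and
#' models) sit closer to one another in colour space than the remaining
#' community members do. Sample A collects all pairwise hexagon distances
#' among UV-green species, sample B all pairwise distances among the others;
#' a one-sided Welch two-sample t-test asks whether mean(A) < mean(B).
#'
#' Pairwise distances are not independent observations, so the t-test is an
#' approximation; this caveat is recorded in the result (`caveat` field) and
#' should accompany any report.
#'
#' @param loci Community loci table with columns `species`, `x`, `y` and a
#'   sector column (default `sector`, as produced by [spectra_to_loci()]).
#' @param sector_col Name of the sector column.
#' @param uvgreen_label Sector value identifying the UV-green group.
#' @return An object of class `"group_contrast"`: Welch `statistic` (t),
#'   `parameter` (fractional df), one-sided `p.value`, group sizes and
#'   pair counts.
#' @export
uvgreen_group_test <- function(loci, sector_col = "sector",
                               uvgreen_label = "uv-green") {
  loci <- .check_loci(loci)
  if (!sector_col %in% names(loci)) {
    abort(paste0("loci table needs a '", sector_col, "' column"))
  }
  in_uvg <- loci[[sector_col]] == uvgreen_label
  # 3 species give 3 pairwise distances; 2 give a single pair, leaving the
  # Welch variance undefined
  if (sum(in_uvg) < 3 || sum(!in_uvg) < 3) {
    abort("size error: need at least 3 species inside and 3 outside uv-green")
  }
  dmat <- pairwise_hexagon_distances(loci)
  pick <- function(keep) {
    m <- dmat[keep, keep, drop = FALSE]
    m[upper.tri(m)]
  }
  a <- pick(in_uvg)
  b <- pick(!in_uvg)
  ht <- t.test(a, b, alternative = "less", var.equal = FALSE)
  structure(
    list(statistic = unname(ht$statistic),
         parameter = unname(ht$parameter),
         p.value = ht$p.value,
         n_uvgreen = sum(in_uvg), n_other = sum(!in_uvg),
         n_pairs_uvgreen = length(a), n_pairs_other = length(b),
         mean_uvgreen = mean(a), mean_other = mean(b),
         caveat = "pairwise distances are not independent; t-test is approximate"),
    class = "group_contrast"
  )
}

#' @export
print.group_contrast <- function(x, ...) {
  cat("Welch group contrast (one-sided, group A smaller)\n")
  cat(sprintf("  t = %.4f, df = %.3f, p = %.4g\n",
              x$statistic, x$parameter, x$p.value))
  cat(sprintf("  mean A = %.4f (n pairs %d), mean B = %.4f (n pairs %d)\n",
              x$mean_uvgreen %||% x$mean_a, x$n_pairs_uvgreen %||% x$n_a,
              x$mean_other %||% x$mean_b, x$n_pairs_other %||% x$n_b))
  cat("  note:", x$caveat, "\n")
  invisible(x)
}

#' @export
tidy.group_contrast <- function(x, ...) {
  tibble(statistic = x$statistic, parameter = x$parameter,
         p.value = x$p.value,
         mean_a = x$mean_uvgreen %||% x$mean_a,
         mean_b = x$mean_other %||% x$mean_b)
}

#' @export
glance.group_contrast <- function(x, ...) tidy(x)
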