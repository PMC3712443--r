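#' Read floral outlines from a TPS file
#'
#' Parses the plain-text TPS landmark format used throughout geometric
#' morphometrics: blocks starting `LM=<n>` followed by `n` lines of `x y`
#' coordinates and an `ID=` or `IMAGE=` line naming the specimen.
#'
#' @param path Path to a TPS file.
#' @return Tidy outline tibble with columns `specimen_id`, `point_index`,
#'   `x`, `y`.
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM\\s*=", lines, ignore.case = TRUE)
  if (!length(starts)) abort("format error: no LM= records in TPS file")
  out <- vector("list", length(starts))
  bounds <- c(starts, length(lines) + 1L)
  for (i in seq_along(starts)) {
    block <- lines[starts[i]:(bounds[i + 1] - 1L)]
    n <- as.integer(sub("^LM\\s*=\\s*", "", block[1], ignore.case = TRUE))
    if (is.na(n) || n < 1 || length(block) < n + 1) {
      abort("format error: malformed LM block in TPS file")
    }
    coords <- do.call(rbind, lapply(block[2:(n + 1)], function(l) {
      as.numeric(strsplit(l, "\\s+")[[1]][1:2])
    }))
    id_line <- grep("^(ID|IMAGE)\\s*=", block, ignore.case = TRUE, value = TRUE)
    id <- if (length(id_line)) {
      sub("^(ID|IMAGE)\\s*=\\s*", "", id_line[1], ignore.case = TRUE)
    } else {
      paste0("specimen_", i)
    }
    out[[i]] <- tibble(specimen_id = id, point_index = seq_len(n),
                       x = coords[, 1], y = coords[, 2])
  }
  bind_rows(out)
}

#' Read floral outlines from a coordinate CSV
#'
#' @param path CSV with columns `specimen_id`, `point_index`, `x`, `y`.
#' @return Tidy outline tibble ordered by specimen and point index.
#' @export
read_outlines_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("specimen_id", "point_index", "x", "y") %in% names(d))) {
    abort("format error: outline CSV needs specimen_id, point_index, x, y")
  }
  d |>
    mutate(specimen_id = as.character(.data$specimen_id)) |>
    arrange(.data$specimen_id, .data$point_index)
}

# points matrix for one specimen, validated; a bare 2-point chord is a legal
# polyline for interpolation (it yields m >= 3 semi-landmarks downstream)
.outline_matrix <- function(df) {
  pts <- cbind(df$x, df$y)
  if (nrow(pts) < 2) abort("geometry error: outline needs at least 2 points")
  steps <- diff(pts)
  if (any(rowSums(steps^2) == 0)) {
    abort("geometry error: repeated consecutive points in outline")
  }
  if (all(pts[1, ] == pts[nrow(pts), ])) {
    abort("geometry error: outline is closed; open curves required")
  }
  pts
}

#' Interpolate equally spaced semi-landmarks along open outlines
#'
#' Places `m` semi-landmarks at equal arc-length intervals along each
#' specimen's polyline, from the start anchor to the end anchor. The anchors
#' (first and last digitised points) are preserved exactly; intermediate
#' points are placed by linear interpolation along the curve.
#'
#' @param outlines Tidy outline tibble (`specimen_id`, `point_index`, `x`,
#'   `y`); points ordered along the curve.
#' @param m Number of semi-landmarks (default 100).
#' @return Outline tibble with `m` points per specimen.
#' @export
interpolate_semilandmarks <- function(outlines, m = 100) {
  if (m < 3) abort("m must be at least 3")
  outlines |>
    as_tibble() |>
    arrange(.data$specimen_id, .data$point_index) |>
    group_by(.data$specimen_id) |>
    group_modify(function(df, key) {
      pts <- .outline_matrix(df)
      seg <- sqrt(rowSums(diff(pts)^2))
      s <- c(0, cumsum(seg))
      if (s[length(s)] == 0) abort("geometry error: zero-length outline")
      target <- seq(0, s[length(s)], length.out = m)
      tibble(point_index = seq_len(m),
             x = approx(s, pts[, 1], xout = target)$y,
             y = approx(s, pts[, 2], xout = target)$y)
    }) |>
    ungroup()
}

# unwrap a sequence of angles so consecutive differences lie in (-pi, pi]
.unwrap <- function(theta) {
  d <- diff(theta)
  adj <- cumsum(c(0, -2 * pi * round(d / (2 * pi))))
  theta + adj
}

#' Tangent-angle (phi) shape functions of open outlines
#'
#' Converts each outline of `m` equally spaced semi-landmarks into its phi
#' shape function: the `m - 1` tangent angles of successive steps, unwrapped
#' to remove branch-cut jumps and standardised for rotation. Because step
#' lengths are equal by construction, the representation carries no size
#' information; translation never enters. Two rotation standardisations are
#' offered: subtracting the angle of the anchor-to-anchor chord (default;
#' deterministic and anchor-respecting) or subtracting the mean tangent
#' angle. An optional zero-mean variant additionally centres each phi
#' function on its own mean (the net-deviation form used by some eigenshape
#' software); the choice is recorded in the `"zero_mean"` attribute.
#'
#' @param outlines Outline tibble with equally spaced semi-landmarks (run
#'   [interpolate_semilandmarks()] first).
#' @param rotation `"chord"` (default) or `"mean"`.
#' @param zero_mean If `TRUE`, subtract each specimen's mean phi.
#' @return Tibble with columns `specimen_id`, `step`, `phi` (radians);
#'   attributes `rotation` and `zero_mean`.
#' @export
outlines_to_phi <- function(outlines, rotation = c("chord", "mean"),
                            zero_mean = FALSE) {
  rotation <- match.arg(rotation)
  res <- outlines |>
    as_tibble() |>
    arrange(.data$specimen_id, .data$point_index) |>
    group_by(.data$specimen_id) |>
    group_modify(function(df, key) {
      pts <- .outline_matrix(df)
      steps <- diff(pts)
      ang <- .unwrap(atan2(steps[, 2], steps[, 1]))
      ref <- if (rotation == "chord") {
        atan2(pts[nrow(pts), 2] - pts[1, 2], pts[nrow(pts), 1] - pts[1, 1])
      } else {
        mean(ang)
      }
      phi <- ang - ref
      # keep the first relative angle on the principal branch so that the
      # same shape rotated across the atan2 branch cut yields identical phi
      phi <- phi - 2 * pi * round(phi[1] / (2 * pi))
      if (zero_mean) phi <- phi - mean(phi)
      tibble(step = seq_along(phi), phi = phi)
    }) |>
    ungroup()
  attr(res, "rotation") <- rotation
  attr(res, "zero_mean") <- zero_mean
  res
}

#' Eigenshape decomposition of phi shape functions
#'
#' Centres the specimen-by-angle matrix of phi functions and performs a
#' singular value decomposition, equivalent to an eigendecomposition of the
#' covariance matrix of phi functions. The right singular vectors are the
#' eigenshape axes (orthonormal modes of outline shape variation), the
#' squared singular values divided by `n - 1` are their variances, and
#' specimen scores are the projections of the centred phi functions onto the
#' axes.
#'
#' @param phi Phi tibble from [outlines_to_phi()] (columns `specimen_id`,
#'   `step`, `phi`), all specimens of equal length; at least 2 specimens.
#' @return An object of class `"eigenshape"` with elements `mean_phi`,
#'   `axes` (p x k orthonormal matrix), `eigenvalues`, `variance_fraction`,
#'   `scores` (n x k matrix, rownames = specimen ids), `total_variance`,
#'   `retain_fraction` (1 for the full decomposition).
#' @export
eigenshape_decompose <- function(phi) {
  wide <- phi |>
    as_tibble() |>
    tidyr::pivot_wider(id_cols = "specimen_id", names_from = "step",
                       values_from = "phi")
  ids <- wide$specimen_id
  x <- as.matrix(wide[, -1])
  if (anyNA(x)) abort("phi functions have unequal lengths or missing values")
  n <- nrow(x)
  if (n < 2) abort("size error: need at least 2 specimens")
  mean_phi <- colMeans(x)
  xc <- sweep(x, 2, mean_phi)
  sv <- svd(xc)
  k <- sum(sv$d > max(sv$d[1], 1) * 1e-12 * max(dim(x)))
  k <- max(k, 1L)
  eigenvalues <- sv$d^2 / (n - 1)
  total <- sum(eigenvalues)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], nrow = k)
  rownames(scores) <- ids
  colnames(scores) <- paste0("es", seq_len(k))
  axes <- sv$v[, seq_len(k), drop = FALSE]
  colnames(axes) <- paste0("es", seq_len(k))
  structure(
    list(mean_phi = mean_phi,
         axes = axes,
         eigenvalues = eigenvalues[seq_len(k)],
         variance_fraction = if (total > 0) eigenvalues[seq_len(k)] / total
                             else rep(0, k),
         scores = scores,
         total_variance = total,
         retain_fraction = 1),
    class = "eigenshape"
  )
}

#' Truncate an eigenshape decomposition to a variance fraction
#'
#' Keeps the smallest number of leading axes whose cumulative variance
#' fraction reaches `fraction` (the conventional choice is the axes
#' describing 90 percent of shape variation).
#'
#' @param x An `"eigenshape"` object.
#' @param fraction Target cumulative variance fraction in (0, 1].
#' @return A truncated `"eigenshape"` object; `total_variance` still records
#'   the variance of the full decomposition.
#' @export
retain_axes <- function(x, fraction = 0.90) {
  stopifnot(inherits(x, "eigenshape"), fraction > 0, fraction <= 1)
  cumv <- cumsum(x$variance_fraction)
  k <- if (fraction == 1) {
    sum(x$eigenvalues > 0)
  } else {
    which(cumv >= fraction - 1e-12)[1]
  }
  if (is.na(k)) k <- length(x$eigenvalues)
  k <- max(k, 1L)
  x$axes <- x$axes[, seq_len(k), drop = FALSE]
  x$eigenvalues <- x$eigenvalues[seq_len(k)]
  x$variance_fraction <- x$variance_fraction[seq_len(k)]
  x$scores <- x$scores[, seq_len(k), drop = FALSE]
  x$retain_fraction <- fraction
  x
}

#' @export
print.eigenshape <- function(x, ...) {
  k <- ncol(x$scores)
  cat(sprintf("Eigenshape decomposition: %d specimens, %d axes retained\n",
              nrow(x$scores), k))
  cat(sprintf("  cumulative variance of retained axes: %.1f%% (target %.0f%%)\n",
              100 * sum(x$variance_fraction), 100 * x$retain_fraction))
  invisible(x)
}

#' @export
tidy.eigenshape <- function(x, ...) {
  tibble(axis = seq_along(x$eigenvalues),
         eigenvalue = x$eigenvalues,
         variance_fraction = x$variance_fraction,
         cumulative = cumsum(x$variance_fraction))
}

#' @export
glance.eigenshape <- function(x, ...) {
  tibble(n_specimens = nrow(x$scores), n_axes = ncol(x$scores),
         total_variance = x$total_variance,
         retained_variance_fraction = sum(x$variance_fraction),
         retain_fraction = x$retain_fraction)
}

#' Specimen scores of an eigenshape decomposition as a tibble
#'
#' @param x An `"eigenshape"` object.
#' @return Tibble with `specimen_id` and one column per retained axis.
#' @export
es_scores <- function(x) {
  stopifnot(inherits(x, "eigenshape"))
  bind_cols(tibble(specimen_id = rownames(x$scores)),
            as_tibble(x$scores))
}

#' Distance of each specimen to its nearest target-family specimen
#'
#' For each specimen outside the target family, the minimum Euclidean
#' distance in retained eigenshape score space to any specimen of the target
#' family (by default Malpighiaceae, the rewarding models).
#'
#' @param scores Score tibble from [es_scores()] (or any tibble with
#'   `specimen_id` + numeric axis columns).
#' @param metadata Tibble with columns `specimen_id`, `species`, `group`,
#'   `family`.
#' @param target_family Family of target specimens.
#' @return Tibble `specimen_id`, `species`, `group`, `family`,
#'   `nearest_distance`.
#' @export
nearest_group_distance <- function(scores, metadata,
                                   target_family = "Malpighiaceae") {
  scores <- as_tibble(scores)
  metadata <- as_tibble(metadata)
  d <- inner_join(scores, metadata, by = "specimen_id")
  if (nrow(d) < nrow(scores)) {
    warn("some specimens lack metadata and were dropped")
  }
  axis_cols <- names(scores)[vapply(scores, is.numeric, logical(1))]
  m <- as.matrix(d[, axis_cols, drop = FALSE])
  is_target <- d$family == target_family
  if (!any(is_target)) {
    abort(paste0("size error: no specimens of target family '",
                 target_family, "'"))
  }
  tm <- m[is_target, , drop = FALSE]
  nd <- vapply(seq_len(nrow(m)), function(i) {
    if (is_target[i]) return(NA_real_)
    min(sqrt(colSums((t(tm) - m[i, ])^2)))
  }, numeric(1))
  d |>
    filter(!is_target) |>
    select(any_of(c("specimen_id", "species", "group", "family"))) |>
    mutate(nearest_distance = nd[!is_target])
}

#' Contrast nearest-model shape distances between two groups
#'
#' One-sided Welch t-test of whether group A (by default yellow-flowered
#' Oncidiinae) has a smaller mean nearest-Malpighiaceae shape distance than
#' group B (all other angiosperms). Outlier exclusion is always an explicit
#' user decision via `exclude`, never automatic.
#'
#' @param distances Tibble from [nearest_group_distance()].
#' @param group_a,group_b Values of the `group` column defining the two
#'   samples; `group_b = NULL` means everything not in `group_a`.
#' @param exclude Character vector of species to drop before testing.
#' @return A `"group_contrast"` object (Welch t, fractional df, one-sided p).
#' @export
group_distance_test <- function(distances, group_a = "yellow",
                                group_b = NULL, exclude = NULL) {
  d <- as_tibble(distances)
  if (!is.null(exclude)) d <- filter(d, !.data$species %in% exclude)
  a <- d$nearest_distance[d$group == group_a]
  b <- if (is.null(group_b)) {
    d$nearest_distance[d$group != group_a]
  } else {
    d$nearest_distance[d$group == group_b]
  }
  if (length(a) < 2 || length(b) < 2) {
    abort("size error: need at least 2 specimens per group after exclusion")
  }
  ht <- t.test(a, b, alternative = "less", var.equal = FALSE)
  structure(
    list(statistic = unname(ht$statistic),
         parameter = unname(ht$parameter),
         p.value = ht$p.value,
         n_a = length(a), n_b = length(b),
         mean_a = mean(a), mean_b = mean(b),
         excluded = exclude %||% character(0),
         caveat = "one-sided Welch test: group A closer to models than group B"),
    class = "group_contrast"
  )
}
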