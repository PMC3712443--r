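outline_tbl <- function(xy, id = "a") {
  tibble::tibble(specimen_id = id, point_index = seq_len(nrow(xy)),
                 x = xy[, 1], y = xy[, 2])
}

test_that("semi-landmark interpolation spaces points by arc length", {
  seg <- outline_tbl(cbind(c(0, 1), c(0, 0)))
  sl <- interpolate_semilandmarks(seg, m = 5)
  expect_equal(sl$x, c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(sl$y, rep(0, 5))

  # already equally spaced -> unchanged
  sl2 <- interpolate_semilandmarks(sl, m = 5)
  expect_equal(sl2$x, sl$x, tolerance = 1e-12)

  # quarter circle: all chords equal within 1e-6
  t <- seq(0, pi / 2, length.out = 2000)
  qc <- outline_tbl(cbind(cos(t), sin(t)))
  sl3 <- interpolate_semilandmarks(qc, m = 91)
  chords <- sqrt(diff(sl3$x)^2 + diff(sl3$y)^2)
  expect_lt(max(chords) - min(chords), 1e-6)

  # anchors preserved exactly
  expect_equal(c(sl3$x[1], sl3$y[1]), c(1, 0))
  expect_equal(c(sl3$x[91], sl3$y[91]), c(cos(pi / 2), 1))

  bad <- outline_tbl(cbind(c(0, 0, 1), c(0, 0, 0)))
  expect_error(interpolate_semilandmarks(bad, 5), "geometry error")
})

test_that("phi functions are zero for a chord and invariant to similarity", {
  seg <- interpolate_semilandmarks(outline_tbl(cbind(c(0, 1), c(0, 0.3))), 20)
  phi <- outlines_to_phi(seg)
  expect_equal(phi$phi, rep(0, 19), tolerance = 1e-12)

  # an arbitrary wiggly open curve
  t <- seq(0, 1, length.out = 200)
  base <- cbind(t, 0.3 * sin(pi * t) + 0.1 * sin(3 * pi * t))
  o1 <- interpolate_semilandmarks(outline_tbl(base), 60)
  a <- 37 * pi / 180
  rot <- 3 * base %*% t(matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2))
  rot <- sweep(rot, 2, c(5, -2), "+")
  o2 <- interpolate_semilandmarks(outline_tbl(rot), 60)
  p1 <- outlines_to_phi(o1)
  p2 <- outlines_to_phi(o2)
  expect_equal(p1$phi, p2$phi, tolerance = 1e-10)

  # rotation across the atan2 branch cut
  a <- 170 * pi / 180
  rot2 <- base %*% t(matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2))
  p3 <- outlines_to_phi(interpolate_semilandmarks(outline_tbl(rot2), 60))
  expect_equal(p1$phi, p3$phi, tolerance = 1e-10)
})

test_that("phi of a semicircle is linear between +pi/2 and -pi/2", {
  # clockwise over the top: from (-1, 0) to (1, 0)
  t <- seq(pi, 0, length.out = 3000)
  semi <- outline_tbl(cbind(cos(t), sin(t)))
  sl <- interpolate_semilandmarks(semi, 181)
  phi <- outlines_to_phi(sl)$phi
  expect_equal(phi[1], pi / 2, tolerance = 0.02)
  expect_equal(phi[180], -pi / 2, tolerance = 0.02)
  expect_lt(max(abs(diff(diff(phi)))), 1e-4)  # uniform slope
})

test_that("eigenshape decomposition matches an independent eigendecomposition", {
  set.seed(31)
  n <- 20; p <- 50
  x <- matrix(rnorm(n * p), n, p) %*% diag(seq(2, 0.1, length.out = p))
  phi <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(x, .name_repair = ~as.character(1:p)),
                  specimen_id = sprintf("sp%02d", 1:n)),
    -specimen_id, names_to = "step", values_to = "phi")
  phi$step <- as.integer(phi$step)
  es <- eigenshape_decompose(phi)

  ev <- eigen(stats::cov(x), symmetric = TRUE)
  k <- ncol(es$scores)
  expect_equal(es$eigenvalues, ev$values[1:k], tolerance = 1e-8)
  # eigenvalue sum conservation
  expect_equal(sum(ev$values), es$total_variance, tolerance = 1e-8)
  # scores equal projections on the oracle's eigenvectors (up to axis sign)
  xc <- sweep(x, 2, colMeans(x))
  proj <- xc %*% ev$vectors[, 1:k]
  for (j in 1:k) {
    expect_equal(abs(es$scores[, j]), abs(proj[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # full-axis reconstruction of the centred matrix
  rec <- es$scores %*% t(es$axes)
  expect_lt(max(abs(rec - xc)), 1e-8)
  # scores orthogonal across axes
  g <- crossprod(es$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
})

test_that("degenerate decompositions behave: identical and paired specimens", {
  phi1 <- tibble::tibble(specimen_id = rep(c("a", "b", "c"), each = 10),
                         step = rep(1:10, 3), phi = rep(sin(1:10 / 2), 3))
  es <- eigenshape_decompose(phi1)
  expect_equal(max(abs(es$scores)), 0, tolerance = 1e-12)
  expect_equal(es$total_variance, 0, tolerance = 1e-12)

  phi2 <- tibble::tibble(specimen_id = rep(c("a", "b"), each = 10),
                         step = rep(1:10, 2),
                         phi = c(sin(1:10 / 2), cos(1:10 / 2)))
  es2 <- eigenshape_decompose(phi2)
  expect_equal(sum(es2$eigenvalues > 1e-12), 1)
  expect_equal(es2$scores[1, 1], -es2$scores[2, 1], tolerance = 1e-10)

  expect_error(eigenshape_decompose(phi2[phi2$specimen_id == "a", ]),
               "size error")
})

test_that("axis retention keeps the smallest axis set reaching the target", {
  es <- structure(list(
    mean_phi = numeric(10),
    axes = diag(10)[, 1:3], eigenvalues = c(0.8, 0.15, 0.05),
    variance_fraction = c(0.8, 0.15, 0.05),
    scores = matrix(rnorm(15), 5, 3,
                    dimnames = list(paste0("s", 1:5), paste0("es", 1:3))),
    total_variance = 1, retain_fraction = 1), class = "eigenshape")
  expect_equal(ncol(retain_axes(es, 0.90)$scores), 2)
  expect_equal(ncol(retain_axes(es, 0.96)$scores), 3)
  expect_equal(ncol(retain_axes(es, 1)$scores), 3)
  expect_equal(ncol(retain_axes(es, 0.5)$scores), 1)
})

test_that("outline-to-score pipeline is similarity invariant", {
  gen <- gen_outlines(c(yellow = 6, "non-yellow" = 6), seed = 12)
  run <- function(outl) {
    sl <- interpolate_semilandmarks(outl, 80)
    es_scores(retain_axes(eigenshape_decompose(outlines_to_phi(sl)), 0.9))
  }
  s1 <- run(gen$outlines)
  a <- 1.1
  tr <- gen$outlines
  xy <- as.matrix(tr[, c("x", "y")]) %*%
    t(matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)) * 4.2
  tr$x <- xy[, 1] + 10; tr$y <- xy[, 2] - 3
  s2 <- run(tr)
  expect_equal(as.matrix(s1[, -1]), as.matrix(s2[, -1]), tolerance = 1e-8)
})

test_that("nearest-model distances match a brute-force search", {
  set.seed(9)
  sc <- tibble::tibble(specimen_id = sprintf("s%02d", 1:15),
                       es1 = rnorm(15), es2 = rnorm(15))
  meta <- tibble::tibble(specimen_id = sc$specimen_id,
                         species = sc$specimen_id,
                         group = rep(c("yellow", "other", "model"), 5),
                         family = rep(c("Orchidaceae", "Other",
                                        "Malpighiaceae"), 5))
  nd <- nearest_group_distance(sc, meta)
  m <- as.matrix(sc[, -1])
  targets <- which(meta$family == "Malpighiaceae")
  for (i in seq_len(nrow(nd))) {
    row <- which(sc$specimen_id == nd$specimen_id[i])
    brute <- min(sqrt(rowSums((m[targets, , drop = FALSE] -
                                 matrix(m[row, ], length(targets), 2,
                                        byrow = TRUE))^2)))
    expect_equal(nd$nearest_distance[i], brute)
  }
  # Pythagorean check
  sc2 <- tibble::tibble(specimen_id = c("m", "q"), es1 = c(0, 3), es2 = c(0, 4))
  meta2 <- tibble::tibble(specimen_id = c("m", "q"), species = c("m", "q"),
                          group = c("model", "yellow"),
                          family = c("Malpighiaceae", "Orchidaceae"))
  expect_equal(nearest_group_distance(sc2, meta2)$nearest_distance, 5)
  expect_error(nearest_group_distance(sc2, dplyr::mutate(meta2, family = "x")),
               "size error")
})

test_that("group distance contrast: null and extreme cases, Welch oracle", {
  d0 <- tibble::tibble(species = sprintf("s%d", 1:10),
                       group = rep(c("yellow", "other"), 5),
                       nearest_distance = rep(c(0.5, 0.5), 5) +
                         rep(c(0.01, -0.01, 0.02, -0.02, 0), 2))
  r0 <- group_distance_test(d0)
  expect_gt(r0$p.value, 0.2)

  d1 <- tibble::tibble(species = sprintf("s%d", 1:8),
                       group = rep(c("yellow", "other"), each = 4),
                       nearest_distance = c(0.01, 0.02, 0.015, 0.02,
                                            1, 1.1, 0.9, 1.05))
  r1 <- group_distance_test(d1)
  expect_lt(r1$p.value, 0.001)
  orc <- oracle_welch(d1$nearest_distance[1:4], d1$nearest_distance[5:8])
  expect_equal(r1$statistic, orc$t, tolerance = 1e-10)
  expect_equal(r1$parameter, orc$df, tolerance = 1e-10)

  # explicit outlier exclusion changes the sample
  d2 <- dplyr::bind_rows(d1, tibble::tibble(species = "outlier",
                                            group = "yellow",
                                            nearest_distance = 5))
  r2 <- group_distance_test(d2, exclude = "outlier")
  expect_equal(r2$statistic, r1$statistic)
  expect_error(group_distance_test(d1[c(1, 5, 6, 7), ]), "size error")
})
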