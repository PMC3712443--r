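receptors <- bee_receptors()
illum <- illuminant_d65()
bg <- leaf_background()

test_that("receptor templates are unimodal, normalised and ordered", {
  for (col in c("uv", "blue", "green")) {
    s <- receptors[[col]]
    expect_true(all(s >= 0))
    expect_equal(max(s), 1, tolerance = 1e-6)
    peak <- receptors$wavelength_nm[which.max(s)]
    # single local maximum
    expect_lte(sum(diff(sign(diff(s))) < 0), 1)
  }
  expect_lt(receptors$wavelength_nm[which.max(receptors$uv)],
            receptors$wavelength_nm[which.max(receptors$blue)])
  expect_lt(receptors$wavelength_nm[which.max(receptors$blue)],
            receptors$wavelength_nm[which.max(receptors$green)])
  expect_error(bee_receptors(c(uv = 500, blue = 436, green = 544)), "uv < blue")
})

test_that("von Kries normalisation: background catches are exactly 1", {
  spec_bg <- as_spectrum(bg$value)
  p <- quantum_catch(spec_bg, receptors, illum, bg)
  expect_equal(c(p$p_uv, p$p_b, p$p_g), c(1, 1, 1), tolerance = 1e-12)

  p0 <- quantum_catch(as_spectrum(rep(0, 401)), receptors, illum, bg)
  expect_equal(c(p0$p_uv, p0$p_b, p0$p_g), c(0, 0, 0))

  # linearity: half the background -> catches 0.5
  ph <- quantum_catch(as_spectrum(bg$value / 2), receptors, illum, bg)
  expect_equal(c(ph$p_uv, ph$p_b, ph$p_g), c(0.5, 0.5, 0.5), tolerance = 1e-12)

  zero_bg <- bg
  zero_bg$value <- rep(0, nrow(bg))
  expect_error(quantum_catch(spec_bg, receptors, illum, zero_bg),
               "degenerate-adaptation")
})

test_that("excitation follows the P/(P+1) transduction closed form", {
  expect_equal(excitation(1), 0.5)
  expect_equal(excitation(0), 0)
  expect_equal(excitation(3), 0.75)
  p <- seq(0, 50, by = 0.25)
  e <- excitation(p)
  expect_true(all(diff(e) > 0))       # strictly monotone
  expect_true(all(e >= 0 & e < 1))
  expect_gt(excitation(1e6), 0.999)   # saturates towards 1
  expect_error(excitation(-0.1), "domain error")
})

test_that("hexagon coordinates: adaptation centre and vertices", {
  expect_equal(unlist(hexagon_locus(0.5, 0.5, 0.5)), c(x = 0, y = 0))
  gv <- hexagon_locus(0, 0, 1 - 1e-15)
  expect_equal(gv$x, sqrt(3) / 2, tolerance = 1e-9)
  expect_equal(gv$y, -1 / 2, tolerance = 1e-9)
  expect_equal(sqrt(gv$x^2 + gv$y^2), 1, tolerance = 1e-9)
  bv <- hexagon_locus(0, 1 - 1e-15, 0)
  expect_equal(c(bv$x, bv$y), c(0, 1), tolerance = 1e-9)
  expect_error(hexagon_locus(1, 0.5, 0.5), "\\[0, 1\\)")
})

test_that("hexagon distance is a metric and the 0.1-unit rule is strict", {
  a <- c(0, 0); b <- c(0, 1)
  expect_equal(hexagon_distance(a, a), 0)
  expect_equal(hexagon_distance(a, b), 1)
  set.seed(7)
  for (i in 1:50) {
    p <- runif(2, -1, 1); q <- runif(2, -1, 1); r <- runif(2, -1, 1)
    expect_equal(hexagon_distance(p, q), hexagon_distance(q, p))
    expect_lte(hexagon_distance(p, r),
               hexagon_distance(p, q) + hexagon_distance(q, r) + 1e-12)
  }
  # mimic-model differences of 0.04 units are below the discrimination
  # threshold; the threshold itself is not "more than" the threshold
  expect_false(is_distinguishable(c(0, 0), c(0.04, 0)))
  expect_false(is_distinguishable(c(0, 0), c(0.1, 0)))
  expect_true(is_distinguishable(c(0, 0), c(0.2, 0)))
})

test_that("sector classification matches the angle-binning oracle", {
  expect_equal(classify_sector(0, 0.9), "blue")
  # symmetric UV+green stimulus sits on the uv-green axis
  l <- hexagon_locus(0.4, 0.1, 0.4)
  expect_equal(l$x, 0)
  expect_equal(l$y, -0.3)
  expect_equal(classify_sector(l$x, l$y), "uv-green")

  set.seed(11)
  n <- 10000
  r <- sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  x <- r * cos(th); y <- r * sin(th)
  expect_equal(classify_sector(x, y), oracle_sector(x, y))
})

test_that("swapping UV and green receptor roles mirrors the sectors", {
  swap_map <- c("blue" = "blue", "blue-green" = "uv-blue", "green" = "uv",
                "uv-green" = "uv-green", "uv" = "green",
                "uv-blue" = "blue-green", "achromatic-center" = "achromatic-center")
  set.seed(3)
  e <- matrix(runif(300, 0, 0.99), ncol = 3)
  l1 <- hexagon_locus(e[, 1], e[, 2], e[, 3])
  l2 <- hexagon_locus(e[, 3], e[, 2], e[, 1])
  s1 <- classify_sector(l1$x, l1$y)
  s2 <- classify_sector(l2$x, l2$y)
  # boundary points can flip at exact mirror angles; exclude loci within
  # 1e-6 of a 30-degree boundary
  deg <- (atan2(l1$x, l1$y) * 180 / pi) %% 60
  interior <- abs(deg - 30) > 1e-3 & deg > 1e-3 & deg < 60 - 1e-3
  expect_equal(s2[interior], unname(swap_map[s1[interior]]))
})

test_that("all physical spectra map strictly inside the unit hexagon", {
  set.seed(23)
  specs <- dplyr::bind_rows(lapply(1:30, function(i) {
    # smooth random physical reflectance in [0, 1]
    base <- stats::filter(runif(441), rep(1 / 41, 41), sides = 2)
    refl <- pmin(pmax(as.numeric(base)[21:421] * runif(1, 0.5, 2), 0), 1)
    as_spectrum(refl, species = paste0("r", i))
  }))
  loci <- spectra_to_loci(specs)
  expect_true(all(sqrt(loci$x^2 + loci$y^2) < 1))
  expect_true(all(loci$e_uv >= 0 & loci$e_uv < 1))
})

test_that("the synthetic yellow flower is bee-UV-green through the full chain", {
  spec <- gen_spectrum("bee-uv-green-yellow", noise_sd = 0)
  loci <- spectra_to_loci(spec)
  # independent hue computation from the excitations
  x <- (sqrt(3) / 2) * (loci$e_g - loci$e_uv)
  y <- loci$e_b - (loci$e_uv + loci$e_g) / 2
  theta <- (atan2(x, y) * 180 / pi) %% 360
  expect_true(theta >= 150 && theta < 210)
  expect_equal(loci$sector, "uv-green")
})
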