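# Independent oracles used across the suite. Each is written from the
# definition of the quantity it checks, not by calling the implementation.

# --- sector classification by explicit angle binning -------------------------
oracle_sector <- function(x, y, achromatic_radius = 0.05) {
  deg <- (atan2(x, y) * 180 / pi) %% 360
  # rotate so that bins are [0,60), [60,120), ...: boundary at odd 30s
  shifted <- (deg + 30) %% 360
  bins <- cut(shifted, breaks = seq(0, 360, by = 60), right = FALSE,
              labels = c("blue", "blue-green", "green", "uv-green", "uv",
                         "uv-blue"))
  out <- as.character(bins)
  out[sqrt(x^2 + y^2) < achromatic_radius] <- "achromatic-center"
  out
}

# --- Welch two-sample t closed form -----------------------------------------
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p_less = pt(t, df))
}

# --- focal distinctness bootstrap, re-implemented from the definition --------
oracle_focal_test <- function(loci, focal, n_boot, seed) {
  xy <- as.matrix(loci[, c("x", "y")])
  n <- nrow(xy)
  fi <- match(focal, loci$species)
  stat <- function(coords, f) {
    others <- setdiff(seq_len(nrow(coords)), f)
    dfoc <- sqrt((coords[others, 1] - coords[f, 1])^2 +
                 (coords[others, 2] - coords[f, 2])^2)
    pr <- utils::combn(others, 2)
    drest <- sqrt((coords[pr[1, ], 1] - coords[pr[2, ], 1])^2 +
                  (coords[pr[1, ], 2] - coords[pr[2, ], 2])^2)
    median(dfoc) - median(drest)
  }
  t_obs <- stat(xy, fi)
  others <- setdiff(seq_len(n), fi)
  set.seed(seed)
  t_star <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    f <- sample.int(n - 1, 1)
    t_star[b] <- stat(xy[others, , drop = FALSE], f)
  }
  list(statistic = t_obs, p.value = mean(t_star >= t_obs))
}

# --- exhaustive parsimony on small trees ------------------------------------
# Enumerates every internal-node labeling, returns the minimum change count
# and the min/max number of 0->1 gains among minimum-change labelings.
oracle_parsimony <- function(tree, tip_states) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  n_int <- n_node - n_tip
  labelings <- as.matrix(expand.grid(rep(list(0:1), n_int)))
  full <- cbind(matrix(rep(tip_states, each = nrow(labelings)),
                       nrow = nrow(labelings)), labelings)
  pa <- tree$edge[, 1]
  ch <- tree$edge[, 2]
  changes <- rowSums(full[, pa, drop = FALSE] != full[, ch, drop = FALSE])
  gains <- rowSums(full[, pa, drop = FALSE] == 0 &
                   full[, ch, drop = FALSE] == 1)
  score <- min(changes)
  mpr <- changes == score
  list(score = score,
       min_gains = min(gains[mpr]),
       max_gains = max(gains[mpr]),
       mpr_gains = sort(unique(gains[mpr])),
       mpr_labelings = full[mpr, , drop = FALSE])
}

# random loci scattered in the unit hexagon (rejection-free: scale to disc)
random_loci <- function(n, seed) {
  set.seed(seed)
  r <- sqrt(runif(n)) * 0.95
  th <- runif(n, 0, 2 * pi)
  tibble::tibble(species = paste0("s", seq_len(n)),
                 x = r * sin(th), y = r * cos(th))
}

# tidy spectrum table from a reflectance vector on the default grid
as_spectrum <- function(reflectance, species = "sp", patch = "labellum",
                        replicate_id = "1", wl = seq(300, 700, by = 1)) {
  tibble::tibble(species = species, patch = patch,
                 replicate_id = replicate_id, site = "", habitat = "",
                 wavelength_nm = wl, reflectance = reflectance)
}
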