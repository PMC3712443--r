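#' Spectral classes available from the synthetic flower generator
#'
#' @return Character vector of class names.
#' @export
spectrum_classes <- function() {
  c("bee-uv-green-yellow", "blue", "white", "cream", "red-human",
    "leaf-background")
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Noise-free class template on the given wavelength vector.
.spectrum_template <- function(class, wl,
                               inflection = 520, slope = 15,
                               uv_center = 360, uv_width = 25,
                               uv_height = 0.25, amplitude = 0.7) {
  switch(class,
    # human-yellow flowers of the mimicry guild: long-wavelength reflectance
    # plus a UV bump -> bee-UV-green
    "bee-uv-green-yellow" =
      amplitude * .sigmoid((wl - inflection) / slope) +
        uv_height * exp(-((wl - uv_center) / uv_width)^2),
    "blue" = 0.03 + 0.55 * exp(-((wl - 450) / 35)^2),
    "white" = rep(0.8, length(wl)),
    # human-cream/white with UV absorption: the common bee-blue-green signal
    "cream" = 0.05 + 0.65 * .sigmoid((wl - 420) / 25),
    "red-human" = 0.03 + 0.6 * .sigmoid((wl - 610) / 15),
    "leaf-background" = leaf_background(range = range(wl),
                                        step = wl[2] - wl[1])$value,
    abort(paste0("config error: unknown spectrum class '", class, "'"))
  )
}

#' Generate a synthetic floral reflectance spectrum
#'
#' Draws one reflectance spectrum from a parametric class template plus
#' i.i.d. Gaussian noise, clipped to the physical range `[0, 1]`. The
#' `"bee-uv-green-yellow"` class realises the signal structure of the
#' mimicry guild: a sigmoid long-pass reflectance (human yellow; default
#' inflection 520 nm) combined with a Gaussian UV reflectance bump (default
#' centre 360 nm). The remaining classes provide blue, flat-white,
#' UV-absorbing cream, human-red and green-foliage spectra. Identical seeds
#' give identical spectra.
#'
#' @param class One of [spectrum_classes()].
#' @param species,patch,replicate_id Metadata labels for the output rows.
#' @param noise_sd Gaussian noise standard deviation in reflectance units
#'   (default 0.02, typical of field spectrometry at this scale).
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @param range,step Wavelength grid (nm).
#' @param ... Template parameters (`inflection`, `slope`, `uv_center`,
#'   `uv_width`, `uv_height`, `amplitude`) overriding the defaults.
#' @return Tidy spectrum tibble (one measurement).
#' @export
gen_spectrum <- function(class, species = class, patch = "labellum",
                         replicate_id = "1", noise_sd = 0.02, seed = NULL,
                         range = c(300, 700), step = 1, ...) {
  wl <- seq(range[1], range[2], by = step)
  base <- .spectrum_template(class, wl, ...)
  refl <- if (noise_sd > 0) {
    if (is.null(seed)) abort("seed required when noise_sd > 0")
    withr::with_seed(seed, base + rnorm(length(wl), 0, noise_sd))
  } else {
    base
  }
  tibble(species = species, patch = patch, replicate_id = replicate_id,
         site = "synthetic", habitat = "synthetic",
         wavelength_nm = wl,
         reflectance = pmin(pmax(refl, 0), 1))
}

#' Generate a synthetic flowering community of reflectance spectra
#'
#' Builds a labelled community with a stated class composition. The default
#' composition emulates a Neotropical study plot: bee-UV-green yellow flowers
#' rare (the deceptive orchids and their models), UV-absorbing cream/white
#' flowers (bee-blue-green, the commonest floral colour in community surveys)
#' abundant.
#'
#' @param n Named integer vector: species count per class.
#' @param seed Integer seed.
#' @param noise_sd Per-spectrum Gaussian noise sd.
#' @param range,step Wavelength grid.
#' @return A list with `spectra` (tidy spectrum table, one measurement per
#'   species, patch `"labellum"`) and `truth` (tibble `species`, `class`).
#' @export
gen_community <- function(n = c("bee-uv-green-yellow" = 3, "blue" = 4,
                                "white" = 3, "cream" = 9, "red-human" = 2),
                          seed, noise_sd = 0.02,
                          range = c(300, 700), step = 1) {
  if (missing(seed)) abort("seed is required")
  stopifnot(sum(n) >= 1)
  bad <- setdiff(names(n), spectrum_classes())
  if (length(bad)) abort(paste0("config error: unknown class ", bad[1]))
  specs <- vector("list", sum(n))
  truth <- vector("list", sum(n))
  i <- 0
  for (cl in names(n)) {
    for (j in seq_len(n[[cl]])) {
      i <- i + 1
      sp <- sprintf("%s_%02d", gsub("[^a-z]+", "_", cl), j)
      seed_i <- as.integer((as.numeric(seed) * 1009 + i) %% 2147483647)
      specs[[i]] <- gen_spectrum(cl, species = sp, noise_sd = noise_sd,
                                 seed = seed_i,
                                 range = range, step = step)
      truth[[i]] <- tibble(species = sp, class = cl)
    }
  }
  list(spectra = bind_rows(specs), truth = bind_rows(truth))
}

#' Generate a community of colour loci directly
#'
#' Places `n` species loci i.i.d. uniformly in a disc of hexagon colour
#' space, optionally displacing one focal species; a minimal stand-in for a
#' colour community used to calibrate the distinctness bootstrap.
#'
#' @param n Number of species.
#' @param radius Disc radius (hexagon units).
#' @param center Disc centre `c(x, y)`.
#' @param focal_shift Displacement (hexagon units) applied to the first
#'   species along +x; 0 keeps the focal exchangeable with the community.
#' @param seed Integer seed.
#' @return Loci tibble (`species`, `x`, `y`), first species named
#'   `"focal"`.
#' @export
gen_loci_disc <- function(n = 20, radius = 0.1, center = c(0, 0),
                          focal_shift = 0, seed) {
  if (missing(seed)) abort("seed is required")
  withr::with_seed(seed, {
    r <- radius * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    tibble(species = c("focal", sprintf("sp_%02d", seq_len(n - 1))),
           x = center[1] + r * cos(th) + c(focal_shift, numeric(n - 1)),
           y = center[2] + r * sin(th))
  })
}

#' Default group mean harmonics for synthetic floral outlines
#'
#' Mean open-curve harmonic coefficients per group. Yellow-flowered orchids
#' and Malpighiaceae models are deliberately close in shape (the convergence
#' the pipeline is meant to detect); other angiosperms are distinct.
#'
#' @param groups Character vector of group names.
#' @return Named list of numeric harmonic vectors.
#' @export
default_group_harmonics <- function(groups) {
  defaults <- list(
    "yellow" = c(0.30, 0.10, 0.02),
    "malpighiaceae" = c(0.28, 0.12, 0.00),
    "non-yellow" = c(0.15, -0.10, 0.05),
    "other" = c(0.12, -0.12, 0.06)
  )
  out <- lapply(groups, function(g) {
    defaults[[g]] %||% abort(paste0("no default harmonics for group '", g,
                                    "'; supply `harmonics`"))
  })
  setNames(out, groups)
}

#' Generate synthetic open floral outlines with group structure
#'
#' Each outline is the graph of a half-period sine series over the chord
#' from (0, 0) to (1, 0):
#' \eqn{y(t) = \sum_k a_k \sin(k \pi t)}, so both anchors stay exactly fixed
#' and every curve is a valid open outline. Group structure comes from group
#' mean harmonic vectors `a`; within-group variation is i.i.d. Gaussian noise
#' on each harmonic coefficient. Identical seeds give identical outlines.
#'
#' @param n_per_group Named integer vector: specimens per group.
#' @param harmonics Named list of mean harmonic vectors per group; default
#'   [default_group_harmonics()].
#' @param sd Within-group standard deviation per harmonic coefficient
#'   (default 0.03).
#' @param m Points per outline (default 100).
#' @param seed Integer seed.
#' @param families Named character vector mapping group to family (default:
#'   the group name).
#' @return A list with `outlines` (tidy outline tibble) and `metadata`
#'   (`specimen_id`, `species`, `group`, `family`).
#' @export
gen_outlines <- function(n_per_group = c("yellow" = 10, "non-yellow" = 10),
                         harmonics = default_group_harmonics(names(n_per_group)),
                         sd = 0.03, m = 100, seed, families = NULL) {
  if (missing(seed)) abort("seed is required")
  if (any(n_per_group < 2)) abort("need at least 2 specimens per group")
  t <- seq(0, 1, length.out = m)
  outlines <- list(); meta <- list(); i <- 0
  withr::with_seed(seed, {
    for (g in names(n_per_group)) {
      a_mean <- harmonics[[g]]
      for (j in seq_len(n_per_group[[g]])) {
        i <- i + 1
        a <- a_mean + rnorm(length(a_mean), 0, sd)
        y <- colSums(a * t(outer(t, seq_along(a), function(tt, k) sin(k * pi * tt))))
        id <- sprintf("%s_%02d", g, j)
        outlines[[i]] <- tibble(specimen_id = id, point_index = seq_len(m),
                                x = t, y = y)
        meta[[i]] <- tibble(specimen_id = id, species = id, group = g,
                            family = unname((families %||% setNames(names(n_per_group),
                                                                    names(n_per_group)))[g]))
      }
    }
  })
  list(outlines = bind_rows(outlines), metadata = bind_rows(meta))
}

#' Generate a random tree with a binary character of known history
#'
#' Simulates a random branching topology and evolves a binary trait on it
#' with recorded ground truth, in one of two modes. In `"planted"` mode
#' (default) the derived state is painted onto a chosen number of disjoint,
#' well-separated clades: every planted clade root is at least
#' `min_separation` edges from every other, which guarantees that no
#' most-parsimonious reconstruction can merge two planted origins, so the
#' true gain count is exactly the number of planted clades and losses are
#' impossible. In `"rates"` mode the trait evolves as a two-state Markov
#' jump process along branches and the realised number of gains (which
#' parsimony may legitimately undercount in the presence of homoplasy) is
#' recorded.
#'
#' @param n_tips Number of tips (default 200).
#' @param gains Number of planted gains (planted mode; default 14).
#' @param mode `"planted"` or `"rates"`.
#' @param gain_rate,loss_rate Jump rates per unit branch length (rates mode).
#' @param clade_sizes Allowed planted clade sizes (tips; default 1:3).
#' @param min_separation Minimum edge-count distance between planted clade
#'   roots (default 6). With clade sizes up to 3 this forbids nesting, and a
#'   counting argument over reconstruction boundaries shows that merging any
#'   subset of planted origins (or absorbing one into an ancestral derived
#'   state, given the root buffer below) is strictly less parsimonious, so
#'   every MPR has exactly the planted number of gains.
#' @param seed Integer seed.
#' @return A list: `tree` (`phylo`), `states` (tibble `tip_name`, `state`,
#'   `genus`), `truth` (list with `n_gains`, `mode`, and planted clade root
#'   nodes where applicable).
#' @export
gen_tree_with_character <- function(n_tips = 200, gains = 14,
                                    mode = c("planted", "rates"),
                                    gain_rate = 0.3, loss_rate = 0.3,
                                    clade_sizes = 1:3, min_separation = 6,
                                    seed) {
  mode <- match.arg(mode)
  if (missing(seed)) abort("seed is required")
  if (n_tips < 4) abort("config error: need at least 4 tips")
  withr::with_seed(seed, {
    tree <- ape::rtree(n_tips)
    if (mode == "planted") {
      res <- .plant_gains(tree, gains, clade_sizes, min_separation)
      state <- res$state
      truth <- list(n_gains = gains, mode = mode,
                    clade_roots = res$clade_roots)
    } else {
      sim <- .simulate_markov_trait(tree, gain_rate, loss_rate)
      state <- sim$state
      truth <- list(n_gains = sim$n_gains, n_losses = sim$n_losses,
                    mode = mode)
    }
  })
  genus <- character(n_tips)
  if (mode == "planted") {
    genus[] <- paste0("bg_", ceiling(seq_len(n_tips) / 10))
    for (i in seq_along(truth$clade_roots)) {
      tips <- .clade_tips(tree, truth$clade_roots[i])
      genus[tips] <- sprintf("gain_genus_%02d", i)
    }
  } else {
    genus[] <- paste0("bg_", ceiling(seq_len(n_tips) / 10))
  }
  list(tree = tree,
       states = tibble(tip_name = tree$tip.label, state = state,
                       genus = genus),
       truth = truth)
}

# tip indices descending from node (node may itself be a tip)
.clade_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  kids <- .children_list(tree)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v <= n_tip) out <- c(out, v) else stack <- c(stack, kids[[v]])
  }
  out
}

.plant_gains <- function(tree, gains, clade_sizes, min_separation) {
  n_tip <- length(tree$tip.label)
  if (gains == 0) {
    return(list(state = integer(n_tip), clade_roots = integer(0)))
  }
  n_node <- max(tree$edge)
  sizes <- vapply(seq_len(n_node), function(v) length(.clade_tips(tree, v)),
                  integer(1))
  root <- n_tip + 1L
  candidates <- which(sizes %in% clade_sizes)
  candidates <- setdiff(candidates, root)
  t1 <- tree; t1$edge.length <- rep(1, nrow(tree$edge))
  topo_d <- ape::dist.nodes(t1)
  # keep planted clade roots >= 2 edges below the root so that an MPR cannot
  # place the derived state ancestrally at no extra cost
  candidates <- candidates[topo_d[candidates, root] >= 2]
  for (attempt in seq_len(100)) {
    order_try <- sample(candidates)
    chosen <- integer(0)
    for (v in order_try) {
      if (all(topo_d[v, chosen] >= min_separation)) {
        chosen <- c(chosen, v)
        if (length(chosen) == gains) break
      }
    }
    if (length(chosen) == gains) {
      state <- integer(n_tip)
      for (v in chosen) state[.clade_tips(tree, v)] <- 1L
      return(list(state = state, clade_roots = chosen))
    }
  }
  abort(paste0("config error: could not plant ", gains,
               " sufficiently separated gains on a ", n_tip, "-tip tree"))
}

.simulate_markov_trait <- function(tree, gain_rate, loss_rate) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  state_at <- integer(n_node)
  state_at[n_tip + 1L] <- 0L
  n_gains <- 0L; n_losses <- 0L
  edge_pre <- ape::reorder.phylo(tree, "cladewise")$edge
  len_pre <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (i in seq_len(nrow(edge_pre))) {
    s <- state_at[edge_pre[i, 1]]
    remaining <- len_pre[i]
    repeat {
      rate <- if (s == 0L) gain_rate else loss_rate
      if (rate <= 0) break
      wait <- stats::rexp(1, rate)
      if (wait > remaining) break
      remaining <- remaining - wait
      if (s == 0L) { s <- 1L; n_gains <- n_gains + 1L }
      else { s <- 0L; n_losses <- n_losses + 1L }
    }
    state_at[edge_pre[i, 2]] <- s
  }
  list(state = state_at[seq_len(n_tip)], n_gains = n_gains,
       n_losses = n_losses)
}
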