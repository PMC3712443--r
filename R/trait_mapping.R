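#' Read a phylogeny from a newick file
#'
#' Thin validated wrapper around [ape::read.tree()]: unresolved nodes are
#' kept as polytomies, duplicate tip names are an error (edge lengths, if
#' present, are ignored by all parsimony operations).
#'
#' @param path Path to a newick file containing one tree.
#' @return An [ape] `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) abort(paste0("parse error: ", conditionMessage(e))))
  if (is.null(tree)) abort("parse error: not a valid newick file")
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  if (anyDuplicated(tree$tip.label)) {
    abort("data error: duplicate tip names in tree")
  }
  tree
}

#' Read a binary tip character from a TSV file
#'
#' @param path TSV with columns `tip_name`, `state` (0/1, blank or NA for
#'   missing) and optionally `genus`.
#' @return Tibble with columns `tip_name`, `state` (integer or NA), and
#'   `genus` when present.
#' @export
read_states_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("tip_name", "state") %in% names(d))) {
    abort("format error: states TSV needs columns tip_name, state")
  }
  d$state <- suppressWarnings(as.integer(d$state))
  if (any(!is.na(d$state) & !d$state %in% 0:1)) {
    abort("data error: states must be 0, 1 or missing")
  }
  d
}

# Normalise a character to an integer vector aligned with tree$tip.label
# (NA = missing, treated as fully ambiguous {0, 1}).
.states_vector <- function(tree, states) {
  if (is.data.frame(states)) {
    nm_col <- intersect(c("tip_name", "tip", "species"), names(states))[1]
    if (is.na(nm_col)) abort("states table needs a tip_name column")
    v <- setNames(as.integer(states$state), as.character(states[[nm_col]]))
  } else {
    v <- setNames(as.integer(states), names(states))
  }
  unknown <- setdiff(names(v), tree$tip.label)
  if (length(unknown)) {
    abort(paste0("data error: scored tip(s) not in tree: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  out <- v[tree$tip.label]
  names(out) <- tree$tip.label
  if (all(is.na(out))) abort("data error: no scored tips")
  if (sum(!is.na(out)) < 2) abort("data error: need at least 2 scored tips")
  out
}

# Children list indexed by node number, from the edge matrix.
.children_list <- function(tree) {
  n_node <- max(tree$edge)
  kids <- vector("list", n_node)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2])
  }
  kids
}

#' Fitch-Hartigan parsimony of a binary character on a tree
#'
#' Computes the parsimony score (minimum number of state changes) of a binary
#' character on a rooted tree, using the Fitch downpass generalised to
#' polytomies after Hartigan: at each internal node, each state is scored by
#' the number of children whose optimal set contains it; the node's set is
#' the states attaining the maximum count `k`, and the score increases by
#' (number of children - k). For bifurcating trees this is exactly the Fitch
#' intersection/union rule. Missing tip states are treated as fully
#' ambiguous. Polytomies are treated as hard (genuinely multifurcating), the
#' appropriate reading for consensus trees with unresolved nodes.
#'
#' For an unordered binary character this minimum-change criterion coincides
#' with linear (Wagner) parsimony.
#'
#' @param tree A rooted `phylo` object (polytomies allowed).
#' @param states Binary tip states: a tibble with `tip_name` and `state`
#'   columns (see [read_states_tsv()]) or a named 0/1 vector; `NA` = missing.
#' @return An object of class `"parsimony_fit"`: `score`, `state_sets`
#'   (per-node downpass sets as a logical matrix with columns `s0`, `s1`),
#'   `root_states` (optimal root states), `n_tips`, plus the tree.
#' @export
fitch_parsimony <- function(tree, states) {
  s <- .states_vector(tree, states)
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  kids <- .children_list(tree)
  sets <- matrix(FALSE, n_node, 2, dimnames = list(NULL, c("s0", "s1")))
  sets[seq_len(n_tip), 1] <- is.na(s) | s == 0L
  sets[seq_len(n_tip), 2] <- is.na(s) | s == 1L
  score <- 0L
  edge_post <- ape::reorder.phylo(tree, "postorder")$edge
  for (p in unique(edge_post[, 1])) {
    ch <- kids[[p]]
    n0 <- sum(sets[ch, 1])
    n1 <- sum(sets[ch, 2])
    k <- max(n0, n1)
    sets[p, ] <- c(n0 == k, n1 == k)
    score <- score + length(ch) - k
  }
  root <- n_tip + 1L
  structure(
    list(score = score,
         state_sets = sets,
         root_states = which(sets[root, ]) - 1L,
         n_tips = n_tip,
         tree = tree),
    class = "parsimony_fit"
  )
}

#' @export
print.parsimony_fit <- function(x, ...) {
  cat(sprintf("Fitch-Hartigan parsimony: score %d on %d tips\n",
              x$score, x$n_tips))
  cat("  optimal root state(s):", paste(x$root_states, collapse = ", "), "\n")
  invisible(x)
}

# Sankoff dynamic program with gain (0 -> 1 transition) bookkeeping.
# Returns cost, gmin, gmax: n_node x 2 matrices (columns = node state 0, 1).
.sankoff_gains <- function(tree, s) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  kids <- .children_list(tree)
  cost <- matrix(Inf, n_node, 2)
  gmin <- matrix(0, n_node, 2)
  gmax <- matrix(0, n_node, 2)
  for (i in seq_len(n_tip)) {
    if (is.na(s[i])) {
      cost[i, ] <- 0
    } else {
      cost[i, s[i] + 1L] <- 0
    }
  }
  edge_post <- ape::reorder.phylo(tree, "postorder")$edge
  for (p in unique(edge_post[, 1])) {
    for (st in 0:1) {
      total <- 0; tmin <- 0; tmax <- 0
      for (ch in kids[[p]]) {
        opt <- cost[ch, ] + c(st != 0, st != 1)
        best <- min(opt)
        tie <- which(opt == best)  # costs are exact integers
        gain_contrib_min <- Inf; gain_contrib_max <- -Inf
        for (t in tie) {
          gadd <- as.integer(st == 0 && (t - 1L) == 1L)
          gain_contrib_min <- min(gain_contrib_min, gmin[ch, t] + gadd)
          gain_contrib_max <- max(gain_contrib_max, gmax[ch, t] + gadd)
        }
        total <- total + best
        tmin <- tmin + gain_contrib_min
        tmax <- tmax + gain_contrib_max
      }
      cost[p, st + 1L] <- total
      gmin[p, st + 1L] <- tmin
      gmax[p, st + 1L] <- tmax
    }
  }
  list(cost = cost, gmin = gmin, gmax = gmax)
}

#' Count independent origins of the derived state by parsimony
#'
#' Among all most-parsimonious reconstructions (MPRs) of a binary character,
#' counts the minimum and maximum number of gains (0 to 1 transitions along
#' edges). The root state is chosen to minimise total changes; when both root
#' states are optimal, both are explored and reported. A gain count is
#' attributed per edge; a root already in state 1 contributes no gain (the
#' derived state is then ancestral), which is why the minimum over MPRs
#' matches an "evolved at least this many times" reading only when the
#' ancestral state is the plesiomorphic 0.
#'
#' The computation is a Sankoff-style dynamic program over (node, state)
#' pairs restricted to reconstructions achieving the global parsimony score;
#' it is exact on arbitrary rooted trees including polytomies.
#'
#' @inheritParams fitch_parsimony
#' @return An object of class `"origin_count"`: `parsimony_score`,
#'   `min_gains`, `max_gains`, `root_states`, and `per_root` (a tibble of
#'   min/max gains conditional on each optimal root state).
#' @export
count_origins <- function(tree, states) {
  s <- .states_vector(tree, states)
  dp <- .sankoff_gains(tree, s)
  root <- length(tree$tip.label) + 1L
  total <- min(dp$cost[root, ])
  opt_states <- which(dp$cost[root, ] == total) - 1L
  per_root <- tibble(
    root_state = opt_states,
    min_gains = dp$gmin[root, opt_states + 1L],
    max_gains = dp$gmax[root, opt_states + 1L]
  )
  structure(
    list(parsimony_score = as.integer(total),
         min_gains = as.integer(min(per_root$min_gains)),
         max_gains = as.integer(max(per_root$max_gains)),
         root_states = opt_states,
         per_root = per_root,
         n_tips = length(tree$tip.label)),
    class = "origin_count"
  )
}

#' @export
print.origin_count <- function(x, ...) {
  cat(sprintf("Parsimony origin count: score %d, gains %d-%d across MPRs\n",
              x$parsimony_score, x$min_gains, x$max_gains))
  cat("  optimal root state(s):", paste(x$root_states, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.origin_count <- function(x, ...) x$per_root

#' @export
glance.origin_count <- function(x, ...) {
  tibble(parsimony_score = x$parsimony_score,
         min_gains = x$min_gains, max_gains = x$max_gains,
         n_tips = x$n_tips)
}

#' Annotate a tree with one most-parsimonious reconstruction
#'
#' Labels every internal node with a reconstructed state drawn from one MPR
#' (chosen deterministically: the optimal root state with the fewest gains,
#' then no-change transitions preferred at ties). Nodes where several states
#' are optimal given the chosen parent state are flagged with a trailing
#' `?`. The annotated tree can be written with [ape::write.tree()].
#'
#' @inheritParams fitch_parsimony
#' @return The `phylo` object with `node.label` set to `"0"`, `"1"`, `"0?"`
#'   or `"1?"`.
#' @export
annotate_tree <- function(tree, states) {
  s <- .states_vector(tree, states)
  dp <- .sankoff_gains(tree, s)
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  root <- n_tip + 1L
  kids <- .children_list(tree)
  total <- min(dp$cost[root, ])
  opt <- which(dp$cost[root, ] == total) - 1L
  root_state <- opt[which.min(dp$gmin[root, opt + 1L])]
  assign_state <- integer(n_node)
  ambiguous <- logical(n_node)
  assign_state[root] <- root_state
  ambiguous[root] <- length(opt) > 1
  # cladewise edge order visits parents before children
  edge_pre <- ape::reorder.phylo(tree, "cladewise")$edge
  for (i in seq_len(nrow(edge_pre))) {
    p <- edge_pre[i, 1]; ch <- edge_pre[i, 2]
    ps <- assign_state[p]
    optc <- dp$cost[ch, ] + c(ps != 0, ps != 1)
    best <- min(optc)
    tie <- which(optc == best) - 1L
    ambiguous[ch] <- length(tie) > 1
    assign_state[ch] <- if (ps %in% tie) ps else tie[1]
  }
  lab <- paste0(assign_state, ifelse(ambiguous, "?", ""))
  tree$node.label <- lab[(n_tip + 1L):n_node]
  tree
}

#' Genus-level summary of the derived floral-colour state
#'
#' Joins tip states to a tip-to-genus table and reports, per genus, how many
#' tips carry the derived (bee-UV-green) state. The count of genera with at
#' least one derived tip is the genus-level reading of "evolved in at least
#' N genera"; the edge-level reading is [count_origins()]. The two need not
#' agree and both are reported by the pipeline.
#'
#' @param states Tibble with columns `tip_name`, `state` and `genus`.
#' @return Tibble per genus (`genus`, `n_tips`, `n_derived`) with attribute
#'   `"n_genera_derived"`.
#' @export
genus_origin_summary <- function(states) {
  d <- as_tibble(states)
  if (!all(c("tip_name", "state", "genus") %in% names(d))) {
    abort("states table needs columns tip_name, state, genus")
  }
  out <- d |>
    group_by(.data$genus) |>
    summarise(n_tips = dplyr::n(),
              n_derived = sum(.data$state == 1, na.rm = TRUE),
              .groups = "drop")
  attr(out, "n_genera_derived") <- sum(out$n_derived > 0)
  out
}
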