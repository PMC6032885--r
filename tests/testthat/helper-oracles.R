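# Independent brute-force oracles used to validate the dynamic-programming
# and parsimony implementations. These enumerate paths / labelings
# explicitly and share no code with the package internals.

AA4 <- c("A", "R", "N", "D")  # small alphabet keeps path enumeration cheap

rand_seq <- function(len, alphabet = AA4) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# exhaustive local alignment with affine gaps: enumerate every alignment
# path from every start cell; gap of length k costs go + k * ge
bf_local_score <- function(a, b, sm, go, ge) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  best <- 0
  rec <- function(i, j, last, sc) {
    if (sc > best) best <<- sc
    if (i <= na && j <= nb)
      rec(i + 1, j + 1, "M", sc + sm[av[i], bv[j]])
    if (j <= nb && last != "S")
      rec(i, j + 1, "I", sc - ge - if (last != "I") go else 0)
    if (i <= na && last != "S")
      rec(i + 1, j, "D", sc - ge - if (last != "D") go else 0)
  }
  for (i in seq_len(na)) for (j in seq_len(nb)) rec(i, j, "S", 0)
  best
}

# exhaustive global query-vs-profile alignment score; profile scores and
# gap costs must mirror align_to_profile's contract
bf_profile_score <- function(q_chars, prof, go, ge) {
  m <- length(q_chars); W <- ncol(prof)
  best <- -Inf
  rec <- function(i, j, last, sc) {
    if (i > m && j > W) { if (sc > best) best <<- sc; return(invisible()) }
    if (i <= m && j <= W)
      rec(i + 1, j + 1, "M", sc + prof[q_chars[i], j])
    if (j <= W)  # gap the column
      rec(i, j + 1, "E", sc - ge - if (last != "E") go else 0)
    if (i <= m)  # drop the residue
      rec(i + 1, j, "F", sc - ge - if (last != "F") go else 0)
  }
  rec(1, 1, "S", 0)
  unname(best)
}

# column scores for a 2-row toy backbone, mirroring the documented rule:
# mean substitution score against non-gap residues, gapped rows contribute
# -gap_extend to the mean
toy_profile_scores <- function(backbone_rows, sm, ge) {
  ch <- do.call(rbind, strsplit(backbone_rows, ""))
  W <- ncol(ch)
  states <- rownames(sm)
  prof <- matrix(0, nrow = length(states), ncol = W,
                 dimnames = list(states, NULL))
  for (j in seq_len(W)) {
    col <- ch[, j]
    res <- col[col != "-"]
    prof[, j] <- (rowSums(sm[, res, drop = FALSE]) -
                    ge * sum(col == "-")) / length(col)
  }
  prof
}

# minimal Dollo loss count by subset enumeration: gain fixed, try loss-edge
# subsets of increasing size until one realises the tip states
bf_dollo_losses <- function(tree, states, gain) {
  ntip <- length(tree$tip.label)
  st <- setNames(rep(NA_integer_, ntip), tree$tip.label)
  st[names(states)] <- as.integer(states)
  reach <- function(losses) {
    # tips reachable from gain without crossing a loss edge
    ok <- logical(ntip)
    walk <- function(node) {
      if (node <= ntip) { ok[node] <<- TRUE; return(invisible()) }
      for (e in which(tree$edge[, 1] == node))
        if (!(e %in% losses)) walk(tree$edge[e, 2])
    }
    walk(gain)
    ok
  }
  feasible <- function(losses) {
    r <- reach(losses)
    ones <- which(st == 1L); zeros <- which(st == 0L)
    all(r[ones]) && !any(r[zeros])
  }
  if (feasible(integer(0))) return(0L)
  below <- which(tree$edge[, 1] %in%
                   c(gain, unlist(phangorn::Descendants(tree, gain, "all"))))
  for (k in seq_len(length(below))) {
    for (comb in asplit(combn(below, k), 2))
      if (feasible(comb)) return(k)
  }
  stop("no feasible loss set")
}

# minimal Fitch change count by exhaustive labeling of internal nodes (and
# of unknown tips, which are free to take either state)
bf_fitch_changes <- function(tree, states) {
  ntip <- length(tree$tip.label)
  st <- setNames(rep(NA_integer_, ntip), tree$tip.label)
  st[names(states)] <- as.integer(states)
  free_tips <- which(is.na(st))
  n_int <- tree$Nnode
  best <- Inf
  grid_int <- expand.grid(rep(list(0:1), n_int))
  grid_tip <- if (length(free_tips)) expand.grid(rep(list(0:1),
                                                     length(free_tips)))
              else data.frame(row.names = 1)
  for (gi in seq_len(nrow(grid_int))) {
    lab <- c(st, unlist(grid_int[gi, ]))
    for (ti in seq_len(max(nrow(grid_tip), 1))) {
      if (length(free_tips)) lab[free_tips] <- unlist(grid_tip[ti, ])
      ch <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
      if (ch < best) best <- ch
    }
  }
  as.integer(best)
}

# random rooted tree with positive branch lengths and sorted-label tips
rand_tree <- function(n, min_bl = 0.1, max_bl = 1) {
  tr <- ape::rtree(n, br = function(k) stats::runif(k, min_bl, max_bl))
  tr
}
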