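# Integer-encode an alignment (rows = named character vector of equal
# width): 0 = gap, 1..21 = residue state.
.encode_alignment <- function(rows) {
  ch <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  m <- matrix(match(ch, AA21), nrow = nrow(ch))
  m[is.na(m)] <- 0L
  storage.mode(m) <- "integer"
  rownames(m) <- names(rows)
  m
}

#' Poisson-corrected pairwise distance between two aligned rows
#'
#' Over masked-true columns where both rows carry a residue, the mismatch
#' fraction `p` is Poisson-corrected to `d = -ln(1 - p)`. Saturated pairs
#' (`p >= 0.95`) and pairs sharing fewer than `min_shared` columns are
#' assigned the cap distance with a warning flag.
#'
#' @param row_i,row_j aligned residue strings of equal width.
#' @param mask logical column mask (default: all columns).
#' @param cap distance assigned to saturated/uninformative pairs
#'   (default 5.0).
#' @param min_shared minimum shared residue columns (default 10).
#' @return A list: `d`, `shared`, `capped` (logical).
#' @export
pairwise_distance <- function(row_i, row_j, mask = NULL, cap = 5,
                              min_shared = 10) {
  W <- nchar(row_i)
  if (nchar(row_j) != W) stop("rows must have equal width")
  if (is.null(mask)) mask <- rep(TRUE, W)
  if (length(mask) != W) stop("mask width must match rows")
  if (!any(mask)) stop("no masked-true columns")
  m <- .encode_alignment(setNames(c(row_i, row_j), c("i", "j")))
  pc <- .pair_counts_cpp(m, mask)
  shared <- pc$shared[1, 2]
  if (shared < min_shared)
    return(list(d = cap, shared = shared, capped = TRUE))
  p <- pc$mismatch[1, 2] / shared
  if (p >= 0.95) return(list(d = cap, shared = shared, capped = TRUE))
  list(d = -log(1 - p), shared = shared, capped = FALSE)
}

#' Distance matrix over a profile alignment
#'
#' Applies [pairwise_distance()] to every pair of rows (backbone plus
#' augmented) over the masked columns.
#'
#' @param aln a [profile_alignment()], or a named character vector of
#'   aligned rows.
#' @param mask logical column mask; defaults to the alignment's own mask.
#' @inheritParams pairwise_distance
#' @return A symmetric numeric matrix with zero diagonal; attribute
#'   `"shared"` holds the per-pair shared-column counts and `"capped"` the
#'   saturation flags.
#' @export
distance_matrix <- function(aln, mask = NULL, cap = 5, min_shared = 10) {
  rows <- if (inherits(aln, "profile_alignment")) {
    if (is.null(mask)) mask <- aln$mask
    c(aln$backbone, aln$augmented)
  } else aln
  if (is.null(mask)) mask <- rep(TRUE, nchar(rows[1]))
  if (!any(mask)) stop("no masked-true columns")
  m <- .encode_alignment(rows)
  pc <- .pair_counts_cpp(m, mask)
  shared <- pc$shared
  p <- ifelse(shared > 0, pc$mismatch / pmax(shared, 1L), 1)
  capped <- shared < min_shared | p >= 0.95
  D <- ifelse(capped, cap, -log(1 - pmin(p, 0.9499)))
  diag(D) <- 0
  diag(capped) <- FALSE
  dimnames(D) <- dimnames(shared) <- dimnames(capped) <-
    list(names(rows), names(rows))
  attr(D, "shared") <- shared
  attr(D, "capped") <- capped
  D
}

#' Neighbor-joining tree with deterministic tie-breaking
#'
#' Canonical Saitou-Nei agglomeration on a symmetric distance matrix.
#' Exact ties in the Q criterion are broken toward the lexicographically
#' smallest joined pair of cluster labels (a cluster is labelled by its
#' smallest member id). Negative estimated branch lengths are clamped to 0
#' with the deficit moved to the sister branch, keeping the tree metric.
#'
#' @param D symmetric numeric matrix with dimnames (>= 3 taxa).
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  n <- nrow(D)
  if (is.null(rownames(D))) stop("distance matrix must have dimnames")
  if (n < 3) stop("need at least 3 taxa")
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  # active clusters carried as newick substrings; each labelled by its
  # lexicographically smallest member id for tie-breaking
  sub <- rownames(D)
  labkey <- rownames(D)
  Dm <- D
  while (nrow(Dm) > 3) {
    r <- nrow(Dm)
    rs <- rowSums(Dm)
    Q <- (r - 2) * Dm - outer(rs, rs, "+")
    diag(Q) <- Inf
    cand <- which(Q == min(Q), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(ij) {
      p <- sort(c(labkey[ij[1]], labkey[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    dij <- Dm[i, j]
    li <- dij / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- dij - li
    # clamp negatives, moving the deficit to the sister branch
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0; if (li < 0) li <- 0 }
    newick <- paste0("(", sub[i], ":", fmt(li), ",", sub[j], ":", fmt(lj), ")")
    dnew <- (Dm[i, ] + Dm[j, ] - dij) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    sub <- c(sub[keep], newick)
    labkey <- c(labkey[keep], min(labkey[c(i, j)]))
    rownames(Dm) <- colnames(Dm) <- labkey
  }
  # final trifurcation (standard unrooted NJ output)
  l1 <- (Dm[1, 2] + Dm[1, 3] - Dm[2, 3]) / 2
  l2 <- (Dm[1, 2] + Dm[2, 3] - Dm[1, 3]) / 2
  l3 <- (Dm[1, 3] + Dm[2, 3] - Dm[1, 2]) / 2
  txt <- paste0("(", sub[1], ":", fmt(l1), ",", sub[2], ":", fmt(l2), ",",
                sub[3], ":", fmt(l3), ");")
  ape::read.tree(text = txt)
}

#' Bootstrap supports for a distance tree
#'
#' Resamples the masked columns with replacement `n_reps` times, rebuilds
#' the NJ tree per replicate, and maps bipartition frequencies (in [0, 1])
#' onto the full-data NJ tree. A bipartition absent from every replicate
#' has support 0. Deterministic given `seed`.
#'
#' @param aln a [profile_alignment()] (or named character rows).
#' @param n_reps number of pseudoreplicates (default 100).
#' @param seed integer RNG seed.
#' @param mask,cap,min_shared passed to [distance_matrix()].
#' @return The full-data NJ `phylo` tree with supports in `node.label`
#'   (empty for the root).
#' @export
bootstrap_support <- function(aln, n_reps = 100, seed = 1, mask = NULL,
                              cap = 5, min_shared = 10) {
  stopifnot(n_reps >= 1)
  rows <- if (inherits(aln, "profile_alignment")) {
    if (is.null(mask)) mask <- aln$mask
    c(aln$backbone, aln$augmented)
  } else aln
  W <- nchar(rows[1])
  if (is.null(mask)) mask <- rep(TRUE, W)
  cols <- which(mask)
  chars <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  full <- neighbor_joining(distance_matrix(rows, mask = mask, cap = cap,
                                           min_shared = min_shared))
  reps <- vector("list", n_reps)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  for (b in seq_len(n_reps)) {
    bcols <- sample(cols, length(cols), replace = TRUE)
    brows <- setNames(apply(chars[, bcols, drop = FALSE], 1, paste,
                            collapse = ""), names(rows))
    reps[[b]] <- neighbor_joining(distance_matrix(brows, cap = cap,
                                                  min_shared = min_shared))
  }
  part <- ape::prop.part(reps)
  cnt <- ape::prop.clades(full, part = part, rooted = FALSE)
  cnt[is.na(cnt)] <- 0
  supports <- cnt / n_reps
  full$node.label <- as.character(supports)
  full$node.label[1] <- ""   # root of the unrooted representation
  full
}

#' Remove long-branching tips from a tree
#'
#' A tip's divergence is measured rooting-free as its median path length
#' to every other tip (robust to other outliers); tips whose divergence
#' exceeds `factor` times the median divergence over all tips are removed
#' iteratively (worst first, recomputing after each removal). Tips named in `anchors` (e.g. backbone sequences)
#' are never removed; an over-long anchor is retained with a warning.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @param factor removal threshold multiplier (> 1; default 3).
#' @param anchors character vector of protected tip labels.
#' @return A list: `tree` (pruned), `removed` (character vector).
#' @export
prune_long_branches <- function(tree, factor = 3, anchors = character(0)) {
  stopifnot(factor > 1)
  removed <- character(0)
  repeat {
    if (length(tree$tip.label) < 4) {
      if (length(removed) > 0)
        warning("pruning stopped: would leave fewer than 3 tips")
      break
    }
    D <- ape::cophenetic.phylo(tree)
    avg <- vapply(seq_len(nrow(D)), function(i)
      stats::median(D[i, -i]), numeric(1))
    names(avg) <- rownames(D)
    med <- stats::median(avg)
    over_lab <- names(avg)[avg > factor * med]
    if (length(over_lab) == 0) break
    prot <- intersect(over_lab, anchors)
    if (length(prot) > 0)
      warning("long-branching backbone anchor(s) retained: ",
              paste(prot, collapse = ", "))
    cand <- setdiff(over_lab, anchors)
    if (length(cand) == 0) break
    worst <- cand[which.max(avg[cand])]
    tree <- ape::drop.tip(tree, worst)
    removed <- c(removed, worst)
  }
  list(tree = tree, removed = removed)
}

#' Read a gene tree from newick, normalising support dialects
#'
#' Internal-node labels are parsed as supports. Both the 0-1 and 0-100
#' dialects are accepted: when any numeric label exceeds 1 the whole set is
#' divided by 100. Non-numeric labels are left untouched.
#'
#' @param x newick text, or a path to a newick file.
#' @return A `phylo` tree; numeric supports (0-1) in `node.label`.
#' @export
read_gene_tree <- function(x) {
  tr <- if (file.exists(x[1]) && !grepl("\\(", x[1])) ape::read.tree(file = x)
        else ape::read.tree(text = x)
  if (is.null(tr)) stop("malformed newick input")
  if (!is.null(tr$node.label)) {
    sup <- suppressWarnings(as.numeric(tr$node.label))
    if (any(!is.na(sup))) {
      if (max(sup, na.rm = TRUE) > 1) sup <- sup / 100
      tr$node.label <- ifelse(is.na(sup), tr$node.label, as.character(sup))
    }
  }
  tr
}

#' Write a gene tree to newick
#'
#' Branch lengths are emitted at 6-decimal precision; supports, when
#' present, are written as internal node labels in the 0-1 dialect.
#'
#' @param tree a `phylo` tree.
#' @param path optional output file; when `NULL` the newick text is
#'   returned.
#' @return newick text (invisibly when written to file).
#' @export
write_gene_tree <- function(tree, path = NULL) {
  tree$edge.length <- round(tree$edge.length, 6)
  txt <- ape::write.tree(tree)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}
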