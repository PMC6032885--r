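#' Backbone catalogue: subfamily labels for curated backbone sequences
#'
#' Maps every backbone sequence id to its subfamily, names the reference
#' anchor used for cross-tree branch-length normalisation, and declares
#' megaclade fallbacks (supported clades uniting two subfamilies, used when
#' a query groups with both members but neither alone).
#'
#' @param seq_id,subfamily character vectors (parallel).
#' @param anchor_id,anchor_clade reference anchor sequence and its
#'   subfamily; defaults `"HsRIN2"` / `"RIN"` (the RIN clade is restricted
#'   to Holozoa, so its internal branch lengths are stable across trees).
#' @param megaclades named list: megaclade label -> member subfamilies;
#'   default unites Rabex5 and GAPVD1.
#' @return A `backbone_catalog` data.frame with attributes.
#' @export
backbone_catalog <- function(seq_id, subfamily, anchor_id = "HsRIN2",
                             anchor_clade = "RIN",
                             megaclades = list(
                               "Rabex5+GAPVD1" = c("Rabex5", "GAPVD1"))) {
  x <- data.frame(seq_id = as.character(seq_id),
                  subfamily = as.character(subfamily),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(x$seq_id)) stop("duplicate backbone ids")
  if (anchor_id %in% x$seq_id &&
      x$subfamily[x$seq_id == anchor_id] != anchor_clade)
    stop("anchor_id does not belong to anchor_clade")
  structure(x, anchor_id = anchor_id, anchor_clade = anchor_clade,
            megaclades = megaclades,
            class = c("backbone_catalog", "data.frame"))
}

# numeric support per internal node; missing/blank labels count as 1
# (unannotated nodes -- e.g. the root of an unrooted representation --
# never block an assignment on their own)
.support_vec <- function(tree) {
  n_int <- tree$Nnode
  if (is.null(tree$node.label)) return(rep(1, n_int))
  s <- suppressWarnings(as.numeric(tree$node.label))
  s[is.na(s)] <- 1
  s
}

# Choose the working root for an unrooted tree: the edge whose bipartition
# splits the fewest backbone subfamilies (ties: most even backbone split,
# then lowest edge index), then root the tree there. Mirrors reading a
# tree "from the outgroup side" so that each backbone subfamily forms a
# clade wherever the tree allows it.
.working_root <- function(tree, catalog) {
  bb <- catalog$seq_id[catalog$seq_id %in% tree$tip.label]
  sub <- setNames(catalog$subfamily, catalog$seq_id)[bb]
  ntip <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, seq_len(ntip + tree$Nnode), type = "tips")
  best <- NULL
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    side <- tree$tip.label[desc[[child]]]
    if (length(side) == 0 || length(side) == ntip) next
    in_side <- bb %in% side
    split_count <- sum(vapply(split(in_side, sub), function(v)
      any(v) && !all(v), logical(1)))
    balance <- abs(sum(in_side) - (length(bb) - sum(in_side)))
    key <- c(split_count, balance, e)
    if (is.null(best) || key[1] < best[1] ||
        (key[1] == best[1] && key[2] < best[2])) {
      best <- key
      best_side <- side
    }
  }
  if (is.null(best)) return(tree)
  rooted <- tryCatch(
    ape::root(tree, outgroup = best_side, resolve.root = TRUE),
    error = function(e) tree)
  rooted
}

# descendant tip labels per node of a rooted tree
.node_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  d <- phangorn::Descendants(tree, seq_len(ntip + tree$Nnode), type = "tips")
  lapply(d, function(i) tree$tip.label[i])
}

# path length from a tip to one of its ancestor nodes
.tip_to_node <- function(tree, tip_label, node) {
  tip <- match(tip_label, tree$tip.label)
  total <- 0
  cur <- tip
  while (cur != node) {
    e <- which(tree$edge[, 2] == cur)
    if (length(e) == 0) stop("node is not an ancestor of tip")
    total <- total + tree$edge.length[e]
    cur <- tree$edge[e, 1]
  }
  total
}

#' Branch-length depth of a tip within its clade
#'
#' Sum of branch lengths from `tip` to the base (MRCA) of `clade_tips`.
#' For a single-tip clade the base is the tip's parent, so the depth is the
#' pendant edge length.
#'
#' @param tree a rooted `phylo` tree with branch lengths.
#' @param tip a tip label in `clade_tips`.
#' @param clade_tips tip labels forming a clade under the current rooting.
#' @return Numeric depth.
#' @export
clade_depth <- function(tree, tip, clade_tips) {
  if (!tip %in% clade_tips) stop("tip must be a member of clade_tips")
  idx <- match(clade_tips, tree$tip.label)
  if (anyNA(idx)) stop("clade_tips absent from tree")
  if (length(idx) == 1) {
    e <- which(tree$edge[, 2] == idx)
    return(tree$edge.length[e])
  }
  base <- ape::getMRCA(tree, clade_tips)
  ntip <- length(tree$tip.label)
  members <- tree$tip.label[phangorn::Descendants(tree, base, "tips")[[1]]]
  if (!setequal(members, clade_tips))
    stop("clade_tips are not monophyletic under this rooting")
  .tip_to_node(tree, tip, base)
}

#' Anchor-normalised clade depth
#'
#' [clade_depth()] of the tip divided by the depth of the catalogue's
#' reference anchor within its own clade, making depths comparable across
#' trees. When the anchor is absent from the tree, the raw depth is
#' returned with the `normalized` flag set to `FALSE`.
#'
#' @inheritParams clade_depth
#' @param catalog a [backbone_catalog()].
#' @return A list: `ratio`, `normalized` (logical).
#' @export
normalized_depth <- function(tree, tip, clade_tips, catalog) {
  d <- clade_depth(tree, tip, clade_tips)
  anchor <- attr(catalog, "anchor_id")
  if (!anchor %in% tree$tip.label)
    return(list(ratio = d, normalized = FALSE))
  anchor_tips <- intersect(
    catalog$seq_id[catalog$subfamily == attr(catalog, "anchor_clade")],
    tree$tip.label)
  base <- if (length(anchor_tips) > 1) ape::getMRCA(tree, anchor_tips) else
    tree$edge[which(tree$edge[, 2] == match(anchor, tree$tip.label)), 1]
  ad <- .tip_to_node(tree, anchor, base)
  if (ad <= 0) stop("anchor depth is zero: degenerate tree")
  list(ratio = d / ad, normalized = TRUE)
}

#' Assign query sequences to subfamilies via backbone-anchored clades
#'
#' For every non-backbone tip, ascends from the tip under the working
#' rooting until reaching the smallest clade that contains at least one
#' backbone member of exactly one subfamily, no backbone members of any
#' other subfamily, and support at or above `min_support`. If no pure
#' single-subfamily clade qualifies, the same test is repeated with each
#' megaclade's member subfamilies merged (fallback flag set); otherwise the
#' sequence is `"unclassified"`. Classified queries also receive an
#' anchor-normalised depth to the base of their subfamily clade, for
#' Scrollsaw representative selection.
#'
#' @param tree a `phylo` gene tree (unrooted accepted; a working root is
#'   chosen on the edge separating backbone subfamilies most cleanly).
#' @param catalog a [backbone_catalog()].
#' @param min_support minimum clade support in [0, 1] (default 0.80).
#' @return A data.frame: `seq_id`, `subfamily`, `support`, `node`,
#'   `megaclade` (logical), `depth`, `normalized_depth`, `normalized`
#'   (logical: anchor present).
#' @export
assign_subfamilies <- function(tree, catalog, min_support = 0.80) {
  stopifnot(min_support >= 0, min_support <= 1)
  tree <- .working_root(tree, catalog)
  ntip <- length(tree$tip.label)
  bb <- intersect(catalog$seq_id, tree$tip.label)
  if (length(bb) == 0) stop("tree contains no backbone tips")
  submap <- setNames(catalog$subfamily, catalog$seq_id)
  queries <- setdiff(tree$tip.label, bb)
  supports <- .support_vec(tree)
  tips_of <- .node_tips(tree)
  megas <- attr(catalog, "megaclades")

  classify_one <- function(q, merge_map) {
    # merge_map: subfamily -> effective label (identity or megaclade)
    anc <- phangorn::Ancestors(tree, match(q, tree$tip.label), "all")
    for (node in anc) {
      members <- tips_of[[node]]
      bb_in <- intersect(members, bb)
      if (length(bb_in) == 0) next
      fams <- unique(merge_map[submap[bb_in]])
      if (length(fams) > 1) return(NULL)   # impure: no larger clade can help
      sup <- supports[node - ntip]
      if (sup >= min_support)
        return(list(subfamily = fams, node = node, support = sup))
    }
    NULL
  }

  ident <- setNames(unique(catalog$subfamily), unique(catalog$subfamily))
  out <- vector("list", length(queries))
  for (k in seq_along(queries)) {
    q <- queries[k]
    hit <- classify_one(q, ident)
    mega <- FALSE
    if (is.null(hit) && length(megas) > 0) {
      for (mg in names(megas)) {
        mm <- ident
        mm[megas[[mg]]] <- mg
        hit <- classify_one(q, mm)
        if (!is.null(hit) && hit$subfamily == mg) { mega <- TRUE; break }
        hit <- NULL
      }
    }
    if (is.null(hit)) {
      out[[k]] <- data.frame(seq_id = q, subfamily = "unclassified",
                             support = NA_real_, node = NA_integer_,
                             megaclade = FALSE, depth = NA_real_,
                             normalized_depth = NA_real_, normalized = NA,
                             stringsAsFactors = FALSE)
    } else {
      out[[k]] <- data.frame(seq_id = q, subfamily = hit$subfamily,
                             support = hit$support, node = hit$node,
                             megaclade = mega, depth = NA_real_,
                             normalized_depth = NA_real_, normalized = NA,
                             stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(seq_id = character(), subfamily = character(),
               support = numeric(), node = integer(), megaclade = logical(),
               depth = numeric(), normalized_depth = numeric(),
               normalized = logical(), stringsAsFactors = FALSE)

  # depths: base of each assigned subfamily = MRCA of its backbone tips
  # and the queries assigned to it (megaclades: member backbone tips)
  anchor <- attr(catalog, "anchor_id")
  anchor_clade <- attr(catalog, "anchor_clade")
  anchor_depth <- NA_real_
  if (anchor %in% tree$tip.label) {
    a_tips <- intersect(catalog$seq_id[catalog$subfamily == anchor_clade],
                        tree$tip.label)
    a_base <- if (length(a_tips) > 1) ape::getMRCA(tree, a_tips) else
      tree$edge[which(tree$edge[, 2] == match(anchor, tree$tip.label)), 1]
    anchor_depth <- .tip_to_node(tree, anchor, a_base)
  }
  for (fam in setdiff(unique(res$subfamily), "unclassified")) {
    rows <- which(res$subfamily == fam)
    fam_members <- if (fam %in% names(megas)) megas[[fam]] else fam
    base_tips <- c(intersect(catalog$seq_id[catalog$subfamily %in% fam_members],
                             tree$tip.label),
                   res$seq_id[rows])
    base <- if (length(base_tips) > 1) ape::getMRCA(tree, base_tips) else
      tree$edge[which(tree$edge[, 2] == match(base_tips, tree$tip.label)), 1]
    for (r in rows) {
      d <- .tip_to_node(tree, res$seq_id[r], base)
      res$depth[r] <- d
      if (!is.na(anchor_depth) && anchor_depth > 0) {
        res$normalized_depth[r] <- d / anchor_depth
        res$normalized[r] <- TRUE
      } else {
        res$normalized_depth[r] <- d
        res$normalized[r] <- FALSE
      }
    }
  }
  rownames(res) <- NULL
  res
}

#' Scrollsaw representative selection
#'
#' For each (group, subfamily) combination present in the assignments,
#' selects exactly the sequence with the minimal normalised depth --- the
#' slowest-evolving member of its clade in its lineage. Exact ties resolve
#' to the lexicographically smaller sequence id. Unclassified sequences are
#' ignored.
#'
#' @param assignments a data.frame from [assign_subfamilies()] (columns
#'   `seq_id`, `subfamily`, `normalized_depth`), possibly pooled over
#'   several trees.
#' @param grouping named character vector: `seq_id` -> group label
#'   (supergroup or subclade).
#' @return A data.frame: `group`, `subfamily`, `seq_id`,
#'   `normalized_depth`.
#' @export
select_representatives <- function(assignments, grouping) {
  a <- assignments[assignments$subfamily != "unclassified" &
                     !is.na(assignments$normalized_depth), , drop = FALSE]
  if (nrow(a) == 0)
    return(data.frame(group = character(), subfamily = character(),
                      seq_id = character(), normalized_depth = numeric(),
                      stringsAsFactors = FALSE))
  grp <- grouping[a$seq_id]
  if (anyNA(grp)) stop("every assigned sequence needs a group label")
  a$group <- unname(grp)
  a <- a[order(a$group, a$subfamily, a$normalized_depth, a$seq_id), ]
  key <- paste(a$group, a$subfamily, sep = "\r")
  a <- a[!duplicated(key), c("group", "subfamily", "seq_id",
                             "normalized_depth")]
  rownames(a) <- NULL
  a
}
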