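#' Construct a presence/absence (paralogue count) matrix
#'
#' A `presence_matrix` is an integer matrix of taxa (rows) by characters
#' (columns, usually subfamilies) holding paralogue counts, with `NA` for
#' unknown states, plus per-taxon metadata. Absence can only be asserted
#' for taxa with complete (genome) data: for transcriptome-only taxa a zero
#' count is recorded as `NA` ("unknown"), never 0.
#'
#' @param counts integer matrix with taxa rownames and character colnames.
#' @param taxa data.frame with columns `taxon_id`, `supergroup`,
#'   `eu_domain`, `transcriptome` (logical).
#' @param character_groups optional named list mapping ancestral ("root")
#'   characters to one or more matrix columns (e.g. a megaclade character
#'   spanning the Rabex5, GAPVD1 and fallback columns). Defaults to one
#'   group per column.
#' @return A `presence_matrix` object.
#' @export
presence_matrix <- function(counts, taxa, character_groups = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts needs taxa rownames and character colnames")
  if (!setequal(rownames(counts), taxa$taxon_id))
    stop("taxa metadata must cover exactly the matrix rows")
  taxa <- taxa[match(rownames(counts), taxa$taxon_id), ]
  if (is.null(taxa$eu_domain))
    taxa$eu_domain <- unname(SUPERGROUP_DOMAIN[taxa$supergroup])
  if (anyNA(taxa$eu_domain)) stop("missing eu_domain labels")
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  if (any(is.na(counts) & !taxa$transcriptome))
    stop("NA (unknown) states are only allowed for transcriptome taxa")
  if (is.null(character_groups))
    character_groups <- setNames(as.list(colnames(counts)), colnames(counts))
  structure(list(counts = counts, taxa = taxa,
                 character_groups = character_groups),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("presence_matrix:", nrow(x$counts), "taxa x", ncol(x$counts),
      "characters;", sum(x$taxa$transcriptome), "transcriptome taxa\n")
  invisible(x)
}

#' Tally subfamily assignments into a presence matrix
#'
#' Counts classified sequences per (taxon, subfamily); unclassified
#' sequences are tallied in their own column. Transcriptome taxa with zero
#' hits for a character receive `NA` rather than 0.
#'
#' @param assignments data.frame with columns `seq_id`, `subfamily`, and
#'   `taxon_id` (or a separate `taxon_of` lookup).
#' @param taxa data.frame as in [presence_matrix()], defining the full row
#'   set (including taxa with no sequences at all).
#' @param taxon_of optional named vector `seq_id` -> `taxon_id`, used when
#'   `assignments` lacks a `taxon_id` column.
#' @return A `presence_matrix`.
#' @export
build_matrix <- function(assignments, taxa, taxon_of = NULL) {
  a <- assignments
  if (!"taxon_id" %in% names(a)) {
    if (is.null(taxon_of)) stop("need taxon_id column or taxon_of lookup")
    a$taxon_id <- unname(taxon_of[a$seq_id])
  }
  if (anyNA(a$taxon_id)) stop("assignment with unknown taxon")
  if (!all(a$taxon_id %in% taxa$taxon_id)) stop("assignment taxon not in taxa")
  fams <- sort(unique(a$subfamily))
  fams <- c(setdiff(fams, "unclassified"),
            if ("unclassified" %in% fams) "unclassified")
  counts <- matrix(0L, nrow = nrow(taxa), ncol = length(fams),
                   dimnames = list(taxa$taxon_id, fams))
  if (nrow(a) > 0) {
    tab <- table(factor(a$taxon_id, levels = taxa$taxon_id),
                 factor(a$subfamily, levels = fams))
    counts[] <- as.integer(tab)
  }
  counts[counts == 0L & taxa$transcriptome[match(rownames(counts),
                                                 taxa$taxon_id)]] <- NA_integer_
  presence_matrix(counts, taxa)
}

# union presence per root character over its matrix columns:
# 1 present, 0 absent, NA unknown
.character_states <- function(pm) {
  out <- sapply(pm$character_groups, function(cols) {
    sub <- pm$counts[, cols, drop = FALSE]
    present <- apply(sub, 1, function(v) any(v >= 1, na.rm = TRUE))
    unknown <- apply(sub, 1, function(v) all(is.na(v)))
    ifelse(present, 1L, ifelse(unknown, NA_integer_, 0L))
  })
  rownames(out) <- rownames(pm$counts)
  out
}

#' Infer the ancestral (LECA) gene complement from a presence matrix
#'
#' Under the root-agnostic default (`rule = "two-of-three"`), a character is
#' placed in the LECA complement iff it is present (count >= 1) in taxa of
#' at least two of the three eukaryote domains (Amorphea, Diaphoretickes,
#' Excavata), so that the character must straddle the root wherever the
#' root falls among the three. `rule = "strict"` applies the narrower
#' Amorphea-plus-Excavata requirement. Unknown (`NA`) states never count as
#' presence.
#'
#' @param pm a [presence_matrix()].
#' @param rule `"two-of-three"` (default) or `"strict"`.
#' @return Character vector of ancestral characters (root-character names
#'   from the matrix's `character_groups`).
#' @export
infer_ancestral_set <- function(pm, rule = c("two-of-three", "strict")) {
  rule <- match.arg(rule)
  st <- .character_states(pm)
  dom <- pm$taxa$eu_domain[match(rownames(st), pm$taxa$taxon_id)]
  doms <- c("Amorphea", "Diaphoretickes", "Excavata")
  pres <- sapply(doms, function(d)
    colSums(st[dom == d, , drop = FALSE] == 1L, na.rm = TRUE) > 0)
  if (is.null(dim(pres))) pres <- matrix(pres, nrow = 1,
                                         dimnames = list(colnames(st), doms))
  keep <- if (rule == "two-of-three") rowSums(pres) >= 2 else
    pres[, "Amorphea"] & pres[, "Excavata"]
  colnames(st)[keep]
}

#' Dollo-parsimony gain/loss mapping of one character
#'
#' Places the single gain at the MRCA of the presence-1 tips (or at the
#' root when `gain_at_root = TRUE`) and finds the minimal set of loss edges
#' below the gain such that exactly the presence-1 tips retain the
#' character. Unknown tips are free: they never force a loss, and a
#' maximal presence-free subtree containing only unknown tips needs no loss
#' edge.
#'
#' @param tree a rooted `phylo` species tree.
#' @param states named vector over the tips: 1 present, 0 absent, `NA`
#'   unknown. Tips absent from `states` are treated as unknown.
#' @param gain_at_root force the gain onto the root (e.g. when the
#'   ancestral-set rule places the character in the LECA).
#' @return A list: `gain` (node id, or `NA` when no tip is present),
#'   `losses` (matrix of loss edges, columns `parent`, `child`),
#'   `n_losses`.
#' @export
dollo_map <- function(tree, states, gain_at_root = FALSE) {
  ntip <- length(tree$tip.label)
  st <- rep(NA_integer_, ntip)
  names(st) <- tree$tip.label
  common <- intersect(names(states), tree$tip.label)
  st[common] <- as.integer(states[common])
  ones <- which(st == 1L)
  if (length(ones) == 0)
    return(list(gain = NA_integer_,
                losses = matrix(integer(0), ncol = 2,
                                dimnames = list(NULL, c("parent", "child"))),
                n_losses = 0L))
  root <- ntip + 1L
  gain <- if (gain_at_root || length(ones) == ntip) root
          else if (length(ones) == 1) ones[[1]]
          else ape::getMRCA(tree, ones)
  desc <- phangorn::Descendants(tree, seq_len(ntip + tree$Nnode), "tips")
  has_one <- vapply(desc, function(d) any(st[d] == 1L, na.rm = TRUE),
                    logical(1))
  has_zero <- vapply(desc, function(d) any(!is.na(st[d]) & st[d] == 0L),
                     logical(1))
  # edges strictly below the gain whose parent subtree retains the
  # character but whose child subtree has no presence and at least one
  # known absence -> one loss each (minimal by construction)
  below <- if (gain <= ntip) integer(0) else
    c(gain, unlist(phangorn::Descendants(tree, gain, "all")))
  losses <- matrix(integer(0), ncol = 2,
                   dimnames = list(NULL, c("parent", "child")))
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    if (!(p %in% below)) next
    if (has_one[p] || p == gain) {
      if (!has_one[ch] && has_zero[ch]) {
        # only a maximal lost subtree gets the loss (parent still has it)
        losses <- rbind(losses, c(p, ch))
      }
    }
  }
  # drop losses nested inside other loss subtrees
  if (nrow(losses) > 1) {
    keep <- rep(TRUE, nrow(losses))
    for (i in seq_len(nrow(losses))) {
      anc <- phangorn::Ancestors(tree, losses[i, "child"], "all")
      if (any(losses[keep & seq_len(nrow(losses)) != i, "child"] %in% anc))
        keep[i] <- FALSE
    }
    losses <- losses[keep, , drop = FALSE]
  }
  list(gain = gain, losses = losses, n_losses = nrow(losses))
}

#' Fitch-parsimony minimal change count for a binary character
#'
#' Standard two-pass equal-weight parsimony on a rooted tree. Unknown tips
#' are marginalised by assigning them the full state set, so they never
#' contribute changes.
#'
#' @inheritParams dollo_map
#' @return Integer: the minimal number of state changes.
#' @export
fitch_changes <- function(tree, states) {
  ntip <- length(tree$tip.label)
  st <- rep(NA_integer_, ntip)
  names(st) <- tree$tip.label
  common <- intersect(names(states), tree$tip.label)
  st[common] <- as.integer(states[common])
  nnode <- ntip + tree$Nnode
  sets <- vector("list", nnode)
  for (i in seq_len(ntip))
    sets[[i]] <- if (is.na(st[i])) c(0L, 1L) else st[i]
  changes <- 0L
  # postorder edge traversal lists every node's child edges before its own
  # parent edge, so parents appear children-first
  for (node in unique(tree$edge[ape::postorder(tree), 1])) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    s <- sets[[kids[1]]]
    for (k in kids[-1]) {
      inter <- intersect(s, sets[[k]])
      if (length(inter) == 0) {
        s <- union(s, sets[[k]])
        changes <- changes + 1L
      } else s <- inter
    }
    sets[[node]] <- s
  }
  changes
}

#' Count independent acquisitions of a domain architecture
#'
#' Each phylogenetically distinct subfamily context carrying the
#' architecture is one character (cross-character identity is already
#' excluded by the gene phylogeny); [dollo_map()] allows each character a
#' single gain, so the number of characters with at least one presence tip
#' is the number of independent acquisitions.
#'
#' @param pm a [presence_matrix()] whose columns are
#'   subfamily-by-architecture characters.
#' @param tree the rooted species tree over the matrix taxa.
#' @return Integer count of independent gains.
#' @export
count_independent_acquisitions <- function(pm, tree) {
  st <- .character_states(pm)
  gains <- 0L
  for (ch in colnames(st)) {
    m <- dollo_map(tree, st[, ch])
    if (!is.na(m$gain)) gains <- gains + 1L
  }
  gains
}

#' Map gains and losses for every character of a presence matrix
#'
#' Runs [dollo_map()] per root character; characters in `leca_set` have
#' their gain forced to the root.
#'
#' @param pm a [presence_matrix()].
#' @param tree rooted `phylo` species tree.
#' @param leca_set character names whose gain is placed at the root
#'   (e.g. the output of [infer_ancestral_set()]).
#' @return A data.frame event map: `character`, `event` (`gain`/`loss`),
#'   `node` (gain node), `parent`, `child` (loss edge).
#' @export
event_map <- function(pm, tree, leca_set = character(0)) {
  st <- .character_states(pm)
  rows <- list()
  for (ch in colnames(st)) {
    m <- dollo_map(tree, st[, ch], gain_at_root = ch %in% leca_set)
    if (is.na(m$gain)) next
    rows[[length(rows) + 1L]] <- data.frame(
      character = ch, event = "gain", node = m$gain,
      parent = NA_integer_, child = NA_integer_, stringsAsFactors = FALSE)
    if (m$n_losses > 0)
      rows[[length(rows) + 1L]] <- data.frame(
        character = ch, event = "loss", node = NA_integer_,
        parent = m$losses[, "parent"], child = m$losses[, "child"],
        stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(character = character(), event = character(),
                      node = integer(), parent = integer(), child = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read/write a presence matrix as TSV
#'
#' Taxa are rows; the first four columns are `taxon_id`, `supergroup`,
#' `eu_domain`, `transcriptome`; remaining columns are characters with
#' `NA` for unknown.
#'
#' @param pm a [presence_matrix()].
#' @param path file path.
#' @return `write_presence_tsv` returns `path` invisibly;
#'   `read_presence_tsv` a `presence_matrix`.
#' @export
write_presence_tsv <- function(pm, path) {
  df <- cbind(pm$taxa[, c("taxon_id", "supergroup", "eu_domain",
                          "transcriptome")],
              as.data.frame(pm$counts))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_presence_tsv
#' @param character_groups as in [presence_matrix()].
#' @export
read_presence_tsv <- function(path, character_groups = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- df[, c("taxon_id", "supergroup", "eu_domain", "transcriptome")]
  counts <- as.matrix(df[, setdiff(names(df), names(meta)), drop = FALSE])
  rownames(counts) <- meta$taxon_id
  presence_matrix(counts, meta, character_groups)
}
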