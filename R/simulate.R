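# fixed supergroup -> eukaryote-domain lookup (tripartite classification)
SUPERGROUP_DOMAIN <- c(
  Holozoa = "Amorphea", Fungi = "Amorphea", Apusozoa = "Amorphea",
  Amoebozoa = "Amorphea", Obazoa = "Amorphea",
  Excavata = "Excavata", Discoba = "Excavata", Metamonada = "Excavata",
  Archaeplastida = "Diaphoretickes", Cryptophyta = "Diaphoretickes",
  SAR = "Diaphoretickes", Stramenopila = "Diaphoretickes",
  Alveolata = "Diaphoretickes", Rhizaria = "Diaphoretickes",
  Haptophyta = "Diaphoretickes")

#' Labelled rooted species tree
#'
#' Couples a rooted `phylo` tree with per-tip taxonomy labels. The
#' eukaryote-domain label of every tip must agree with its supergroup under
#' the fixed tripartite lookup (Amorphea / Diaphoretickes / Excavata).
#'
#' @param tree a rooted `phylo` object with branch lengths >= 0.
#' @param taxa data.frame with columns `taxon_id`, `supergroup`,
#'   `eu_domain` (optional: filled from the lookup), `transcriptome`
#'   (optional, default `FALSE`).
#' @return A `species_tree` list: `tree`, `taxa`.
#' @export
species_tree <- function(tree, taxa) {
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths")
  if (!setequal(tree$tip.label, taxa$taxon_id))
    stop("taxa metadata must cover exactly the tree tips")
  if (is.null(taxa$eu_domain) || all(is.na(taxa$eu_domain)))
    taxa$eu_domain <- unname(SUPERGROUP_DOMAIN[taxa$supergroup])
  if (is.null(taxa$transcriptome)) taxa$transcriptome <- FALSE
  known <- taxa$supergroup %in% names(SUPERGROUP_DOMAIN)
  bad <- known & taxa$eu_domain != SUPERGROUP_DOMAIN[taxa$supergroup]
  if (any(bad, na.rm = TRUE))
    stop("eu_domain inconsistent with supergroup for: ",
         paste(taxa$taxon_id[bad], collapse = ", "))
  if (anyNA(taxa$eu_domain)) stop("missing eu_domain labels")
  structure(list(tree = tree, taxa = taxa), class = "species_tree")
}

#' @export
print.species_tree <- function(x, ...) {
  cat("species_tree:", length(x$tree$tip.label), "taxa,",
      length(unique(x$taxa$supergroup)), "supergroups\n")
  invisible(x)
}

#' Balanced species tree for simulation benchmarks
#'
#' A fully balanced binary tree of `2^depth` tips with equal branch
#' lengths, its tips assigned to eight supergroups in consecutive blocks
#' (four Amorphea, two Excavata, two Diaphoretickes supergroups), giving
#' every eukaryote domain multiple representatives. Deterministic.
#'
#' @param depth tree depth (default 5, i.e. 32 tips).
#' @param branch_length length of every edge (default 0.2 expected
#'   substitutions/site, so root-to-tip depth is `depth * branch_length`).
#' @return A [species_tree()].
#' @export
balanced_species_tree <- function(depth = 5, branch_length = 0.2) {
  n <- 2^depth
  build <- function(lo, hi, d) {
    if (lo == hi) return(sprintf("t%02d:%g", lo, branch_length))
    mid <- (lo + hi) %/% 2
    inner <- paste0("(", build(lo, mid, d + 1), ",",
                    build(mid + 1, hi, d + 1), ")")
    if (d == 0) paste0(inner, ";") else paste0(inner, ":", branch_length)
  }
  tr <- ape::read.tree(text = build(1, n, 0))
  groups <- c("Holozoa", "Fungi", "Apusozoa", "Amoebozoa",
              "Discoba", "Metamonada", "Archaeplastida", "SAR")
  block <- ceiling(n / length(groups))
  sg <- rep(groups, each = block)[seq_len(n)]
  taxa <- data.frame(taxon_id = sprintf("t%02d", seq_len(n)),
                     supergroup = sg, stringsAsFactors = FALSE)
  species_tree(tr, taxa)
}

#' Simulation parameters for gene-family evolution
#'
#' @param subfamilies character vector of subfamily (character) names
#'   present at the family root.
#' @param loss_prob,dup_prob per-branch loss and duplication probabilities
#'   in [0, 1]; defaults 0.2 and 0.1.
#' @param root_presence named 0/1 vector over `subfamilies` (default all 1).
#' @param rate substitution rate scale (> 0) multiplying branch lengths;
#'   default 0.5.
#' @param domain_blocks list of blocks, each `list(name, length, rel_rate)`
#'   with `rel_rate` in (0, 1] (domains evolve no faster than linkers).
#'   Default: one "Vps9" block of 104 residues at relative rate 0.25.
#' @param linker_length residues of fast-evolving linker placed before,
#'   between and after domain blocks (default 100).
#' @param tip_rate optional named vector of per-taxon rate multipliers
#'   applied on pendant gene-tree branches (models lineage-specific
#'   acceleration).
#' @param protected_taxa optional character vector of taxa on whose
#'   lineages loss is suppressed. This conditions the simulation on
#'   survival in a reference lineage, mirroring how real subfamilies are
#'   ascertained: they are defined by their functionally characterised
#'   members, so a subfamily with no surviving reference sequence would
#'   never enter the backbone. Loss draws are still consumed from the RNG
#'   stream, so protection does not shift downstream draws.
#' @param seed integer seed; one global stream drives every stochastic
#'   step in documented order.
#' @return A `sim_params` list.
#' @export
sim_params <- function(subfamilies = c("Rabex5", "GAPVD1", "Varp", "Alsin",
                                       "Vps9DCP1", "RIN"),
                       loss_prob = 0.2, dup_prob = 0.1,
                       root_presence = NULL, rate = 0.5,
                       domain_blocks = list(list(name = "Vps9", length = 104,
                                                 rel_rate = 0.25)),
                       linker_length = 100, tip_rate = NULL,
                       protected_taxa = NULL, seed = 1) {
  if (loss_prob < 0 || loss_prob > 1 || dup_prob < 0 || dup_prob > 1)
    stop("probabilities must be in [0, 1]")
  if (rate <= 0) stop("rate must be positive")
  for (b in domain_blocks)
    if (b$rel_rate <= 0 || b$rel_rate > 1)
      stop("domain relative rates must be in (0, 1]")
  if (is.null(root_presence))
    root_presence <- setNames(rep(1L, length(subfamilies)), subfamilies)
  structure(list(subfamilies = subfamilies, loss_prob = loss_prob,
                 dup_prob = dup_prob, root_presence = root_presence,
                 rate = rate, domain_blocks = domain_blocks,
                 linker_length = linker_length,
                 tip_rate = tip_rate, protected_taxa = protected_taxa,
                 seed = as.integer(seed)),
            class = "sim_params")
}

# site-wise rate profile over the simulated protein layout:
# linker blocks at rate 1, domain blocks at their relative rates.
# Returns list(rates, blocks = data.frame(name, start, end) 0-based).
.site_layout <- function(params) {
  rates <- numeric(0)
  blocks <- data.frame(name = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE)
  lk <- params$linker_length
  rates <- c(rates, rep(1, lk))
  for (b in params$domain_blocks) {
    blocks <- rbind(blocks, data.frame(name = b$name, start = length(rates),
                                       end = length(rates) + b$length))
    rates <- c(rates, rep(b$rel_rate, b$length))
    rates <- c(rates, rep(1, lk))
  }
  list(rates = rates, blocks = blocks)
}

#' Simulate a gene-family history along a species tree
#'
#' For each subfamily present at the root, walks the species tree from the
#' root to the tips; on each branch every live lineage is lost with
#' probability `loss_prob` and (if surviving) duplicated with probability
#' `dup_prob`, duplications splitting at the top of the branch. Records the
#' resulting gene trees, per-node true presence, per-tip copy assignments
#' and the full event list. Deterministic given `params$seed`
#' (subfamilies are processed in declared order; within a subfamily,
#' species-tree children in edge order).
#'
#' @param stree a [species_tree()].
#' @param params a [sim_params()].
#' @return A `sim_truth` list: `stree`, `params`, `gene_trees` (nested
#'   lists, one per subfamily; `NULL` when extinct), `tips` (data.frame
#'   `seq_id`, `taxon_id`, `subfamily`, `copy`), `presence` (node x
#'   subfamily 0/1 matrix over all species-tree nodes), `events`
#'   (data.frame `character`, `edge_parent`, `edge_child`, `event`),
#'   `rng_state` (stream position for [evolve_sequences()]).
#' @export
simulate_history <- function(stree, params) {
  tr <- stree$tree
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  root <- ntip + 1L
  node_name <- c(tr$tip.label, paste0("n", (ntip + 1L):nnode))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
          add = TRUE)
  set.seed(params$seed)

  presence <- matrix(0L, nrow = nnode, ncol = length(params$subfamilies),
                     dimnames = list(node_name, params$subfamilies))
  # nodes whose subtree reaches a protected (loss-suppressed) taxon
  protected_node <- rep(FALSE, nnode)
  if (!is.null(params$protected_taxa)) {
    d <- phangorn::Descendants(tr, seq_len(nnode), "tips")
    prot_idx <- match(intersect(params$protected_taxa, tr$tip.label),
                      tr$tip.label)
    protected_node <- vapply(d, function(x) any(x %in% prot_idx),
                             logical(1))
  }
  events <- list()
  gene_trees <- setNames(vector("list", length(params$subfamilies)),
                         params$subfamilies)
  tips <- list()

  for (fam in params$subfamilies) {
    if (params$root_presence[[fam]] != 1) next
    copy_counter <- new.env()
    add_event <- function(p, ch, ev)
      events[[length(events) + 1L]] <<- data.frame(
        character = fam, edge_parent = node_name[p],
        edge_child = node_name[ch], event = ev, stringsAsFactors = FALSE)
    # gene subtree for a lineage sitting exactly at species node `sp`
    continue <- local({
      descend_edge <- function(sp_parent, sp_child, L) {
        if (stats::runif(1) < params$loss_prob &&
            !protected_node[sp_child]) {
          add_event(sp_parent, sp_child, "loss")
          return(NULL)
        }
        if (stats::runif(1) < params$dup_prob) {
          add_event(sp_parent, sp_child, "duplication")
          a <- continue(sp_child)
          b <- continue(sp_child)
          if (is.null(a) && is.null(b)) return(NULL)
          if (is.null(a) || is.null(b)) {
            s <- if (is.null(a)) b else a
            s$blen <- s$blen + L
            return(s)
          }
          a$blen <- a$blen + L
          b$blen <- b$blen + L
          return(list(tip = FALSE, children = list(a, b), blen = 0))
        }
        s <- continue(sp_child)
        if (is.null(s)) return(NULL)
        s$blen <- s$blen + L
        s
      }
      function(sp) {
        presence[sp, fam] <<- 1L
        if (sp <= ntip) {
          taxon <- tr$tip.label[sp]
          k <- (get0(taxon, envir = copy_counter, ifnotfound = 0L)) + 1L
          assign(taxon, k, envir = copy_counter)
          id <- sprintf("%s.%s.%d", taxon, fam, k)
          tips[[length(tips) + 1L]] <<- data.frame(
            seq_id = id, taxon_id = taxon, subfamily = fam, copy = k,
            stringsAsFactors = FALSE)
          return(list(tip = TRUE, label = id, taxon = taxon, blen = 0))
        }
        kid_edges <- which(tr$edge[, 1] == sp)
        subs <- list()
        for (e in kid_edges) {
          s <- descend_edge(sp, tr$edge[e, 2], tr$edge.length[e])
          if (!is.null(s)) subs[[length(subs) + 1L]] <- s
        }
        if (length(subs) == 0) return(NULL)
        if (length(subs) == 1) return(subs[[1]])
        list(tip = FALSE, children = subs, blen = 0)
      }
    })
    gene_trees[[fam]] <- continue(root)
  }

  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(character = character(), edge_parent = character(),
               edge_child = character(), event = character(),
               stringsAsFactors = FALSE)
  tp <- if (length(tips)) do.call(rbind, tips) else
    data.frame(seq_id = character(), taxon_id = character(),
               subfamily = character(), copy = integer(),
               stringsAsFactors = FALSE)
  structure(list(stree = stree, params = params, gene_trees = gene_trees,
                 tips = tp, presence = presence, events = ev,
                 rng_state = get(".Random.seed", globalenv())),
            class = "sim_truth")
}

# newick text for a simulated gene tree (branch lengths, no supports)
.gene_newick <- function(node) {
  if (is.null(node)) return(NULL)
  rec <- function(x) {
    if (x$tip) return(sprintf("%s:%.6f", x$label, x$blen))
    paste0("(", paste(vapply(x$children, rec, character(1)),
                      collapse = ","), "):", sprintf("%.6f", x$blen))
  }
  paste0(rec(node), ";")
}

#' Export a simulated gene tree as newick
#'
#' @param truth a `sim_truth` from [simulate_history()].
#' @param subfamily which gene tree to export.
#' @return Newick text, or `NULL` for an extinct subfamily.
#' @export
gene_tree_newick <- function(truth, subfamily) {
  .gene_newick(truth$gene_trees[[subfamily]])
}

#' Write the simulated event list as TSV
#'
#' Columns: `character`, `edge_parent`, `edge_child`,
#' `event` (loss/duplication).
#'
#' @param truth a `sim_truth`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_events_tsv <- function(truth, path) {
  write.table(truth$events, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Evolve protein sequences along simulated gene trees
#'
#' Draws one set of family-wide domain-block sequences and, per subfamily,
#' a root protein (uniform over the 20 residues in linker regions, the
#' family block sequence in domain regions), then evolves it along the
#' gene-tree branches: a site with rate `r` on a branch of length `t`
#' mutates with probability `1 - exp(-r * t)` to a uniformly chosen
#' different residue, where `r` is `rate * rel_rate(block)` (times the
#' taxon's `tip_rate` multiplier on pendant branches). Continues the RNG
#' stream recorded by [simulate_history()], so a fixed `params$seed`
#' reproduces the full simulation byte-for-byte.
#'
#' @param truth a `sim_truth` from [simulate_history()].
#' @return A [seq_set()] carrying true taxon/supergroup/domain/subfamily
#'   labels; zero rows when every subfamily is extinct.
#' @export
evolve_sequences <- function(truth) {
  params <- truth$params
  layout <- .site_layout(params)
  L <- length(layout$rates)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
          add = TRUE)
  assign(".Random.seed", truth$rng_state, globalenv())

  # family-wide domain blocks (shared ancestrally across subfamilies)
  fam_blocks <- lapply(params$domain_blocks, function(b)
    sample.int(20L, b$length, replace = TRUE))
  tip_rate <- params$tip_rate
  out <- list()
  for (fam in params$subfamilies) {
    gt <- truth$gene_trees[[fam]]
    if (is.null(gt)) next
    root_seq <- sample.int(20L, L, replace = TRUE)
    for (i in seq_len(nrow(layout$blocks)))
      root_seq[(layout$blocks$start[i] + 1L):layout$blocks$end[i]] <-
        fam_blocks[[i]]
    evolve <- function(node, parent_seq) {
      mult <- if (node$tip && !is.null(tip_rate) &&
                  node$taxon %in% names(tip_rate))
        tip_rate[[node$taxon]] else 1
      p <- 1 - exp(-params$rate * layout$rates * mult * node$blen)
      mut <- stats::runif(L) < p
      s <- parent_seq
      if (any(mut)) {
        shift <- sample.int(19L, sum(mut), replace = TRUE)
        s[mut] <- ((s[mut] - 1L + shift) %% 20L) + 1L
      }
      if (node$tip) {
        out[[length(out) + 1L]] <<- data.frame(
          seq_id = node$label, taxon = node$taxon, subfamily = fam,
          residues = paste(AA20[s], collapse = ""), stringsAsFactors = FALSE)
      } else {
        for (ch in node$children) evolve(ch, s)
      }
    }
    evolve(gt, root_seq)
  }
  if (length(out) == 0)
    return(seq_set(character(0), character(0)))
  df <- do.call(rbind, out)
  meta <- truth$stree$taxa[match(df$taxon, truth$stree$taxa$taxon_id), ]
  seq_set(seq_id = df$seq_id, residues = df$residues,
          taxon_id = df$taxon, supergroup = meta$supergroup,
          eu_domain = meta$eu_domain, subfamily = df$subfamily)
}
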