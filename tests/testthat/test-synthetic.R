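test_that("the fixture eukaryote tree carries consistent labels", {
  st <- fixture_eukaryote_tree()
  expect_true(ape::is.rooted(st$tree))
  groups <- table(st$taxa$supergroup)
  expect_true(all(groups >= 2 | names(groups) %in%
                    c("Alveolata", "Haptophyta", "Cryptophyta")))
  hol <- st$taxa[st$taxa$supergroup == "Holozoa", ]
  expect_true(all(hol$eu_domain == "Amorphea"))
  exc <- st$taxa[st$taxa$supergroup == "Excavata", ]
  expect_true(all(exc$eu_domain == "Excavata"))
  expect_true(all(st$taxa$eu_domain %in%
                    c("Amorphea", "Diaphoretickes", "Excavata")))
  # deterministic
  expect_identical(ape::write.tree(st$tree),
                   ape::write.tree(fixture_eukaryote_tree()$tree))
})

test_that("the fixture presence matrix encodes the reported facts", {
  pm <- fixture_presence_matrix()
  # Giardia has no family member at all
  expect_equal(sum(pm$counts["Giardia_intestinalis", ], na.rm = TRUE), 0L)
  # Varp present across Holozoa
  hol <- pm$taxa$taxon_id[pm$taxa$supergroup == "Holozoa"]
  expect_true(all(pm$counts[hol, "Varp"] >= 1))
  # amoebozoan transcriptome rows carry unknown absences, never hard zeros
  tx <- pm$taxa$taxon_id[pm$taxa$transcriptome]
  expect_gt(length(tx), 0)
  expect_true(all(is.na(pm$counts[tx, ]) | pm$counts[tx, ] >= 1))
  # RIN never appears outside Holozoa
  nonhol <- setdiff(rownames(pm$counts), hol)
  expect_equal(sum(pm$counts[nonhol, "RIN"], na.rm = TRUE), 0L)
})

test_that("history simulation respects forced and forbidden event regimes", {
  st <- balanced_species_tree(depth = 3)
  p0 <- sim_params(loss_prob = 0, dup_prob = 0, seed = 4)
  t0 <- simulate_history(st, p0)
  expect_true(all(t0$presence == 1L))
  # single-copy at every tip
  expect_equal(nrow(t0$tips),
               8 * length(p0$subfamilies))
  expect_true(all(t0$tips$copy == 1L))
  # loss_prob = 1: everything dies on the root-child branches
  p1 <- sim_params(loss_prob = 1, dup_prob = 0, seed = 4)
  t1 <- simulate_history(st, p1)
  expect_equal(nrow(t1$tips), 0)
  expect_true(all(t1$events$event == "loss"))
  expect_error(sim_params(loss_prob = 1.2), "probabilities")
})

test_that("simulation is byte-deterministic under a fixed seed", {
  st <- balanced_species_tree(depth = 4)
  p <- sim_params(seed = 99, linker_length = 30,
                  domain_blocks = list(list(name = "Vps9", length = 40,
                                            rel_rate = 0.25)))
  t1 <- simulate_history(st, p); s1 <- evolve_sequences(t1)
  t2 <- simulate_history(st, p); s2 <- evolve_sequences(t2)
  expect_identical(t1$events, t2$events)
  expect_identical(s1, s2)
  # FASTA output is byte-identical too
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(s1, f1); write_fasta(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # and changes with the seed
  t3 <- simulate_history(st, sim_params(seed = 100, linker_length = 30,
                                        domain_blocks = p$domain_blocks))
  expect_false(identical(t1$events, t3$events))
})

test_that("node presence matches independent path enumeration (no duplications)", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    tr <- rand_tree(n)
    taxa <- data.frame(taxon_id = tr$tip.label,
                       supergroup = "Holozoa", stringsAsFactors = FALSE)
    st <- species_tree(tr, taxa)
    p <- sim_params(subfamilies = "F", loss_prob = 0.4, dup_prob = 0,
                    seed = rep)
    truth <- simulate_history(st, p)
    # presence at a node iff its root path crosses no loss edge
    ntip <- length(tr$tip.label)
    lost_children <- truth$events$edge_child[truth$events$event == "loss"]
    node_name <- c(tr$tip.label, paste0("n", (ntip + 1):(ntip + tr$Nnode)))
    for (node in seq_len(ntip + tr$Nnode)) {
      path_ok <- TRUE
      cur <- node
      while (cur != ntip + 1) {
        if (node_name[cur] %in% lost_children) { path_ok <- FALSE; break }
        cur <- tr$edge[tr$edge[, 2] == cur, 1]
      }
      expect_equal(unname(truth$presence[node, "F"]),
                   as.integer(path_ok),
                   info = paste("rep", rep, "node", node))
    }
    # tips with presence 0 have no sequences
    absent <- rownames(truth$presence)[truth$presence[, "F"] == 0]
    expect_false(any(truth$tips$taxon_id %in% absent))
  }
})

test_that("site mutation fractions are calibrated to 1 - exp(-rt)", {
  # one long branch, huge site counts, slow domain vs fast linker
  tr <- ape::read.tree(text = "(A:1,B:0);")
  st <- species_tree(tr, data.frame(taxon_id = c("A", "B"),
                                    supergroup = "Holozoa",
                                    stringsAsFactors = FALSE))
  p <- sim_params(subfamilies = "F", loss_prob = 0, dup_prob = 0, rate = 1,
                  linker_length = 5000,
                  domain_blocks = list(list(name = "D", length = 10000,
                                            rel_rate = 0.1)),
                  seed = 8)
  truth <- simulate_history(st, p)
  seqs <- evolve_sequences(truth)
  a <- strsplit(seqs$residues[seqs$taxon_id == "A"], "")[[1]]
  b <- strsplit(seqs$residues[seqs$taxon_id == "B"], "")[[1]]
  # B sits at distance ~0 from the root: its sequence is the root state
  linker_idx <- c(1:5000, 15001:20000)
  domain_idx <- 5001:15000
  for (set in list(list(idx = linker_idx, r = 1),
                   list(idx = domain_idx, r = 0.1))) {
    pexp <- 1 - exp(-set$r)
    obs <- mean(a[set$idx] != b[set$idx])
    sd3 <- 3 * sqrt(pexp * (1 - pexp) / length(set$idx))
    expect_lt(abs(obs - pexp), sd3)
  }
  # and domain sites mutate less than linker sites
  expect_lt(mean(a[domain_idx] != b[domain_idx]),
            mean(a[linker_idx] != b[linker_idx]))
  # zero branch length: child identical to parent state
  expect_equal(sum(tr$edge.length[tr$edge[, 2] ==
                                    match("B", tr$tip.label)]), 0)
})

test_that("event lists and gene trees export to standard formats", {
  st <- balanced_species_tree(depth = 3)
  p <- sim_params(seed = 5)
  truth <- simulate_history(st, p)
  f <- tempfile(fileext = ".tsv")
  write_events_tsv(truth, f)
  ev <- read.delim(f, stringsAsFactors = FALSE)
  expect_setequal(names(ev), c("character", "edge_parent", "edge_child",
                               "event"))
  expect_true(all(ev$event %in% c("loss", "duplication")))
  # surviving gene trees parse as valid newick
  for (fam in p$subfamilies) {
    nwk <- gene_tree_newick(truth, fam)
    if (!is.null(nwk)) {
      gt <- ape::read.tree(text = nwk)
      expect_true(!is.null(gt) || grepl("^[^(]+:", nwk))
    }
  }
})
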