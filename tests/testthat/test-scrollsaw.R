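# hand-built gene tree: two backbone subfamilies plus queries
#   ((q1:0.1, v1:0.1)0.95, (v2:0.2, q2:0.2)0.5, ((r1:0.1, r2:0.1)0.9,
#    q3:0.3)0.99)
toy_catalog <- backbone_catalog(c("v1", "v2", "r1", "r2"),
                                c("Varp", "Varp", "RIN", "RIN"),
                                anchor_id = "r1", anchor_clade = "RIN")

toy_tree <- function() {
  read_gene_tree(paste0(
    "(((q1:0.1,v1:0.1)0.95:0.2,(v2:0.2,q2:0.2)0.5:0.2)0.9:0.1,",
    "((r1:0.1,r2:0.4)0.9:0.3,q3:0.3)0.99:0.1);"))
}

test_that("queries are assigned through supported pure clades only", {
  asg <- assign_subfamilies(toy_tree(), toy_catalog, min_support = 0.8)
  a <- setNames(asg$subfamily, asg$seq_id)
  expect_equal(unname(a["q1"]), "Varp")      # support 0.95 cherry with v1
  expect_equal(unname(a["q2"]), "Varp")      # 0.5 cherry fails, 0.9 clade holds
  expect_equal(unname(a["q3"]), "RIN")       # 0.99 clade with both r tips
  expect_true(all(!asg$megaclade))
  # raising the bar leaves weakly supported queries unclassified
  asg2 <- assign_subfamilies(toy_tree(), toy_catalog, min_support = 0.97)
  a2 <- setNames(asg2$subfamily, asg2$seq_id)
  expect_equal(unname(a2["q1"]), "unclassified")
  expect_equal(unname(a2["q3"]), "RIN")
})

test_that("megaclade fallback fires only when single subfamilies fail", {
  cat2 <- backbone_catalog(c("x1", "y1"), c("Rabex5", "GAPVD1"),
                           anchor_id = "o1", anchor_clade = "RIN")
  # query nested between the two subfamilies at high support
  tr <- read_gene_tree(
    "(((x1:0.1,q1:0.1)0.95:0.1,y1:0.15)0.95:0.2,(o1:0.3,o2:0.3)0.9:0.2);")
  cat3 <- backbone_catalog(c("x1", "y1", "o1"),
                           c("Rabex5", "GAPVD1", "RIN"),
                           anchor_id = "o1", anchor_clade = "RIN")
  asg <- assign_subfamilies(tr, cat3, min_support = 0.8)
  a <- setNames(asg$subfamily, asg$seq_id)
  expect_equal(unname(a["q1"]), "Rabex5")    # pure cherry wins first
  # weaken the cherry: only the megaclade remains
  tr2 <- read_gene_tree(
    "(((x1:0.1,q1:0.1)0.5:0.1,y1:0.15)0.95:0.2,(o1:0.3,o2:0.3)0.9:0.2);")
  asg2 <- assign_subfamilies(tr2, cat3, min_support = 0.8)
  q <- asg2[asg2$seq_id == "q1", ]
  expect_equal(q$subfamily, "Rabex5+GAPVD1")
  expect_true(q$megaclade)
})

test_that("clade depths add branch lengths to the clade base", {
  tr <- ape::read.tree(text = "((a:0.1,b:0.4):0.3,(c:0.1,d:0.2):0.5);")
  expect_equal(clade_depth(tr, "a", c("a", "b")), 0.1)
  expect_equal(clade_depth(tr, "b", c("a", "b")), 0.4)
  # chain: tip -> cherry base -> deeper base
  expect_equal(clade_depth(tr, "a", c("a", "b", "c", "d")), 0.4)
  # single-tip clade: pendant edge
  expect_equal(clade_depth(tr, "c", "c"), 0.1)
  expect_error(clade_depth(tr, "a", c("a", "c")), "monophyletic")
  expect_error(clade_depth(tr, "a", c("b", "c")), "member")
})

test_that("anchor normalisation is scale-invariant with a raw fallback", {
  tr <- toy_tree()
  nd <- normalized_depth(tr, "q1", c("q1", "v1"), toy_catalog)
  # anchor r1 sits 0.1 below the RIN base
  expect_true(nd$normalized)
  expect_equal(nd$ratio, 0.1 / 0.1)
  # doubling every branch leaves the ratio unchanged
  tr2 <- tr; tr2$edge.length <- tr2$edge.length * 2
  nd2 <- normalized_depth(tr2, "q1", c("q1", "v1"), toy_catalog)
  expect_equal(nd2$ratio, nd$ratio)
  # anchor absent: raw depth, flagged
  cat_na <- backbone_catalog(c("v1", "v2", "r1", "r2"),
                             c("Varp", "Varp", "RIN", "RIN"),
                             anchor_id = "missing", anchor_clade = "RIN")
  nd3 <- normalized_depth(tr, "q1", c("q1", "v1"), cat_na)
  expect_false(nd3$normalized)
  expect_equal(nd3$ratio, 0.1)
})

test_that("representative selection picks minimal depths deterministically", {
  asg <- data.frame(seq_id = c("s1", "s2", "s3", "s4", "s5"),
                    subfamily = c("Varp", "Varp", "Varp", "RIN",
                                  "unclassified"),
                    normalized_depth = c(0.5, 0.2, 0.2, 0.7, 0.1),
                    stringsAsFactors = FALSE)
  grp <- setNames(c("G1", "G1", "G1", "G1", "G1"), asg$seq_id)
  reps <- select_representatives(asg, grp)
  expect_equal(nrow(reps), 2)
  # tie between s2 and s3 at 0.2: lexicographically smaller id wins
  expect_equal(reps$seq_id[reps$subfamily == "Varp"], "s2")
  expect_equal(reps$seq_id[reps$subfamily == "RIN"], "s4")
  # idempotence: selecting from the selected set returns it unchanged
  reps2 <- select_representatives(
    asg[asg$seq_id %in% reps$seq_id, ], grp)
  expect_equal(reps2$seq_id, reps$seq_id)
})

test_that("rate-accelerated tips are never chosen as representatives", {
  # simulate one subfamily with a 5x-rate taxon, measure depths directly
  st <- balanced_species_tree(depth = 3, branch_length = 0.3)
  fast <- "t03"
  p <- sim_params(subfamilies = "Varp", loss_prob = 0, dup_prob = 0,
                  tip_rate = setNames(5, fast), seed = 11)
  truth <- simulate_history(st, p)
  seqs <- evolve_sequences(truth)
  rows <- setNames(seqs$residues, seqs$seq_id)
  D <- distance_matrix(rows)
  tr <- neighbor_joining(D)
  # the accelerated taxon shows the longest pendant branch by far
  pend <- setNames(tr$edge.length[match(seq_along(tr$tip.label),
                                        tr$edge[, 2])], tr$tip.label)
  fast_id <- seqs$seq_id[seqs$taxon_id == fast]
  expect_gt(min(pend[fast_id]), max(pend[setdiff(names(pend), fast_id)]))
  # and with pendant depths as the selection criterion it is never picked
  asg <- data.frame(seq_id = names(pend), subfamily = "Varp",
                    normalized_depth = unname(pend),
                    stringsAsFactors = FALSE)
  reps <- select_representatives(asg, setNames(rep("G", length(pend)),
                                               names(pend)))
  expect_false(any(reps$seq_id %in% fast_id))
})
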