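test_that("matrix building counts paralogues and keeps transcriptome absences unknown", {
  taxa <- data.frame(taxon_id = c("gx", "gy", "tz"),
                     supergroup = c("Holozoa", "Discoba", "Amoebozoa"),
                     transcriptome = c(FALSE, FALSE, TRUE),
                     stringsAsFactors = FALSE)
  asg <- data.frame(seq_id = c("a", "b", "c", "d"),
                    subfamily = c("Varp", "Varp", "unclassified", "Alsin"),
                    taxon_id = c("gx", "gx", "gx", "tz"),
                    stringsAsFactors = FALSE)
  pm <- build_matrix(asg, taxa)
  expect_equal(pm$counts["gx", "Varp"], 2L)
  expect_equal(pm$counts["gx", "unclassified"], 1L)
  # genome taxon, zero hits -> 0; transcriptome taxon, zero hits -> NA
  expect_equal(pm$counts["gy", "Varp"], 0L)
  expect_true(is.na(pm$counts["tz", "Varp"]))
  expect_equal(pm$counts["tz", "Alsin"], 1L)
  expect_error(build_matrix(data.frame(seq_id = "z", subfamily = "Varp",
                                       taxon_id = "nope"), taxa),
               "taxon")
})

test_that("ancestral-set rules respect domains, unknowns and monotonicity", {
  taxa <- data.frame(taxon_id = c("am1", "am2", "di1", "ex1"),
                     supergroup = c("Holozoa", "Amoebozoa", "SAR",
                                    "Discoba"),
                     transcriptome = c(FALSE, FALSE, FALSE, TRUE),
                     stringsAsFactors = FALSE)
  counts <- matrix(c(1, 0, 1, NA,    # two domains -> in
                     1, 1, 0, NA,    # Amorphea only -> out
                     0, 1, 0, 1),    # Amorphea + Excavata -> in (both rules)
                   nrow = 4,
                   dimnames = list(taxa$taxon_id, c("X", "Y", "Z")))
  pm <- presence_matrix(counts, taxa)
  expect_setequal(infer_ancestral_set(pm), c("X", "Z"))
  expect_setequal(infer_ancestral_set(pm, "strict"), "Z")
  # adding a presence never shrinks the set
  counts2 <- counts; counts2["ex1", "Y"] <- 1
  pm2 <- presence_matrix(counts2, taxa)
  expect_true(all(infer_ancestral_set(pm) %in% infer_ancestral_set(pm2)))
  # unknown states never count as presence
  counts3 <- counts; counts3["ex1", "X"] <- NA
  expect_setequal(infer_ancestral_set(presence_matrix(counts3, taxa)),
                  c("X", "Z"))
})

test_that("Dollo mapping handles the worked examples", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  m <- dollo_map(tr, c(A = 1, B = 1, C = 0, D = 0))
  expect_equal(m$gain, ape::getMRCA(tr, c("A", "B")))
  expect_equal(m$n_losses, 0L)
  # forced root gain with presence in A and C: two losses
  m2 <- dollo_map(tr, c(A = 1, B = 0, C = 1, D = 0), gain_at_root = TRUE)
  expect_equal(m2$gain, 5L)
  expect_equal(m2$n_losses, 2L)
  # unknown tips never force losses
  m3 <- dollo_map(tr, c(A = 1, B = NA, C = 0, D = 0))
  expect_equal(m3$n_losses, 0L)
  # no presence: empty entry
  m4 <- dollo_map(tr, c(A = 0, B = 0, C = 0, D = 0))
  expect_true(is.na(m4$gain))
  expect_equal(m4$n_losses, 0L)
})

test_that("Dollo loss counts equal exhaustive minima on random characters", {
  set.seed(13)
  for (rep in 1:40) {
    n <- sample(4:10, 1)
    tr <- rand_tree(n)
    st <- sample(c(0L, 1L, NA), n, replace = TRUE,
                 prob = c(0.4, 0.45, 0.15))
    names(st) <- tr$tip.label
    if (sum(st == 1L, na.rm = TRUE) == 0) st[1] <- 1L
    for (root_gain in c(FALSE, TRUE)) {
      m <- dollo_map(tr, st, gain_at_root = root_gain)
      gain <- if (root_gain) length(tr$tip.label) + 1L else m$gain
      expect_equal(m$n_losses, bf_dollo_losses(tr, st, gain),
                   info = paste("rep", rep, "root", root_gain))
    }
  }
})

test_that("Fitch counts match exhaustive labeling minima and bound Dollo", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(fitch_changes(tr, c(A = 1, B = 1, C = 1, D = 1)), 0L)
  expect_equal(fitch_changes(tr, c(A = 1, B = 1, C = 0, D = 0)), 1L)
  # alternating states on a caterpillar, against brute force
  cat6 <- ape::read.tree(
    text = "(A:1,(B:1,(C:1,(D:1,(E:1,F:1):1):1):1):1);")
  st <- setNames(c(1L, 0L, 1L, 0L, 1L, 0L), LETTERS[1:6])
  expect_equal(fitch_changes(cat6, st), bf_fitch_changes(cat6, st))
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    tr2 <- rand_tree(n)
    st2 <- setNames(sample(c(0L, 1L, NA), n, TRUE, c(0.4, 0.4, 0.2)),
                    tr2$tip.label)
    expect_equal(fitch_changes(tr2, st2), bf_fitch_changes(tr2, st2),
                 info = paste("rep", rep))
    # consistency with Dollo: fitch <= 1 + dollo losses
    if (sum(st2 == 1L, na.rm = TRUE) > 0) {
      d <- dollo_map(tr2, st2)
      expect_lte(fitch_changes(tr2, st2), 1L + d$n_losses)
    }
  }
})

test_that("independent architecture acquisitions are counted per character", {
  st <- fixture_eukaryote_tree()
  pm <- fixture_architecture_characters()
  expect_equal(count_independent_acquisitions(pm, st$tree), 3L)
  # collapsing all occurrences into one character gives one gain
  v <- ifelse(apply(is.na(pm$counts), 1, all), NA_integer_,
              as.integer(rowSums(pm$counts, na.rm = TRUE) > 0))
  one <- presence_matrix(
    matrix(v, ncol = 1, dimnames = list(rownames(pm$counts), "ANK+Vps9")),
    pm$taxa)
  expect_equal(count_independent_acquisitions(one, st$tree), 1L)
  # empty matrix: zero
  empty <- presence_matrix(
    matrix(0L, nrow = nrow(pm$counts), ncol = 1,
           dimnames = list(rownames(pm$counts), "none")), pm$taxa)
  expect_equal(count_independent_acquisitions(empty, st$tree), 0L)
})

test_that("event maps respect Dollo invariants and round-trip with TSV", {
  pm <- fixture_presence_matrix()
  st <- fixture_eukaryote_tree()
  leca <- infer_ancestral_set(pm)
  ev <- event_map(pm, st$tree, leca_set = leca)
  # at most one gain per character
  gains <- table(ev$character[ev$event == "gain"])
  expect_true(all(gains == 1))
  # matrix TSV round-trip preserves counts and unknowns
  f <- tempfile(fileext = ".tsv")
  write_presence_tsv(pm, f)
  back <- read_presence_tsv(f, character_groups = pm$character_groups)
  expect_equal(back$counts, pm$counts)
  expect_equal(infer_ancestral_set(back), leca)
})
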