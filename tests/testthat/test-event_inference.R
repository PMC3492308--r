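test_that("Dollo reconstruction handles textbook cases", {
  tree <- ape::read.tree(text = "((A,B),(C,D));")
  # present everywhere: origin at root, no losses
  d <- dollo_reconstruct(c("A", "B", "C", "D"), tree)
  expect_equal(d$origin, 5L)
  expect_equal(d$n_losses, 0L)
  # present in A, B, D: one loss on the branch to C
  d2 <- dollo_reconstruct(c("A", "B", "D"), tree)
  expect_equal(d2$origin, 5L)
  expect_equal(d2$loss_branches, match("C", tree$tip.label))
  # single carrier: origin at the tip itself
  d3 <- dollo_reconstruct("B", tree)
  expect_equal(d3$origin, match("B", tree$tip.label))
  expect_equal(d3$n_losses, 0L)
  expect_error(dollo_reconstruct(character(0), tree),
               class = "cobintron_bad_input")
})

test_that("Dollo equals the exhaustive minimal-loss oracle", {
  set.seed(71)
  for (rep in 1:300) {
    n <- sample(4:8, 1)
    tree <- random_topology(n)
    k <- sample(seq_len(n), 1)
    present <- sample(tree$tip.label, k)
    got <- dollo_reconstruct(present, tree)
    want <- oracle_dollo(present, tree)
    expect_equal(got$origin, want$origin)
    expect_equal(got$loss_branches, want$loss_branches)
  }
})

test_that("Dollo losses are invariant under leaf-order permutation", {
  set.seed(73)
  tree <- random_topology(8)
  present <- sample(tree$tip.label, 5)
  base <- dollo_reconstruct(present, tree)
  base_clades <- sort(vapply(base$loss_branches, function(v)
    paste(sort(cobintron:::leaves_below_or_self(tree, v)), collapse = ","),
    character(1)))
  for (i in 1:5) {
    tr2 <- ape::read.tree(text = ape::write.tree(ape::rotateConstr(
      tree, sample(tree$tip.label))))
    d2 <- dollo_reconstruct(sample(present), tr2)
    clades2 <- sort(vapply(d2$loss_branches, function(v)
      paste(sort(cobintron:::leaves_below_or_self(tr2, v)), collapse = ","),
      character(1)))
    expect_equal(clades2, base_clades)
  }
})

test_that("lateral-gain flags need both anomaly and patchiness", {
  tree <- ape::read.tree(text = "((A,B),(C,D));")
  members <- data.frame(intron_id = c("iA", "iC"),
                        species_id = c("A", "C"))
  cid <- matrix(90, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(cid) <- 100
  ii_hot <- function(a, b) 99      # near-identical introns
  ii_cold <- function(a, b) 90     # tracks the cdna
  # anomaly + intervening lineage (B, D lack the family) -> flagged
  fl <- flag_lateral_gains(members, ii_hot, cid, tree, delta = 5)
  expect_equal(nrow(fl), 1L)
  expect_setequal(c(fl$species_a, fl$species_b), c("A", "C"))
  # no anomaly -> nothing
  expect_equal(nrow(flag_lateral_gains(members, ii_cold, cid, tree)), 0L)
  # anomaly but no intervening lineage lacking the family -> nothing
  all_members <- data.frame(intron_id = paste0("i", LETTERS[1:4]),
                            species_id = LETTERS[1:4])
  expect_equal(nrow(flag_lateral_gains(all_members, ii_hot, cid, tree)), 0L)
  # monotone in delta: raising delta never adds flags
  f5 <- flag_lateral_gains(members, ii_hot, cid, tree, delta = 5)
  f8 <- flag_lateral_gains(members, ii_hot, cid, tree, delta = 8)
  f20 <- flag_lateral_gains(members, ii_hot, cid, tree, delta = 20)
  expect_true(nrow(f20) <= nrow(f8) && nrow(f8) <= nrow(f5))
})

test_that("transpositions are the minority-position members", {
  fam <- data.frame(family_id = 1L,
                    intron_id = paste0("i", 1:9),
                    ref_codon = c(rep(67L, 8), 69L))
  tp <- detect_transpositions(fam)
  expect_equal(nrow(tp), 1L)
  expect_equal(tp$intron_id, "i9")
  expect_equal(tp$position, 69L)
  expect_equal(tp$modal_position, 67L)
  fam2 <- data.frame(family_id = 2L, intron_id = paste0("j", 1:11),
                     ref_codon = c(168L, 168L, rep(169L, 6), rep(208L, 3)))
  tp2 <- detect_transpositions(fam2)
  expect_setequal(unique(tp2$position), c(168L, 208L))
  expect_equal(unique(tp2$modal_position), 169L)
  fam3 <- data.frame(family_id = 3L, intron_id = c("k1", "k2"),
                     ref_codon = c(131L, 131L))
  expect_equal(nrow(detect_transpositions(fam3)), 0L)
})

test_that("event-free histories infer origins only", {
  sim <- simulate_catalogue(quick_config(79, gain_rate = 0, loss_rate = 0,
                                         transfer_rate = 0,
                                         transposition_rate = 0))
  cat1 <- assign_positions(extract_all_introns(sim$catalogue),
                           reference = sort(sim$tree$tip.label)[1])
  fam <- truth_family_table(cat1, sim)
  ev <- recover_events(cat1, sim$tree, fam, truth = sim$truth)
  expect_equal(nrow(ev$losses), 0L)
  expect_equal(nrow(ev$lateral_gains), 0L)
  expect_equal(nrow(ev$transpositions), 0L)
  expect_gt(nrow(ev$origins), 0L)
})

test_that("loss-only histories are recovered in the identifiable stratum", {
  recalls <- c()
  for (sd in 83:88) {
    sim <- simulate_catalogue(quick_config(sd, gain_rate = 0,
                                           loss_rate = 0.8,
                                           transfer_rate = 0,
                                           transposition_rate = 0))
    if (!nrow(sim$truth$complements)) next
    cat1 <- assign_positions(extract_all_introns(sim$catalogue),
                             reference = sort(names(sim$catalogue$records))[1])
    fam <- truth_family_table(cat1, sim)
    ev <- recover_events(cat1, sim$tree, fam, truth = sim$truth)
    recalls <- c(recalls, ev$recovery["loss", "recall"])
  }
  expect_gte(mean(recalls, na.rm = TRUE), 0.9)
})

test_that("recovery is deterministic given the seed", {
  sim <- simulate_catalogue(quick_config(89))
  cat1 <- assign_positions(extract_all_introns(sim$catalogue),
                           reference = sort(names(sim$catalogue$records))[1])
  fam <- truth_family_table(cat1, sim)
  e1 <- recover_events(cat1, sim$tree, fam, truth = sim$truth)
  e2 <- recover_events(cat1, sim$tree, fam, truth = sim$truth)
  expect_identical(e1, e2)
})

test_that("a clade-confined family without anomaly is origin-only", {
  tree <- ape::read.tree(text = "(((A,B),C),(D,E));")
  members <- data.frame(intron_id = c("iA", "iB"),
                        species_id = c("A", "B"))
  cid <- matrix(92, 5, 5, dimnames = list(LETTERS[1:5], LETTERS[1:5]))
  diag(cid) <- 100
  d <- dollo_reconstruct(c("A", "B"), tree)
  expect_equal(d$n_losses, 0L)
  expect_equal(sort(cobintron:::leaves_below_or_self(tree, d$origin)),
               c("A", "B"))
  fl <- flag_lateral_gains(members, function(a, b) 93, cid, tree)
  expect_equal(nrow(fl), 0L)
})
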