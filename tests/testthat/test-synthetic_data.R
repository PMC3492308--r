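test_that("configuration is validated", {
  expect_error(simulation_config(loss_rate = -1),
               class = "cobintron_bad_config")
  expect_error(simulation_config(n_taxa = 0), class = "cobintron_bad_config")
  expect_error(simulation_config(cds_length_codons = 5),
               class = "cobintron_bad_config")
  expect_error(simulation_config(intron_length_range = c(100, 50)),
               class = "cobintron_bad_config")
})

test_that("tree simulation: edge cases, determinism, Yule depth law", {
  set.seed(1)
  t1 <- simulate_species_tree(simulation_config(n_taxa = 1))
  expect_equal(length(t1$tip.label), 1L)
  set.seed(5)
  ta <- simulate_species_tree(simulation_config(n_taxa = 8))
  set.seed(5)
  tb <- simulate_species_tree(simulation_config(n_taxa = 8))
  expect_identical(ape::write.tree(ta), ape::write.tree(tb))
  expect_true(all(ta$edge.length > 0))
  # ultrametric
  d <- ape::node.depth.edgelength(ta)
  expect_equal(diff(range(d[1:8])), 0, tolerance = 1e-8)
  # pure-birth depth from the first split: E = (H_n - 1) / birth
  set.seed(11)
  cfg <- simulation_config(n_taxa = 6, birth_rate = 1, death_rate = 0)
  depths <- replicate(200, {
    tr <- simulate_species_tree(cfg)
    max(ape::node.depth.edgelength(tr))
  })
  Hn <- sum(1 / (2:6))
  se <- stats::sd(depths) / sqrt(length(depths))
  expect_lt(abs(mean(depths) - Hn), 4 * se)
})

test_that("Jukes-Cantor evolution matches its closed form and edge cases", {
  set.seed(2)
  s <- cobintron:::random_dna(30000)
  p_obs <- replicate(8, {
    1 - cobintron:::hamming_identity(s, jc_evolve(s, 0.1, 2)) / 100
  })
  p_exp <- 0.75 * (1 - exp(-4 * 0.1 * 2 / 3))
  se <- sqrt(p_exp * (1 - p_exp) / 30000) / sqrt(8)
  expect_lt(abs(mean(p_obs) - p_exp), 5 * se)
  # two leaves at distance d: composition of branch transitions is JC at d
  tree <- ape::read.tree(text = "(a:1.2,b:0.8);")
  cfg <- simulation_config(subst_rate = 0.05, cds_length_codons = 2000L)
  set.seed(3)
  leaves <- evolve_coding_sequences(tree, cfg)
  p_pair <- 1 - cobintron:::hamming_identity(leaves[["a"]],
                                             leaves[["b"]]) / 100
  d <- 2 * 0.05
  p_exp <- 0.75 * (1 - exp(-4 * d / 3))
  # start/stop-preservation and stop resampling bias the rate only slightly
  expect_lt(abs(p_pair - p_exp), 6 * sqrt(p_exp * (1 - p_exp) / 6000))
  # zero rate: all leaves identical to the root
  set.seed(4)
  frozen0 <- evolve_coding_sequences(tree,
    simulation_config(subst_rate = 0), root_cds = leaves[["a"]])
  expect_identical(unname(unique(frozen0)), leaves[["a"]])
  # sister-pair identity is tunable to ~99% with a small distance
  id99 <- 100 * (1 - 0.75 * (1 - exp(-4 * 0.01 / 3)))
  expect_gt(id99, 99)
})

test_that("translated simulated coding sequences have no internal stops", {
  for (sd in 1:3) {
    sim <- simulate_catalogue(quick_config(sd, n_taxa = 4))
    for (cdna in sim$cdnas) expect_no_error(translate_coding(cdna))
  }
})

test_that("event-free histories pass ancestral families to every leaf", {
  cfg <- quick_config(13, gain_rate = 0, loss_rate = 0, transfer_rate = 0,
                      transposition_rate = 0)
  sim <- simulate_catalogue(cfg)
  comp <- sim$truth$complements
  expect_equal(nrow(sim$truth$events), 0L)
  expect_equal(nrow(comp), 8L * cfg$n_ancestral_families)
  expect_true(all(table(comp$species_id) == cfg$n_ancestral_families))
  # consensus holds for every planted intron
  cat1 <- extract_all_introns(sim$catalogue)
  cons <- vapply(seq_len(nrow(cat1$introns)), function(i)
    unlist(validate_splice_consensus(cat1$introns[i, ])), logical(2))
  expect_true(all(cons))
})

test_that("heavy loss empties most genes; transfers copy sequences verbatim", {
  sim <- simulate_catalogue(quick_config(17, loss_rate = 3, gain_rate = 0,
                                         transfer_rate = 0,
                                         transposition_rate = 0))
  n_empty <- sum(!sort(sim$tree$tip.label) %in%
                   sim$truth$complements$species_id)
  expect_gt(n_empty / 8, 0.5)

  # a recent transfer's intron pair is more alike than the species' cdnas
  sim2 <- simulate_catalogue(quick_config(19, transfer_rate = 1.5,
                                          loss_rate = 0.2))
  ev <- sim2$truth$events
  tt <- ev[ev$kind == "transfer", , drop = FALSE]
  tt <- tt[order(-tt$time), ]
  comp <- sim2$truth$complements
  found <- FALSE
  for (j in seq_len(nrow(tt))) {
    rec <- cobintron:::leaves_below_or_self(sim2$tree, tt$branch_child[j])
    don <- cobintron:::leaves_below_or_self(sim2$tree, tt$donor_child[j])
    carriers <- comp[comp$family_id == tt$family_id[j], ]
    a <- carriers[carriers$species_id %in% rec, ][1, ]
    b <- carriers[carriers$species_id %in% don, ][1, ]
    if (is.na(a$species_id) || is.na(b$species_id) ||
        identical(a$species_id, b$species_id)) next
    ii <- cobintron:::hamming_identity(a$sequence, b$sequence)
    ci <- cobintron:::hamming_identity(sim2$cdnas[[a$species_id]],
                                       sim2$cdnas[[b$species_id]])
    expect_gt(ii, ci)
    found <- TRUE
    break
  }
  expect_true(found)
})

test_that("rendering conserves length and enforces the splice consensus", {
  cdna <- paste0("ATG", strrep("ACT", 40), "TAA")    # T sites every codon
  intron <- cobintron:::random_intron_seq(1000)
  comp <- data.frame(species_id = "x", insertion_point = 6L,
                     sequence = intron)
  rec <- render_genomic_sequences(setNames(cdna, "x"), comp)[[1]]
  expect_equal(nchar(rec$gdna) - nchar(rec$cdna), 1000L)
  none <- render_genomic_sequences(setNames(cdna, "x"),
                                   comp[0, , drop = FALSE])[[1]]
  expect_identical(none$gdna, none$cdna)
  expect_error(render_genomic_sequences(setNames(cdna, "x"),
    data.frame(species_id = "x", insertion_point = 4L, sequence = intron)),
    class = "cobintron_site_consensus")
  bad <- sub("G$", "A", intron)
  expect_error(render_genomic_sequences(setNames(cdna, "x"),
    data.frame(species_id = "x", insertion_point = 6L, sequence = bad)),
    class = "cobintron_site_consensus")
})

test_that("paper-like family counts give total intronic spans of 8-13 kb", {
  sim <- simulate_catalogue(quick_config(23, n_ancestral_families = 7,
                                         gain_rate = 0, loss_rate = 0,
                                         transfer_rate = 0,
                                         transposition_rate = 0))
  spans <- vapply(sim$catalogue$records, function(r)
    nchar(r$gdna) - nchar(r$cdna), integer(1))
  expect_true(all(spans >= 8000 & spans <= 13000))
})

test_that("identical seed and configuration reproduce bit-identical output", {
  a <- simulate_catalogue(quick_config(29))
  b <- simulate_catalogue(quick_config(29))
  expect_identical(lapply(a$catalogue$records, unclass),
                   lapply(b$catalogue$records, unclass))
  expect_identical(a$truth$events, b$truth$events)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
})
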