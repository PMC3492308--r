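test_that("identical sequences give one full-length perfect HSP", {
  set.seed(51)
  s <- cobintron:::random_dna(1000)
  for (eng in c("blastn", "sw")) {
    h <- find_hsps(s, s, engine = eng)
    expect_gte(nrow(h), 1L)
    expect_equal(unname(unlist(h[1, c("qstart", "qend")])), c(1L, 1000L))
    expect_equal(h$identities[1], h$aligned_len[1])
    st <- tile_and_score(h, 1000, 1000)
    expect_equal(st$coverage, 1.0)
    expect_equal(st$mean_identity, 100)
  }
})

test_that("independent random sequences rarely reach E <= 1e-5", {
  set.seed(53)
  hits <- replicate(20, {
    a <- cobintron:::random_dna(1000)
    b <- cobintron:::random_dna(1000)
    nrow(find_hsps(a, b)) > 0
  })
  expect_gte(mean(!hits), 0.95)
})

test_that("a shared 300-nt block is recovered as one tiled HSP", {
  set.seed(57)
  block <- cobintron:::random_dna(300)
  a <- paste0(cobintron:::random_dna(350), block, cobintron:::random_dna(350))
  b <- paste0(cobintron:::random_dna(200), block, cobintron:::random_dna(500))
  h <- find_hsps(a, b)
  st <- tile_and_score(h, nchar(a), nchar(b))
  expect_equal(st$n_hsps_tiled, 1L)
  expect_gte(st$coverage * 1000, 295)
  # independent oracle: one optimal local alignment must find the block
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(2, -3),
    gapOpening = 5, gapExtension = 2)
  expect_gte(Biostrings::nchar(aln), 295)
  ora_span <- c(Biostrings::start(Biostrings::pattern(aln)),
                Biostrings::end(Biostrings::pattern(aln)))
  expect_lte(abs(h$qstart[1] - ora_span[1]), 5)
  expect_lte(abs(h$qend[1] - ora_span[2]), 5)
})

test_that("tiling arithmetic follows the printed coverage formula", {
  hsps <- data.frame(qstart = c(1, 500), qend = c(200, 649),
                     sstart = c(1, 500), send = c(200, 649),
                     identities = c(190, 140), aligned_len = c(200, 150),
                     score = c(100, 80), bitscore = c(50, 40),
                     evalue = c(1e-20, 1e-10))
  st <- tile_and_score(hsps, 1000, 800)
  expect_equal(st$coverage, 350 / 1000)
  expect_equal(st$mean_identity, 100 * 330 / 350)
  expect_equal(st$n_hsps_tiled, 2L)
})

test_that("greedy tiling equals the exhaustive subset oracle (<= 6 HSPs)", {
  set.seed(59)
  for (rep in 1:200) {
    n <- sample(1:6, 1)
    hsps <- random_hsp_set(n)
    got <- tile_and_score(hsps, 400, 300, max_clip = 0L)
    want <- oracle_tile(hsps, 400, 300)
    expect_equal(got$coverage, want$coverage)
    expect_equal(got$mean_identity, want$mean_identity)
  }
})

test_that("homology thresholds apply strictly and reciprocally", {
  th <- homology_thresholds()
  s <- function(cov, id) list(coverage = cov, mean_identity = id,
                              n_hsps_tiled = 1L)
  expect_true(homologous(s(0.35, 85), s(0.35, 85), th))
  expect_false(homologous(s(0.25, 99), s(0.25, 99), th))
  expect_false(homologous(s(0.50, 79), s(0.50, 79), th))
  # strict reciprocity needs both orientations; "any" accepts one
  expect_false(homologous(s(0.35, 85), s(0.25, 85), th))
  th_any <- homology_thresholds(reciprocal = "any")
  expect_true(homologous(s(0.35, 85), s(0.25, 85), th_any))
  # symmetry under strict reciprocity
  expect_equal(homologous(s(0.35, 85), s(0.25, 85), th),
               homologous(s(0.25, 85), s(0.35, 85), th))
})

test_that("families are connected components with deterministic ids", {
  introns <- data.frame(intron_id = c("A", "B", "C", "D"),
                        sequence = "ACGT")
  pairs <- data.frame(intron_a = c("A", "B"), intron_b = c("B", "C"),
                      homologous = TRUE)
  fam <- build_families(introns, pairs)
  expect_equal(fam$family_id[match(c("A", "B", "C"), fam$intron_id)],
               rep(1L, 3))
  expect_equal(fam$n_members[fam$intron_id == "D"], 1L)
})

test_that("clustering recovers the true partition below 20% divergence", {
  sim <- simulate_catalogue(quick_config(61, intron_subst_rate = 0.025))
  cat1 <- assign_positions(extract_all_introns(sim$catalogue),
                           reference = sort(sim$tree$tip.label)[1])
  truth <- truth_family_table(cat1, sim)
  # precondition of the claim: within-family divergence < 20%
  ok <- TRUE
  for (f in unique(truth$family_id)) {
    seqs <- cat1$introns$sequence[match(
      truth$intron_id[truth$family_id == f], cat1$introns$intron_id)]
    if (length(seqs) < 2) next
    for (i in seq_along(seqs)[-1])
      if (nchar(seqs[1]) == nchar(seqs[i]) &&
          cobintron:::hamming_identity(seqs[1], seqs[i]) < 80) ok <- FALSE
  }
  expect_true(ok)
  pairs <- pairwise_homology(cat1$introns)
  fam <- build_families(cat1$introns, pairs, cat1$assignments)
  inf <- fam$family_id[match(truth$intron_id, fam$intron_id)]
  expect_true(all(outer(inf, inf, "==") ==
                    outer(truth$family_id, truth$family_id, "==")))

  # input-order invariance of the full clustering
  perm <- sample(nrow(cat1$introns))
  fam2 <- build_families(cat1$introns[perm, ], pairs, cat1$assignments)
  expect_identical(fam, fam2)

  # monotonicity: stricter thresholds only remove homology edges
  for (th2 in list(homology_thresholds(min_identity = 0.9),
                   homology_thresholds(min_coverage = 0.6))) {
    stricter <- pairs
    stricter$homologous <- pairs$coverage_ab > th2$min_coverage &
      pairs$coverage_ba > th2$min_coverage &
      pairs$identity_ab > 100 * th2$min_identity &
      pairs$identity_ba > 100 * th2$min_identity
    expect_true(all(!stricter$homologous | pairs$homologous))
    fam3 <- build_families(cat1$introns, stricter, cat1$assignments)
    # every stricter family is contained in one original family
    merged <- merge(fam3[, c("intron_id", "family_id")],
                    fam[, c("intron_id", "family_id")], by = "intron_id")
    expect_true(all(tapply(merged$family_id.y, merged$family_id.x,
                           function(x) length(unique(x))) == 1L))
  }
})
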