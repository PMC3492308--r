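test_that("codon/phase arithmetic matches the convention and inverts", {
  expect_equal(codon_and_phase(201), data.frame(codon = 67L, phase = 0L))
  expect_equal(codon_and_phase(490), data.frame(codon = 164L, phase = 1L))
  expect_equal(codon_and_phase(1), data.frame(codon = 1L, phase = 1L))
  expect_equal(codon_and_phase(3), data.frame(codon = 1L, phase = 0L))
  p <- 1:100000
  cp <- codon_and_phase(p)
  expect_identical(insertion_point(cp$codon, cp$phase), as.integer(p))
})

test_that("translation uses table 4 and rejects internal stops", {
  expect_equal(translate_coding("ATGTGA"), "MW")    # TGA = Trp
  expect_equal(translate_coding("ATGTAA"), "M")     # trailing stop dropped
  expect_error(translate_coding("ATGTAAATGTAA"),
               class = "cobintron_internal_stop")
  expect_error(translate_coding("ATGA"),
               class = "cobintron_cdna_not_codon_multiple")
  set.seed(6)
  expect_no_error(translate_coding(cobintron:::random_root_cds(394L)))
})

test_that("reference mapping handles identity, deletions and gap flags", {
  idm <- map_position_to_reference(1:4, "MKLV", "MKLV")
  expect_equal(idm$ref_codon, 1:4)
  expect_false(any(idm$ref_gap))
  # reference MKLV, query MLV (K deleted): query codon 2 (L) -> ref codon 3
  m <- map_position_to_reference(2, "MLV", "MKLV")
  expect_equal(m$ref_codon, 3L)
  # query has an extra residue facing a reference gap -> flagged, nearest left
  m2 <- map_position_to_reference(2, "MKLV", "MLV")
  expect_true(m2$ref_gap)
  expect_equal(m2$ref_codon, 1L)
  expect_error(map_position_to_reference(9, "MLV", "MKLV"),
               class = "cobintron_outside_alignment")
})

test_that("reference introns self-map to their own codon/phase", {
  sim <- simulate_catalogue(quick_config(37))
  ref <- sort(sim$tree$tip.label)[1]
  cat1 <- assign_positions(extract_all_introns(sim$catalogue),
                           reference = ref, normalize_sliding = FALSE)
  asn <- cat1$assignments[cat1$assignments$species_id == ref, ]
  pts <- cat1$introns$insertion_point[match(asn$intron_id,
                                            cat1$introns$intron_id)]
  expect_equal(asn$ref_codon, codon_and_phase(pts)$codon)
  expect_equal(asn$phase, codon_and_phase(pts)$phase)
  expect_false(any(asn$ref_gap))
})

make_sliding_pair <- function() {
  # species A: intron at p = 12 with consensus (T before, G last).
  # species B: same gdna content but annotated one base to the left, which
  # breaks the consensus; a +1 slide restores it and unifies the location.
  exon <- "ATGAAACCCTTTGGGAAATAA"
  set.seed(8)
  # boundary bases pinned so no junction ambiguity blurs the construction
  intrA <- paste0("TC", cobintron:::random_dna(46), "AG")   # 50 nt, ends G
  gdna <- paste0(substr(exon, 1, 12), intrA, substr(exon, 13, 21))
  recA <- gene_record("aa", gdna, exon, species_name = "Alpha alpha")
  # B's annotation: intron = gdna[12..61] (starts one earlier, ends one
  # earlier); cdna then differs in one base (T at 12 replaced by intron's
  # last base G)
  cdnaB <- paste0(substr(exon, 1, 11), "G", substr(exon, 13, 21))
  recB <- gene_record("bb", gdna, cdnaB, species_name = "Beta beta")
  list(recA = recA, recB = recB)
}

test_that("sliding introns are normalized onto one location", {
  pr <- make_sliding_pair()
  cat1 <- extract_all_introns(new_catalogue(list(pr$recA, pr$recB)))
  # B's greedy extraction lands one base left of A's
  pa <- cat1$introns$insertion_point[cat1$introns$species_id == "aa"]
  pb <- cat1$introns$insertion_point[cat1$introns$species_id == "bb"]
  expect_equal(pa, 12L)
  expect_equal(pb, 11L)
  cat2 <- assign_positions(cat1, reference = "aa")
  asn <- cat2$assignments
  expect_equal(unique(asn$ref_codon), 4L)
  expect_equal(unique(asn$phase), 0L)
  slid <- asn$slid_by[asn$species_id == "bb"]
  expect_equal(slid, 1L)
  expect_false(any(asn$unresolved_sliding))
  # the slid intron keeps its length and regains the consensus
  ib <- cat2$introns[cat2$introns$species_id == "bb", ]
  expect_equal(ib$length, 50L)
  expect_equal(ib$terminal_base, "G")
  expect_equal(ib$upstream_exon_base, "T")
  # idempotence: renormalizing changes nothing
  cat3 <- normalize_sliding_introns(cat2)
  expect_identical(cat3$assignments, cat2$assignments)
  expect_identical(cat3$introns, cat2$introns)
})

test_that("coincident introns are untouched and stubborn groups flagged", {
  sim <- simulate_catalogue(quick_config(43, gain_rate = 0, loss_rate = 0,
                                         transfer_rate = 0,
                                         transposition_rate = 0))
  cat1 <- assign_positions(extract_all_introns(sim$catalogue),
                           reference = sort(sim$tree$tip.label)[1])
  expect_true(all(cat1$assignments$slid_by == 0L))
  expect_false(any(cat1$assignments$unresolved_sliding))

  # a near-coincident pair with no consensus-restoring shift stays put:
  # B's intron is all C (no terminal G reachable within 5 nt)
  pr <- make_sliding_pair()
  exon <- pr$recA$cdna
  gB <- paste0(substr(exon, 1, 11), strrep("C", 50), substr(exon, 12, 21))
  recB <- gene_record("bb", gB, exon, species_name = "Beta beta")
  recA <- pr$recA
  suppressWarnings({
    cat2 <- extract_all_introns(new_catalogue(list(recA, recB)))
    cat3 <- assign_positions(cat2, reference = "aa")
  })
  asn <- cat3$assignments
  if (length(unique(cobintron:::ref_nt_location(asn$ref_codon,
                                                asn$phase))) > 1L) {
    expect_true(any(asn$unresolved_sliding))
    expect_true(all(asn$slid_by == 0L))
  }
})

test_that("names follow the genus-epithet-ordinal convention", {
  sim <- simulate_catalogue(quick_config(47))
  recs <- sim$catalogue$records
  binoms <- c("Monilinia fructicola", "Monilinia fructigena",
              "Monilia mumecola", "Ajellomyces dermatitidis",
              "Ustilaginoidea virens", "Botryotinia fuckeliana",
              "Gibberella zeae", "Podospora anserina")
  for (i in seq_along(recs)) recs[[i]]$species_name <- binoms[i]
  cat1 <- assign_positions(extract_all_introns(new_catalogue(recs)),
                           reference = names(recs)[1])
  asn <- cat1$assignments
  counts <- table(asn$species_id)
  for (sp in names(counts)) {
    nm <- sort(asn$name[asn$species_id == sp])
    ab <- cobintron:::species_abbreviations(
      names(recs), vapply(recs, `[[`, character(1), "species_name"))[[sp]]
    if (counts[[sp]] == 1L) expect_equal(nm, ab)
    else expect_equal(nm, sort(paste0(ab, seq_len(counts[[sp]]))))
  }
  # names are a bijection
  expect_false(anyDuplicated(asn$name) > 0)
  # colliding abbreviations split on the first distinguishing letter
  ab <- cobintron:::species_abbreviations(
    c("a", "b"), c("Monilinia fructicola", "Monilinia fructigena"))
  expect_equal(unname(ab), c("Mfc", "Mfg"))
  # the 3rd intron of M. mumecola is "Mm3"
  mm <- names(recs)[vapply(recs, function(r)
    identical(r$species_name, "Monilia mumecola"), logical(1))]
  mm_names <- asn$name[asn$species_id == mm]
  if (length(mm_names) >= 3L) expect_true("Mm3" %in% mm_names)
})
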