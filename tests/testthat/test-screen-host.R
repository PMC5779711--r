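test_that("gel selection applies the 50-bp floor unconditionally and inclusive bounds", {
  frs <- lapply(c(49, 50, 100, 600, 6000), function(L) {
    dna_molecule(random_dna(L, seed = L))
  })
  unbounded <- gel_select(frs, 1, Inf)
  expect_equal(sort(vapply(unbounded, mol_length, integer(1))),
               c(50, 100, 600, 6000))
  expect_equal(vapply(gel_select(frs, 100, 100), mol_length, integer(1)), 100)
  expect_equal(vapply(gel_select(frs, 500, 1000), mol_length, integer(1)), 600)
  expect_error(gel_select(frs, 10, 5), "min_len")
})

test_that("feature screening applies all criteria and diagnoses unknown names", {
  lib <- fixture_library()
  tp <- generate_fixture("toy_plasmid", seed = 4)
  junk <- dna_molecule(random_dna(500, seed = 9), "circular")
  linear_amp <- annotate_features(
    dna_molecule(paste0(lib$entries$ampR$seq, random_dna(40, seed = 10))), lib)
  mix <- c(tp$molecules, list(junk, linear_amp))
  sel <- feature_screen(mix, screen_condition(
    require_circular = TRUE,
    feature_counts = list(list(name = "ampR", cmp = "eq", count = 1),
                          list(name = "pMB1_ori", cmp = "eq", count = 1))))
  expect_length(sel, 1)
  expect_equal(sel[[1]]$id, "toy_plasmid")
  # require_circular = FALSE on an all-circular set is empty
  expect_length(feature_screen(c(tp$molecules, list(junk)),
                               screen_condition(require_circular = FALSE)), 0)
  # gt 0 keeps multi-copy features
  twice <- annotate_features(
    dna_molecule(paste0(lib$entries$ampR$seq, random_dna(30, seed = 11),
                        lib$entries$ampR$seq)), lib)
  expect_length(feature_screen(list(twice), screen_condition(
    feature_counts = list(list(name = "ampR", cmp = "gt", count = 0)))), 1)
  # unknown feature name: zero matches plus a diagnostic
  out <- feature_screen(list(junk), screen_condition(
    feature_counts = list(list(name = "nosuch", cmp = "eq", count = 1))))
  expect_length(out, 0)
  expect_match(attr(out, "diagnostic"), "nosuch")
})

test_that("PCR screening keeps molecules amplifying inside the strict length range", {
  tp <- generate_fixture("toy_plasmid", seed = 4)$molecules[[1]]
  primers <- c(f = substr(tp$seq, 101, 120),
               r = rc_str(substr(tp$seq, 881, 900)))
  junk <- dna_molecule(random_dna(500, seed = 9), "circular")
  kept <- pcr_screen(list(tp, junk), primers, c(700, 900))
  expect_length(kept, 1)
  expect_equal(kept[[1]]$id, "toy_plasmid")
  # strict bounds: the 800-bp product fails a [100, 799] window
  expect_length(pcr_screen(list(tp), primers, c(100, 799)), 0)
  # primers that bind nothing drop everything
  expect_length(pcr_screen(list(tp), c(f = random_dna(20, seed = 12),
                                       r = random_dna(20, seed = 13)),
                           c(0, 1e6)), 0)
})

test_that("ORF detection honors start codons, frames, strands and circular wrap", {
  m <- dna_molecule(paste0("AA", "ATGAAACCCGGGTTT", "TAA", "CC"))
  orfs <- detect_orfs(m, "ATG", min_len = 15, both_strands = FALSE)
  expect_length(orfs, 1)
  expect_equal(c(orfs[[1]]$start, orfs[[1]]$end), c(2, 20))
  expect_length(detect_orfs(m, "ATG", min_len = 21, both_strands = FALSE), 0)
  # GTG start found only when requested
  g <- dna_molecule("GTGAAACCCGGGTTTTAA")
  expect_length(detect_orfs(g, "ATG", 18, FALSE), 0)
  expect_length(detect_orfs(g, c("ATG", "GTG"), 18, FALSE), 1)
  # minus strand
  mm <- dna_molecule(rc_str(m$seq))
  orfs_m <- detect_orfs(mm, "ATG", 15, both_strands = TRUE)
  expect_length(orfs_m, 1)
  expect_equal(orfs_m[[1]]$strand, "-")
  # circular wrap: ATG AAA CCC | GGG TAA split across the origin
  circ <- dna_molecule(paste0("GGGTAA", "CCCCCCCC", "ATGAAACCC"), "circular")
  worfs <- detect_orfs(circ, "ATG", 15, both_strands = FALSE)
  wrapped <- Filter(function(f) f$end > nchar(circ$seq), worfs)
  expect_length(wrapped, 1)
  expect_equal(c(wrapped[[1]]$start, wrapped[[1]]$end), c(14, 29))
})

test_that("alignment comparison annotates matches, substitutions and indels", {
  rp <- generate_fixture("read_pair", seed = 6)
  tmpl <- rp$molecules[[1]]
  t1 <- compare_sequences(tmpl, rp$reads["exact"])
  match1 <- Filter(function(f) f$kind == "alignment_match", t1$features)
  expect_length(match1, 1)
  expect_equal(c(match1[[1]]$start, match1[[1]]$end), rp$manifest$exact_span)
  t2 <- compare_sequences(tmpl, rp$reads["substituted"])
  mm <- Filter(function(f) f$kind == "alignment_mismatch", t2$features)
  expect_length(mm, 1)
  expect_equal(mm[[1]]$start, rp$manifest$sub_template_pos)
  matches2 <- Filter(function(f) f$kind == "alignment_match", t2$features)
  expect_length(matches2, 2)
  t3 <- compare_sequences(tmpl, rp$reads["inserted"])
  ins <- Filter(function(f) f$kind == "alignment_insertion", t3$features)
  expect_length(ins, 1)
  expect_equal(ins[[1]]$qualifiers$length, "3")
  # multiple queries stack; hopeless queries are reported unaligned
  t4 <- compare_sequences(tmpl, c(r1 = unname(rp$reads["exact"]),
                                  bad = random_dna(60, seed = 99)))
  expect_true("bad" %in% attr(t4, "unaligned"))
  # reverse-orientation reads align on the minus strand
  t5 <- compare_sequences(tmpl, c(rc = rc_str(rp$reads[["exact"]])))
  m5 <- Filter(function(f) f$kind == "alignment_match", t5$features)
  expect_equal(m5[[1]]$strand, "-")
  expect_equal(c(m5[[1]]$start, m5[[1]]$end), rp$manifest$exact_span)
})

test_that("transformation modes split DNA across cells as specified", {
  host <- host_cell("DH5a", primase_commands = "pMB1")
  p1 <- dna_molecule(random_dna(300, seed = 1), "circular")
  p2 <- dna_molecule(random_dna(320, seed = 2), "circular")
  expect_length(transform_dna(host, list(p1, p2), mode = "all_in_one"), 1)
  expect_length(transform_dna(host, list(p1, p2), mode = "all_in_one")[[1]]$hosted, 2)
  each <- transform_dna(host, list(p1, p2), mode = "one_per_cell")
  expect_length(each, 2)
  expect_true(all(vapply(each, function(cl) length(cl$hosted), integer(1)) == 1))
  comb <- transform_dna(host, list(p1, p2), mode = "combinational")
  expect_length(comb, 3)
  sizes <- sort(vapply(comb, function(cl) length(cl$hosted), integer(1)))
  expect_equal(sizes, c(1, 1, 2))
  expect_error(transform_dna(host, list(p1), method = "conjugation"),
               "not competent")
})

test_that("combinational transformation yields 2^n - 1 distinct cells", {
  host <- host_cell("DH5a")
  dnas <- lapply(1:4, function(i) dna_molecule(random_dna(100 + i, seed = i),
                                               "circular"))
  cells <- transform_dna(host, dnas, mode = "combinational")
  expect_length(cells, 15)
  keys <- vapply(cells, function(cl) {
    paste(sort(vapply(cl$hosted, canonical_hash, character(1))), collapse = "+")
  }, character(1))
  expect_equal(anyDuplicated(keys), 0)
})

test_that("incubation enforces origin support before antibiotic selection", {
  lib <- fixture_library()
  amp_plas <- annotate_features(
    generate_fixture("toy_plasmid", seed = 4)$molecules[[1]], lib)
  host <- host_cell("DH5a", primase_commands = "pMB1")
  with_p <- transform_dna(host, list(amp_plas))[[1]]
  without <- host
  surv <- incubate(list(with_p, without), "ampicillin")
  expect_length(surv, 1)
  expect_length(surv[[1]]$hosted, 1)
  # plasmid with an unsupported origin is lost; the cell then dies on selection
  r6k <- dna_molecule(random_dna(400, seed = 5), "circular",
                      features = list(
                        feature("oriR6K", "ori", 10, 50,
                                qualifiers = list(origin = "R6K")),
                        feature("kanR", "resistance", 100, 200,
                                qualifiers = list(antibiotic = "kanamycin"))))
  cell <- transform_dna(host, list(r6k))[[1]]
  expect_length(incubate(cell, "kanamycin"), 0)
  # without antibiotics every cell survives but the plasmid is still lost
  no_ab <- incubate(cell, character(0))
  expect_length(no_ab, 1)
  expect_length(no_ab[[1]]$hosted, 0)
  # intrinsic resistance rescues a plasmid-free cell
  tough <- host_cell("tough", intrinsic_resistances = "ampicillin")
  expect_length(incubate(tough, "ampicillin"), 1)
})

test_that("plasmid extraction returns hosted DNA only and never mutates the cell", {
  lib <- fixture_library()
  g <- generate_fixture("genomic_locus", seed = 9)$molecules[[1]]
  p1 <- dna_molecule(random_dna(300, seed = 6), "circular")
  p2 <- dna_molecule(random_dna(310, seed = 7), "circular")
  cell <- host_cell("h", genome_fragments = list(g), hosted = list(p1, p2))
  got <- extract_plasmids(cell)
  expect_length(got, 2)
  expect_false(any(vapply(got, function(m) m$topology == "genomic_fragment",
                          logical(1))))
  expect_identical(extract_plasmids(cell), got)
  expect_length(extract_plasmids(host_cell("empty")), 0)
})
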