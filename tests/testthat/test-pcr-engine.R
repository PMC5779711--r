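test_that("Wallace-rule Tm is the textbook formula and GC never lowers it", {
  expect_equal(melting_temperature("AATTAATTGGCC", tm_params("wallace")), 32)
  set.seed(8)
  for (i in 1:10) {
    s <- random_dna(sample(8:30, 1))
    expect_gte(melting_temperature(paste0(s, "GC"), tm_params("wallace")),
               melting_temperature(s, tm_params("wallace")))
  }
  expect_error(melting_temperature("ACGN"), "ACGT")
})

test_that("nearest-neighbor Tm equals an independent sum over the unified table", {
  # hand calculation with the published dH (kcal/mol) / dS (cal/mol/K)
  # increments, salt-corrected entropy and the standard hybridization
  # equation, written out without the package's helper
  dh_tab <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5,
              TG = -8.5, GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8,
              GA = -8.2, TC = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
              CC = -8.0)
  ds_tab <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
              TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
              GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
              CC = -19.9)
  seqs <- "AGCGTCAGACCGTTAGCCTA"   # 20-mer
  chars <- strsplit(seqs, "")[[1]]
  stacks <- paste0(chars[-length(chars)], chars[-1])
  init <- function(b) if (b %in% c("G", "C")) c(0.1, -2.8) else c(2.3, 4.1)
  dh <- sum(dh_tab[stacks]) + init(chars[1])[1] + init(chars[20])[1]
  ds <- sum(ds_tab[stacks]) + init(chars[1])[2] + init(chars[20])[2]
  ds <- ds + 0.368 * 19 * log(0.05)
  expected <- 1000 * dh / (ds + 1.987 * log(5e-7 / 4)) - 273.15
  expect_equal(melting_temperature(seqs), expected, tolerance = 1e-10)
  expect_error(melting_temperature("ACGTA"), "6-60")
})

test_that("tm_profile equals pointwise melting_temperature and wraps on circles", {
  mol <- dna_molecule(random_dna(60, seed = 14))
  prof <- tm_profile(mol, 12, tm_params("wallace"))
  expect_length(prof, 49)
  for (i in c(1, 20, 49)) {
    expect_equal(prof[i], melting_temperature(substr(mol$seq, i, i + 11),
                                              tm_params("wallace")))
  }
  at <- dna_molecule(strrep("AT", 15))
  expect_true(all(tm_profile(at, 10, tm_params("wallace")) == 20))
  circ <- dna_molecule(mol$seq, "circular")
  expect_length(tm_profile(circ, 12, tm_params("wallace")), 60)
  expect_error(tm_profile(mol, 5), ">= 6")
})

test_that("two-primer PCR amplifies the delimited region; tails are retained verbatim", {
  tmpl <- dna_molecule(random_dna(400, seed = 21))
  fwd <- pcr_primer("f", substr(tmpl$seq, 11, 30))
  rev <- pcr_primer("r", rc_str(substr(tmpl$seq, 371, 390)))
  res <- simulate_pcr(tmpl, list(fwd, rev))
  expect_length(res$products, 1)
  expect_equal(mol_length(res$products[[1]]), 380)
  expect_equal(res$products[[1]]$seq, substr(tmpl$seq, 11, 390))
  # 5' tail
  tail <- "GGGTTTAAACCCGGG"
  res2 <- simulate_pcr(tmpl, list(pcr_primer("ft", paste0(tail, fwd$sequence)), rev))
  expect_equal(mol_length(res2$products[[1]]), 395)
  tops <- c(res2$products[[1]]$seq, rc_str(res2$products[[1]]$seq))
  expect_true(any(startsWith(tops, tail)))
  # phosphorylated primers give phosphorylated product ends
  resP <- simulate_pcr(tmpl, list(pcr_primer("fp", fwd$sequence,
                                             phosphorylated = TRUE),
                                  pcr_primer("rp", rev$sequence,
                                             phosphorylated = TRUE)))
  expect_true(resP$products[[1]]$left_end$phos)
  expect_true(resP$products[[1]]$right_end$phos)
})

test_that("product termini always match primer sequences structurally", {
  set.seed(23)
  for (i in 1:6) {
    tmpl <- dna_molecule(random_dna(300))
    a <- sample(50:120, 1); b <- sample(180:260, 1)
    prs <- list(pcr_primer("f", substr(tmpl$seq, a, a + 19)),
                pcr_primer("r", rc_str(substr(tmpl$seq, b, b + 19))))
    res <- simulate_pcr(tmpl, prs)
    for (p in res$products) {
      starts_f <- startsWith(p$seq, prs[[1]]$sequence) ||
        startsWith(p$seq, prs[[2]]$sequence)
      starts_r <- startsWith(rc_str(p$seq), prs[[1]]$sequence) ||
        startsWith(rc_str(p$seq), prs[[2]]$sequence)
      expect_true(starts_f && starts_r)
    }
  }
})

test_that("circular templates support origin-spanning amplicons", {
  tmpl <- random_dna(400, seed = 25)
  circ <- dna_molecule(tmpl, "circular")
  fwd <- pcr_primer("f", substr(tmpl, 351, 370))
  rev <- pcr_primer("r", rc_str(substr(tmpl, 51, 70)))
  res <- simulate_pcr(circ, list(fwd, rev))
  lens <- vapply(res$products, mol_length, integer(1))
  expect_true(120 %in% lens)
  amp <- res$products[[which(lens == 120)]]
  expect_equal(amp$seq, paste0(substr(tmpl, 351, 400), substr(tmpl, 1, 70)))
})

test_that("overlap extension fuses templates sharing a junction", {
  junction <- random_dna(25, seed = 33)
  ta <- dna_molecule(paste0(random_dna(200, seed = 31), junction))
  tb <- dna_molecule(paste0(junction, random_dna(200, seed = 32)))
  of <- pcr_primer("of", substr(ta$seq, 1, 20))
  orv <- pcr_primer("or", rc_str(substr(tb$seq, 206, 225)))
  res <- simulate_pcr(list(ta, tb), list(of, orv))
  lens <- vapply(res$products, mol_length, integer(1))
  expect_true(425 %in% lens)
  fused <- res$products[[which(lens == 425)]]
  expect_equal(fused$seq, paste0(ta$seq, substr(tb$seq, 26, 225)))
})

test_that("single-primer reactions and primerless templates give empty product sets", {
  tmpl <- dna_molecule(random_dna(200, seed = 26))
  one <- simulate_pcr(tmpl, pcr_primer("f", substr(tmpl$seq, 11, 30)))
  expect_length(one$products, 0)
  none <- simulate_pcr(tmpl, pcr_primer("x", random_dna(20, seed = 27)))
  expect_length(none$products, 0)
})

test_that("oligo analysis finds hairpins, self-dimers and cross-dimers by NN energy", {
  expect_length(analyze_oligos("AAAAAAAAAAAA"), 0)
  hp <- analyze_oligos("GGGGCCAAAAAAGGCCCC")
  kinds <- vapply(hp, `[[`, character(1), "kind")
  expect_true("hairpin" %in% kinds)
  expect_true(all(vapply(hp, `[[`, numeric(1), "delta_g") <= 0))
  # perfect palindrome: self-dimer spans all 16 positions at full duplex energy
  pal <- "GCGCGCGCGCGCGCGC"
  sd <- Filter(function(r) r$kind == "self_dimer", analyze_oligos(pal))
  expect_length(sd, 1)
  expect_length(sd[[1]]$positions, 16)
  expect_equal(sd[[1]]$delta_g, clonesim:::duplex_dg37(pal))
  # cross-dimer between complementary oligos
  a <- "ACGTACGGTCAGTT"
  cd <- Filter(function(r) r$kind == "cross_dimer", analyze_oligos(a, rc_str(a)))
  expect_length(cd, 1)
  expect_length(cd[[1]]$positions, nchar(a))
})

test_that("one_click primers are minimal for the Tm threshold", {
  mol <- dna_molecule(random_dna(300, seed = 28))
  for (tm_min in c(40, 55, 64)) {
    r <- design_primers(mol, "one_click", position = 50, strand = "+",
                        tm_min = tm_min)
    expect_equal(substr(mol$seq, 51, 51), substr(r$sequence, 1, 1))
    expect_gte(r$tm, tm_min)
    if (r$length > 1) {
      expect_lt(melting_temperature(substr(r$sequence, 1, r$length - 1),
                                    tm_params("wallace")), tm_min)
    }
  }
  # degenerate floor: tm_min 0 gives the single-base minimal primer
  r0 <- design_primers(mol, "one_click", position = 10, strand = "+", tm_min = 0)
  expect_equal(r0$length, 1)
  # minus strand: 5' end at the clicked base
  rm_ <- design_primers(mol, "one_click", position = 100, strand = "-",
                        tm_min = 50)
  expect_equal(substr(rm_$sequence, 1, 1),
               rc_str(substr(mol$seq, 101, 101)))
})

test_that("pair_search pairs amplify the requested region when fed to simulate_pcr", {
  set.seed(29)
  for (i in 1:5) {
    mol <- dna_molecule(random_dna(400))
    region <- c(120, 260)
    pairs <- design_primers(mol, "pair_search", region = region, tm_min = 50)
    expect_gt(nrow(pairs), 0)
    res <- simulate_pcr(mol, c(f = pairs$forward[1], r = pairs$reverse[1]))
    lens <- vapply(res$products, mol_length, integer(1))
    expect_true(any(lens >= diff(region)))
  }
})

test_that("sequencing simulation returns the downstream read and rejects ambiguity", {
  tmpl <- dna_molecule(random_dna(500, seed = 30))
  primer <- pcr_primer("s", substr(tmpl$seq, 81, 100))
  expect_equal(simulate_sequencing(tmpl, primer, 300),
               substr(tmpl$seq, 101, 400))
  expect_equal(nchar(simulate_sequencing(tmpl,
                                         pcr_primer("e", substr(tmpl$seq, 431, 450)),
                                         300)), 50)
  dup <- dna_molecule(paste0(tmpl$seq, tmpl$seq))
  expect_error(simulate_sequencing(dup, primer, 100), "multiple")
  expect_error(simulate_sequencing(tmpl, pcr_primer("n", random_dna(20, seed = 31)),
                                   100), "does not anneal")
  # circular template wraps
  circ <- dna_molecule(tmpl$seq, "circular")
  pr <- pcr_primer("c", substr(tmpl$seq, 481, 500))
  expect_equal(simulate_sequencing(circ, pr, 40), substr(tmpl$seq, 1, 40))
})
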