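reg <- read_enzyme_table()

test_that("single-site circular digestion yields one linear fragment with cut-derived ends", {
  plas <- dna_molecule(paste0("GAATTC", random_dna(200, seed = 3)), "circular")
  res <- digest(plas, "EcoRI", registry = reg)
  expect_length(res$fragments, 1)
  f <- res$fragments[[1]]
  expect_equal(f$topology, "linear")
  expect_equal(mol_length(f), 206)
  for (e in list(f$left_end, f$right_end)) {
    expect_equal(e$overhang, "5ov")
    expect_equal(e$seq, "AATT")
    expect_true(e$phos)
  }
  expect_length(res$warnings, 0)
})

test_that("zero sites leave the substrate unchanged, k sites give k / k+1 fragments", {
  lin <- dna_molecule(random_dna(120, seed = 5))
  res <- digest(lin, "NotI", registry = reg)
  expect_length(res$fragments, 1)
  expect_equal(res$fragments[[1]]$seq, lin$seq)
  two <- dna_molecule(paste0(random_dna(50, seed = 6), "GAATTC",
                             random_dna(50, seed = 7), "GAATTC",
                             random_dna(50, seed = 8)))
  expect_length(digest(two, "EcoRI", registry = reg)$fragments, 3)
  circ2 <- dna_molecule(two$seq, "circular")
  expect_length(digest(circ2, "EcoRI", registry = reg)$fragments, 2)
})

test_that("Type IIS cutting is template-derived, outside the site", {
  payload <- "CAGG"   # designed overhang, not part of the recognition site
  m <- dna_molecule(paste0(random_dna(20, seed = 9), "GGTCTC", "A", payload,
                           random_dna(30, seed = 10)))
  res <- digest(m, "BsaI", registry = reg)
  expect_length(res$fragments, 2)
  right <- res$fragments[[2]]
  expect_equal(right$left_end$overhang, "5ov")
  expect_equal(right$left_end$seq, payload)
  expect_true(startsWith(right$seq, payload))
})

test_that("digestion conserves total top-strand mass", {
  set.seed(12)
  enzymes <- reg[c("EcoRI", "BamHI", "PstI", "SmaI", "BsaI")]
  for (i in 1:10) {
    topo <- sample(c("linear", "circular"), 1)
    mol <- dna_molecule(random_dna(sample(300:800, 1)), topo)
    res <- digest(mol, enzymes)
    expect_equal(sum(vapply(res$fragments, mol_length, integer(1))),
                 mol_length(mol))
  }
})

test_that("overlapping sites of distinct enzymes warn and drop the impossible cut", {
  # BamHI GGATCC and the overlapping XhoI site share bases: construct overlap
  # of EcoRI (GAATTC) with an AccI site across it is fiddly; use two enzymes
  # whose overhang regions collide: EcoRI inside a straddling BsaI cut window
  m <- dna_molecule(paste0(random_dna(20, seed = 13), "GGTCTCAGAATTCA",
                           random_dna(30, seed = 14)))
  res <- digest(m, reg[c("BsaI", "EcoRI")])
  expect_gt(length(res$warnings), 0)
  expect_equal(sum(vapply(res$fragments, mol_length, integer(1))), mol_length(m))
})

test_that("features split by a cut are truncated and tagged", {
  pad <- clonesim:::scrub_patterns(random_dna(100, seed = 15), "GAATTC")
  n <- 106
  # feature wraps the origin and spans the EcoRI cut at gap 1
  plas <- dna_molecule(paste0("GAATTC", pad), "circular",
                       features = list(feature("gene", "CDS", n - 10, n + 3)))
  res <- digest(plas, "EcoRI", registry = reg)
  f <- res$fragments[[1]]
  split_feats <- Filter(function(x) x$name == "gene", f$features)
  expect_equal(length(split_feats), 2)
  expect_true(all(vapply(split_feats, function(x)
    identical(x$qualifiers$truncated, "true"), logical(1))))
  expect_equal(sum(vapply(split_feats, function(x) x$end - x$start, integer(1))),
               13)   # the pieces jointly cover the whole feature
})

test_that("CRISPR digestion cuts blunt 3 bp PAM-proximal, requires the PAM", {
  tmpl <- random_dna(60, seed = 16)
  spacer <- substr(tmpl, 11, 30)
  g <- guide_rna("g", spacer, "NGG", 3)
  with_pam <- dna_molecule(paste0(substr(tmpl, 1, 30), "AGG",
                                  random_dna(27, seed = 17)))
  frags <- crispr_digest(with_pam, g)
  expect_length(frags, 2)
  expect_equal(mol_length(frags[[1]]), 27)    # cut 3 bp 5' of the PAM
  expect_equal(frags[[1]]$right_end$overhang, "blunt")
  no_pam <- dna_molecule(paste0(substr(tmpl, 1, 30), "ATT",
                                random_dna(27, seed = 17)))
  expect_length(crispr_digest(no_pam, g), 1)
  expect_error(guide_rna("short", "ACGTACGTACGTACG"), ">= 16")
})

test_that("minus-strand protospacers mirror to top-strand cut positions", {
  tmpl <- random_dna(60, seed = 18)
  spacer <- substr(tmpl, 11, 30)
  g <- guide_rna("g", spacer, "NGG", 3)
  plus <- dna_molecule(paste0(substr(tmpl, 1, 30), "CGG",
                              random_dna(27, seed = 19)))
  minus <- dna_molecule(rc_str(plus$seq))
  fp <- sort(vapply(crispr_digest(plus, g), mol_length, integer(1)))
  fm <- sort(vapply(crispr_digest(minus, g), mol_length, integer(1)))
  expect_equal(fp, fm)
})

test_that("crispr_digest equals digestion with the manually built temporary enzyme", {
  tmpl <- random_dna(80, seed = 20)
  spacer <- substr(tmpl, 21, 40)
  g <- guide_rna("g", spacer, "NGG", 3)
  sub <- dna_molecule(paste0(substr(tmpl, 1, 40), "TGG", random_dna(37, seed = 21)))
  expect_equal(hashes_of(crispr_digest(sub, g)),
               hashes_of(digest(sub, list(crispr_enzyme(g)))$fragments))
})

test_that("enzyme_analysis filters by per-substrate site-count conditions", {
  scrub <- function(x) clonesim:::scrub_patterns(x, c("GAATTC", "GGATCC",
                                                      "AAGCTT"))
  plasA <- dna_molecule(paste0("GAATTC", scrub(random_dna(80, seed = 22)),
                               "GGATCC", scrub(random_dna(80, seed = 23))),
                        "circular")
  plasB <- dna_molecule(paste0("GAATTC", scrub(random_dna(80, seed = 24))),
                        "circular")
  small <- reg[c("EcoRI", "BamHI", "HindIII")]
  ones <- enzyme_analysis(plasA, list(list(cmp = "eq", count = 1)),
                          registry = small)
  expect_setequal(ones, c("EcoRI", "BamHI"))
  zeros <- enzyme_analysis(plasA, list(list(cmp = "eq", count = 0)),
                           registry = small)
  expect_setequal(zeros, "HindIII")
  # (eq 1 on A) AND (eq 0 on B) intersects the per-molecule answers
  both <- enzyme_analysis(list(plasA, plasB),
                          list(list(cmp = "eq", count = 1, mols = 1),
                               list(cmp = "eq", count = 0, mols = 2)),
                          registry = small)
  expect_setequal(both, "BamHI")
})

test_that("find_buffer resolves vendor aliases and ranks by max-min activity", {
  tf <- read_buffer_table(vendor = "Thermofisher")
  # SpeI resolves through the Thermofisher alias BcuI
  res <- find_buffer("SpeI", tf, threshold = 75)
  expect_equal(res$buffer[1], "B")           # BcuI 100, alphabetical tie-break
  expect_equal(res$min_activity[1], 100)
  pair <- find_buffer(c("SpeI", "EcoRI"), tf, threshold = 75)
  expect_equal(pair$min_activity[1], 50)     # best achievable minimum
  expect_true(all(pair$min_activity == sort(pair$min_activity, decreasing = TRUE)))
  expect_true(all(pair$below_threshold == (pair$min_activity < 75)))
  expect_error(find_buffer("NheI", tf), "no Thermofisher product")
  # explicit max-min example
  syn <- structure(list(vendor = "X", table = data.frame(
    vendor = "X", buffer = rep(c("B1", "B2"), each = 2),
    alias = rep(c("e1", "e2"), 2), activity = c(100, 50, 75, 75))),
    class = "buffer_system")
  al <- data.frame(alias = c("e1", "e2"), canonical = c("E1", "E2"),
                   vendor = "X")
  r2 <- find_buffer(c("e1", "e2"), syn, threshold = 60, aliases = al)
  expect_equal(r2$buffer[1], "B2")
})
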