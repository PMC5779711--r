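# Deterministic synthetic-construct generator. Every test input is built in
# code with a known ground truth: the returned object carries a `manifest`
# with the designed coordinates, lengths and expectations, so integration
# tests assert against the manifest rather than magic constants. The same
# (kind, seed, parameters) always yields byte-identical output.

# run code under a fixed RNG seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Random concrete DNA sequence
#'
#' @param n length in bp.
#' @param seed optional seed (uses the current RNG stream when `NULL`).
#' @return a DNA string.
#' @export
random_dna <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# deterministically mutate `seqs` until none of `patterns` occurs (either
# strand) outside the protected intervals (0-based half-open list)
scrub_patterns <- function(seqs, patterns, protect = list()) {
  protected <- function(pos, len) {
    any(vapply(protect, function(iv) pos < iv[2] && pos + len > iv[1],
               logical(1)))
  }
  rotate_base <- function(ch) c(A = "C", C = "G", G = "T", T = "A")[[ch]]
  for (iter in 1:200) {
    changed <- FALSE
    for (pat in patterns) {
      for (p in c(pat, revcomp(pat))) {
        starts <- iupac_match_starts(seqs, p)
        starts <- starts[!vapply(starts, protected, logical(1), nchar(p))]
        if (length(starts) == 0L) next
        # flip the middle base of the first offending occurrence
        pos <- starts[1] + nchar(p) %/% 2L
        ch <- substr(seqs, pos + 1L, pos + 1L)
        substr(seqs, pos + 1L, pos + 1L) <- rotate_base(ch)
        changed <- TRUE
      }
    }
    if (!changed) return(seqs)
  }
  stop("could not scrub patterns deterministically", call. = FALSE)
}

# small synthetic building blocks (fixed sequences so fixtures are stable)
.fx_ori_seq <- function() {
  paste0("TTGAGATCCTTTTTTTCTGCGCGTAATCTGCTGCTTGCAAACAAAAAAACCACCGCTACC")
}

.fx_cds <- function(n_codons, seed) {
  # start codon + random non-stop codons + stop
  with_seed(seed, {
    codons <- c("GCT", "GCC", "AAA", "GAA", "CTG", "GGT", "CCG", "ACC",
                "TAT", "TGG", "CAT", "ATC", "AGC", "GTT", "CAG", "GAC")
    paste0("ATG", paste(sample(codons, n_codons - 2L, replace = TRUE),
                        collapse = ""), "TAA")
  })
}

#' Feature library matching the bundled fixtures
#'
#' Contains the synthetic ori, ampR and kanR blocks that
#' [generate_fixture()] plants, so fixture products can be screened.
#'
#' @return a [feature_library()].
#' @export
fixture_library <- function() {
  feature_library(list(
    pMB1_ori = list(seq = .fx_ori_seq(), kind = "ori",
                    qualifiers = list(origin = "pMB1")),
    ampR = list(seq = .fx_cds(50L, seed = 101L), kind = "resistance",
                qualifiers = list(antibiotic = "ampicillin")),
    kanR = list(seq = .fx_cds(40L, seed = 202L), kind = "resistance",
                qualifiers = list(antibiotic = "kanamycin"))
  ))
}

#' Deterministic test-construct generator
#'
#' Builds synthetic substrates with machine-readable ground truth:
#'
#' * `toy_plasmid`: circular backbone with a named ori, an ampR CDS and an
#'   MCS containing unique EcoRI/BamHI/HindIII sites.
#' * `golden_gate_set`: circular backbone plus `n_inserts` linear inserts
#'   whose BsaI sites release fragments with a designed cycle of unique
#'   4-nt overhangs.
#' * `lox_substrate`: circular plasmid with two loxP sites (direct or
#'   inverted) a known distance apart.
#' * `att_substrate_pair`: one plasmid carrying attB, one carrying attP
#'   (PhiC31, irreversible).
#' * `genomic_locus`: a genomic fragment with a target gene flanked by
#'   unique context, for lambda Red cassette tests (see
#'   [lambda_cassette()]).
#' * `gibson_set`: `n_frags` linear fragments, with shared terminal
#'   overlaps (`overlap > 0`) or disjoint plus terminal primers
#'   (`overlap = 0`, for the assembly designer).
#' * `read_pair`: a template plus reads with planted substitutions and an
#'   insertion, for [compare_sequences()].
#'
#' @param kind fixture kind (see above).
#' @param seed integer seed; the same spec always yields identical output.
#' @param ... size parameters per kind (documented defaults below).
#' @return list with `molecules`, `manifest`, and kind-specific extras.
#' @export
generate_fixture <- function(kind = c("toy_plasmid", "golden_gate_set",
                                      "lox_substrate", "att_substrate_pair",
                                      "genomic_locus", "gibson_set",
                                      "read_pair"),
                             seed = 1L, ...) {
  kind <- match.arg(kind)
  switch(kind,
    toy_plasmid = .fx_toy_plasmid(seed, ...),
    golden_gate_set = .fx_golden_gate(seed, ...),
    lox_substrate = .fx_lox(seed, ...),
    att_substrate_pair = .fx_att_pair(seed, ...),
    genomic_locus = .fx_genomic_locus(seed, ...),
    gibson_set = .fx_gibson(seed, ...),
    read_pair = .fx_read_pair(seed, ...))
}

.fx_toy_plasmid <- function(seed, len = 3000L) {
  lib <- fixture_library()
  ori <- lib$entries$pMB1_ori$seq
  ampr <- lib$entries$ampR$seq
  mcs <- paste0("GAATTC", "ACGCTAGCTT", "GGATCC", "TTGCAGTCAA", "AAGCTT")
  pad_len <- len - nchar(ori) - nchar(ampr) - nchar(mcs)
  stopifnot(pad_len >= 300L)
  p1 <- with_seed(seed, random_dna(pad_len %/% 3L))
  p2 <- with_seed(seed + 1L, random_dna(pad_len %/% 3L))
  p3 <- with_seed(seed + 2L, random_dna(pad_len - 2L * (pad_len %/% 3L)))
  seqs <- paste0(p1, ori, p2, ampr, p3, mcs)
  # unique sites: remove stray occurrences outside the MCS
  mcs_start <- nchar(seqs) - nchar(mcs)
  seqs <- scrub_patterns(seqs, c("GAATTC", "GGATCC", "AAGCTT", "GGTCTC"),
                         protect = list(c(mcs_start, nchar(seqs))))
  mol <- annotate_features(dna_molecule(seqs, "circular", id = "toy_plasmid"),
                           lib)
  list(molecules = list(mol),
       manifest = list(length = nchar(seqs),
                       mcs_start = mcs_start,
                       site_counts = c(EcoRI = 1L, BamHI = 1L, HindIII = 1L),
                       ori = "pMB1", resistance = "ampicillin"),
       library = lib)
}

# distinct non-palindromic 4-nt overhangs whose reverse complements are also
# distinct from every other overhang (no cross-talk in the overhang graph)
.gg_overhangs <- c("ACTG", "GGAC", "CTTC", "TCAG", "AAGC", "GATG", "CCAT")

.fx_golden_gate <- function(seed, n_inserts = 3L, insert_core = 220L,
                            backbone_core = 1400L) {
  stopifnot(n_inserts >= 1L, n_inserts + 1L <= length(.gg_overhangs))
  ov <- .gg_overhangs[seq_len(n_inserts + 1L)]   # o_0 .. o_n
  lib <- fixture_library()
  site <- "GGTCTC"
  rcsite <- revcomp(site)
  inserts <- list()
  cores <- character(n_inserts)
  for (i in seq_len(n_inserts)) {
    core <- with_seed(seed + 10L + i, random_dna(insert_core))
    core <- scrub_patterns(core, c(site, ov))
    cores[i] <- core
    iseq <- paste0(site, "A", ov[i], core, ov[i + 1L], "T", rcsite)
    inserts[[i]] <- dna_molecule(iseq, "linear",
                                 left_end = dna_end(phos = TRUE),
                                 right_end = dna_end(phos = TRUE),
                                 id = paste0("gg_insert", i))
  }
  kc0 <- with_seed(seed + 30L, random_dna(backbone_core))
  ori <- lib$entries$pMB1_ori$seq
  ampr <- lib$entries$ampR$seq
  k_core <- paste0(substr(kc0, 1L, 200L), ori,
                   substr(kc0, 201L, 400L), ampr,
                   substr(kc0, 401L, nchar(kc0)))
  k_core <- scrub_patterns(k_core, c(site, ov),
                           protect = list(c(200L, 200L + nchar(ori)),
                                          c(400L + nchar(ori),
                                            400L + nchar(ori) + nchar(ampr))))
  dropout <- with_seed(seed + 31L, random_dna(300L))
  dropout <- scrub_patterns(dropout, c(site, ov))
  bb_seq <- paste0(site, "A", ov[n_inserts + 1L], k_core, ov[1], "T", rcsite,
                   dropout)
  backbone <- annotate_features(
    dna_molecule(bb_seq, "circular", id = "gg_backbone"), lib)
  product_len <- sum(nchar(cores)) + 4L * n_inserts +
    nchar(k_core) + 4L
  list(molecules = c(list(backbone), inserts),
       manifest = list(overhangs = ov, insert_cores = cores,
                       backbone_core = k_core, product_len = product_len,
                       n_fragments = n_inserts + 1L),
       library = lib)
}

# loxP: 13-bp arm + 8-bp asymmetric spacer (the shared core) + 13-bp arm
LOXP_SEQ <- "ATAACTTCGTATAATGTATGCTATACGAAGTTAT"
LOXP_CORE <- c(13L, 21L)

.fx_lox <- function(seed, orientation = c("direct", "inverted"),
                    gap = 1000L, rest = 1500L) {
  orientation <- match.arg(orientation)
  site2 <- if (orientation == "direct") LOXP_SEQ else revcomp(LOXP_SEQ)
  mid <- scrub_patterns(with_seed(seed + 40L, random_dna(gap)), LOXP_SEQ)
  tail <- scrub_patterns(with_seed(seed + 41L, random_dna(rest)), LOXP_SEQ)
  seqs <- paste0(LOXP_SEQ, mid, site2, tail)
  mol <- dna_molecule(seqs, "circular", id = paste0("lox_", orientation))
  ex1 <- nchar(LOXP_SEQ) + gap      # site1 core_end .. site2 core_end
  list(molecules = list(mol),
       manifest = list(length = nchar(seqs), orientation = orientation,
                       site_starts = c(0L, nchar(LOXP_SEQ) + gap),
                       excision_lengths = c(ex1, nchar(seqs) - ex1)))
}

.fx_att_pair <- function(seed, len_a = 1200L, len_b = 900L) {
  sites <- read_site_table()
  attB <- sites$phiC31_attB$sequence
  attP <- sites$phiC31_attP$sequence
  rest_a <- scrub_patterns(with_seed(seed + 50L, random_dna(len_a - nchar(attB))),
                           c(attB, attP))
  rest_b <- scrub_patterns(with_seed(seed + 51L, random_dna(len_b - nchar(attP))),
                           c(attB, attP))
  molA <- dna_molecule(paste0(attB, rest_a), "circular", id = "attB_plasmid")
  molB <- dna_molecule(paste0(attP, rest_b), "circular", id = "attP_plasmid")
  list(molecules = list(molA, molB),
       manifest = list(cointegrate_len = len_a + len_b,
                       lengths = c(len_a, len_b)))
}

.fx_genomic_locus <- function(seed, context = 700L, target_len = 600L) {
  left <- with_seed(seed + 60L, random_dna(context))
  target <- .fx_cds(target_len %/% 3L, seed = seed + 61L)
  right <- with_seed(seed + 62L, random_dna(context))
  # the replaced interval is guarded by bases that differ from any CDS start
  # (ATG...) / end (...TAA), so a cassette's homology arms match the genome
  # over exactly their designed length and no further
  seqs <- paste0(left, "CC", target, "GG", right)
  t0 <- context
  t1 <- context + nchar(target) + 4L
  mol <- dna_molecule(seqs, "genomic_fragment",
                      features = list(feature("target_gene", "CDS", t0 + 2L,
                                              t1 - 2L)),
                      id = "genomic_locus")
  list(molecules = list(mol),
       manifest = list(length = nchar(seqs), target = c(t0, t1),
                       context = context))
}

#' Build a lambda Red knockout cassette against a genomic locus fixture
#'
#' The cassette is `[5' spacer] + left arm + payload + right arm +
#' [3' spacer]`, where the arms copy the `arm_len` bases flanking the
#' locus fixture's target interval and the optional spacers (random,
#' non-homologous) displace the arms from the cassette termini so the arm's
#' distal edge lies at `arm_len + spacer` from the terminus.
#'
#' @param locus the `genomic_locus` fixture (as returned by
#'   [generate_fixture()]).
#' @param arm_len homology arm length, bp.
#' @param payload payload sequence (default: the bundled kanR cassette).
#' @param spacer_len length of the terminal spacers, bp (0 = arms flush).
#' @param seed seed for the spacer sequence.
#' @return a linear [dna_molecule()] cassette.
#' @export
lambda_cassette <- function(locus, arm_len, payload = NULL, spacer_len = 0L,
                            seed = 7L) {
  mol <- locus$molecules[[1]]
  t0 <- locus$manifest$target[1]
  t1 <- locus$manifest$target[2]
  stopifnot(arm_len <= t0, t1 + arm_len <= nchar(mol$seq))
  if (is.null(payload)) payload <- fixture_library()$entries$kanR$seq
  left_arm <- substr0(mol$seq, t0 - arm_len, t0)
  right_arm <- substr0(mol$seq, t1, t1 + arm_len)
  sp1 <- if (spacer_len > 0L) {
    scrub_patterns(with_seed(seed, random_dna(spacer_len)),
                   c(left_arm, right_arm))
  } else ""
  sp2 <- if (spacer_len > 0L) {
    scrub_patterns(with_seed(seed + 1L, random_dna(spacer_len)),
                   c(left_arm, right_arm))
  } else ""
  dna_molecule(paste0(sp1, left_arm, payload, right_arm, sp2), "linear",
               features = list(feature("kanR", "resistance",
                                       nchar(sp1) + arm_len,
                                       nchar(sp1) + arm_len + nchar(payload),
                                       qualifiers = list(antibiotic = "kanamycin"))),
               id = sprintf("cassette_arm%d_sp%d", arm_len, spacer_len))
}

.fx_gibson <- function(seed, n_frags = 3L, core_len = 500L, overlap = 25L) {
  stopifnot(n_frags >= 2L)
  cores <- lapply(seq_len(n_frags), function(i) {
    with_seed(seed + 70L + i, random_dna(core_len))
  })
  if (overlap > 0L) {
    # fragment i = core_i + prefix(core_{i+1}, overlap): terminal overlaps
    frags <- lapply(seq_len(n_frags), function(i) {
      nxt <- cores[[if (i == n_frags) 1L else i + 1L]]
      dna_molecule(paste0(cores[[i]], substr(nxt, 1L, overlap)), "linear",
                   id = paste0("gib_frag", i))
    })
    product_len <- n_frags * core_len
    primers <- NULL
  } else {
    frags <- lapply(seq_len(n_frags), function(i) {
      dna_molecule(cores[[i]], "linear", id = paste0("gib_frag", i))
    })
    product_len <- n_frags * core_len
    primers <- lapply(seq_len(n_frags), function(i) {
      list(fwd = pcr_primer(paste0("f", i), substr(cores[[i]], 1L, 20L)),
           rev = pcr_primer(paste0("r", i),
                            revcomp(substr(cores[[i]], core_len - 19L,
                                           core_len))))
    })
  }
  list(molecules = frags,
       manifest = list(product_len = product_len, overlap = overlap,
                       n_frags = n_frags),
       primers = primers)
}

.fx_read_pair <- function(seed, template_len = 800L) {
  tmpl <- with_seed(seed + 80L, random_dna(template_len))
  exact <- substr0(tmpl, 100L, 600L)
  sub_read <- exact
  ch <- substr(sub_read, 251L, 251L)                 # offset 250 in the read
  substr(sub_read, 251L, 251L) <- c(A = "C", C = "G", G = "T", T = "A")[[ch]]
  ins_read <- paste0(substr0(exact, 0L, 200L), "GGG",
                     substr0(exact, 200L, nchar(exact)))
  list(molecules = list(dna_molecule(tmpl, "linear", id = "ref_template")),
       reads = c(exact = exact, substituted = sub_read, inserted = ins_read),
       manifest = list(exact_span = c(100L, 600L), sub_template_pos = 350L,
                       ins_template_junction = 300L, ins_len = 3L))
}
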