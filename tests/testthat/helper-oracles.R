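# Independent oracles used across the suite. These deliberately avoid the
# package's own search/matching code paths: brute-force window comparison,
# exhaustive chain enumeration, and direct splice construction.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# brute-force IUPAC pattern scan (subject base set must be contained in the
# pattern symbol's set), linear subject, 0-based starts
oracle_scan <- function(subject, pattern) {
  ss <- strsplit(subject, "")[[1]]
  pp <- strsplit(pattern, "")[[1]]
  n <- length(ss); m <- length(pp)
  if (m > n) return(integer(0))
  hits <- integer(0)
  for (i in 0:(n - m)) {
    ok <- TRUE
    for (j in seq_len(m)) {
      if (!all(IUPAC_SETS[[ss[i + j]]] %in% IUPAC_SETS[[pp[j]]])) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

rc_str <- function(x) clonesim::revcomp(x)

# random typed end for the joining oracle; overhangs drawn from a small
# palette so compatible pairs are common
random_end <- function() {
  kind <- sample(c("blunt", "5ov", "3ov"), 1, prob = c(0.3, 0.4, 0.3))
  phos <- runif(1) < 0.7
  if (kind == "blunt") return(dna_end("blunt", phos = phos))
  ovs <- c("ACTG", "AT", "GGCC", "TTAA", "CAGT", "CG")
  dna_end(kind, sample(ovs, 1), phos = phos)
}

random_fragment <- function(len = NULL) {
  if (is.null(len)) len <- sample(20:60, 1)
  dna_molecule(random_dna(len), left_end = random_end(),
               right_end = random_end())
}

# oracle join predicate, written out from the stated rules
oracle_can_join <- function(r, l) {
  if (r$hairpin || l$hairpin) return(FALSE)
  if (!(r$phos || l$phos)) return(FALSE)
  if (r$overhang != l$overhang) return(FALSE)
  if (r$overhang == "blunt") return(TRUE)
  r$seq == rc_str(l$seq)
}

# exhaustive enumeration of all ligation products of `frags` (one copy
# each): every ordered arrangement of every subset, both orientations,
# junction-checked pairwise; linear chains of >= 2 fragments plus every
# closable circle (single fragments included). Returns canonical hashes.
oracle_ligation_products <- function(frags) {
  k <- length(frags)
  out <- character(0)
  orient <- function(i, o) if (o == 1) frags[[i]] else reverse_complement(frags[[i]])
  emit <- function(mol) out <<- c(out, canonical_hash(mol))
  recurse <- function(chain, used) {
    if (length(used) >= 2L) emit(chain)
    if (oracle_can_join(chain$right_end, chain$left_end)) {
      emit(dna_molecule(chain$seq, "circular", features = chain$features))
    }
    for (i in setdiff(seq_len(k), used)) {
      for (o in 1:2) {
        cand <- orient(i, o)
        if (oracle_can_join(chain$right_end, cand$left_end)) {
          joined <- dna_molecule(paste0(chain$seq, cand$seq), "linear",
                                 left_end = chain$left_end,
                                 right_end = cand$right_end)
          recurse(joined, c(used, i))
        }
      }
    }
  }
  for (i in seq_len(k)) {
    for (o in 1:2) recurse(orient(i, o), i)
  }
  sort(unique(out))
}

hashes_of <- function(mols) sort(unique(vapply(mols, canonical_hash, character(1))))

# two linear fragments sharing one interior homology block, with mismatch
# guard bases so the maximal match is exactly the designed block
guarded_homology_pair <- function(block_len = 25L, pad = 60L) {
  block <- random_dna(block_len)
  a <- dna_molecule(paste0(random_dna(pad), "C", block, "G", random_dna(pad)))
  b <- dna_molecule(paste0(random_dna(pad), "T", block, "A", random_dna(pad)))
  list(a = a, b = b, block = block,
       xa = pad + 1L, xb = pad + 1L)
}
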