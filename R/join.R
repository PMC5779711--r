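# Joining machinery: end modification, the ligation rules, and the bounded
# search that both ligation and (virtual) recombination run on.
#
# Two ends join iff (1) at least one of the two carries a 5' phosphate and
# (2) both are blunt, or both overhangs have the same polarity (5' or 3')
# and reverse-complementary sequences. Hairpin ends never ligate. Virtual
# (recombination-intermediate) ends join only with each other, by marker
# complementarity, and the phosphate rule is waived for them.

# complement of a virtual marker: DNA markers (homology blocks, shared
# cores) complement by reverse-complement; tag markers of irreversible
# site pairs toggle a ">"/"<" suffix
marker_comp <- function(m) {
  if (grepl("^[ACGTRYSWKMBDHVN]+$", m)) return(revcomp(m))
  last <- substr(m, nchar(m), nchar(m))
  head <- substr(m, 1L, nchar(m) - 1L)
  if (last == ">") paste0(head, "<")
  else if (last == "<") paste0(head, ">")
  else m
}

# can `right_end` of an upstream molecule join `left_end` of a downstream
# one? `virtual` selects the recombination rules.
ends_can_join <- function(right_end, left_end, virtual = FALSE) {
  if (is.null(right_end) || is.null(left_end)) return(FALSE)
  if (right_end$hairpin || left_end$hairpin) return(FALSE)
  vr <- right_end$overhang == "virtual"
  vl <- left_end$overhang == "virtual"
  if (virtual) {
    if (!vr || !vl) return(FALSE)
    return(right_end$marker == marker_comp(left_end$marker))
  }
  if (vr || vl) return(FALSE)
  if (!(right_end$phos || left_end$phos)) return(FALSE)
  if (right_end$overhang != left_end$overhang) return(FALSE)
  if (right_end$overhang == "blunt") return(TRUE)
  # degenerate bases in an overhang never match: no fabricated base pairing
  if (!is_concrete_dna(right_end$seq) || !is_concrete_dna(left_end$seq)) {
    return(FALSE)
  }
  right_end$seq == revcomp(left_end$seq)
}

# concatenate two linear molecules across a validated junction; anything
# joined into a genomic fragment stays genomic
join_linear <- function(a, b) {
  feats <- c(a$features, shift_features(b$features, nchar(a$seq)))
  topo <- if (a$topology == "genomic_fragment" ||
              b$topology == "genomic_fragment") "genomic_fragment" else "linear"
  dna_molecule(paste0(a$seq, b$seq), topo,
               left_end = a$left_end, right_end = b$right_end,
               features = feats, note = "ligation product")
}

# close a linear molecule into a circle (junction already validated)
close_circle <- function(a) {
  dna_molecule(a$seq, "circular", features = a$features,
               note = "circularization product")
}

#' Joining-mode descriptor for ligation and recombination
#'
#' @param mode `"normal"` (breadth-limited search over `rounds` joining
#'   rounds, each fragment used at most its copy limit per product) or
#'   `"exhaustive"` (only products consuming exactly the specified copy count
#'   of every fragment).
#' @param rounds number of joining rounds (normal mode).
#' @param copies per-fragment copy counts (recycled; default 1 each).
#' @return an object of class `join_mode`.
#' @export
join_mode <- function(mode = c("normal", "exhaustive"), rounds = 3L,
                      copies = 1L) {
  mode <- match.arg(mode)
  stopifnot(rounds >= 1L, all(copies >= 1L))
  structure(list(mode = mode, rounds = as.integer(rounds),
                 copies = as.integer(copies)),
            class = "join_mode")
}

# --- the shared search core -------------------------------------------------
#
# `items` are linear molecules; `groups[i]` maps item i to the input molecule
# it descends from (identity for plain ligation). Copy accounting is per
# group: in normal mode a product may use the items of group g at most
# `copies[g]` times in total; in exhaustive mode the per-group totals must
# equal `copies[g]` exactly.

MAX_POOL <- 2000L

join_search <- function(items, mode, virtual = FALSE, groups = NULL) {
  k <- length(items)
  if (k == 0L) return(list())
  if (is.null(groups)) groups <- seq_len(k)
  ngroup <- max(groups)
  copies <- rep_len(mode$copies, ngroup)
  if (mode$mode == "normal") {
    .join_normal(items, groups, copies, mode$rounds, virtual)
  } else {
    .join_exhaustive(items, groups, copies, virtual)
  }
}

.join_normal <- function(items, groups, copies, rounds, virtual) {
  # copy limits are per item: each piece may enter a product at most as many
  # times as its parent fragment's copy count
  k <- length(items)
  limits <- copies[groups]
  comp0 <- function(i) {
    v <- integer(k)
    v[i] <- 1L
    v
  }
  pool <- lapply(seq_len(k), function(i) {
    list(mol = items[[i]], comp = comp0(i), input = TRUE)
  })
  seen <- new.env(parent = emptyenv())
  for (e in pool) assign(canonical_hash(e$mol), TRUE, envir = seen)
  products <- list()
  add <- function(mol, comp) {
    h <- canonical_hash(mol)
    if (!is.null(seen[[h]])) return(NULL)
    assign(h, TRUE, envir = seen)
    entry <- list(mol = mol, comp = comp, input = FALSE)
    products[[h]] <<- mol
    entry
  }
  for (round in seq_len(rounds)) {
    fresh <- list()
    np <- length(pool)
    for (i in seq_len(np)) {
      a <- pool[[i]]
      if (a$mol$topology == "circular") next
      # self-circularization (inputs included)
      if (ends_can_join(a$mol$right_end, a$mol$left_end, virtual)) {
        e <- add(close_circle(a$mol), a$comp)
        if (!is.null(e)) fresh <- c(fresh, list(e))
      }
      for (j in seq_len(np)) {
        b <- pool[[j]]
        if (b$mol$topology == "circular") next
        comp <- a$comp + b$comp
        if (any(comp > limits)) next
        # both orientations of both operands: a chain may only be buildable
        # with its first element flipped
        for (am in list(a$mol, reverse_complement(a$mol))) {
          for (bm in list(b$mol, reverse_complement(b$mol))) {
            if (ends_can_join(am$right_end, bm$left_end, virtual)) {
              e <- add(join_linear(am, bm), comp)
              if (!is.null(e)) fresh <- c(fresh, list(e))
            }
          }
        }
      }
    }
    if (length(fresh) == 0L) break
    pool <- c(pool, fresh)
    if (length(pool) > MAX_POOL) break
  }
  # final circularization sweep so round-limited chains can still close
  for (e in pool) {
    if (!e$input && e$mol$topology == "linear" &&
        ends_can_join(e$mol$right_end, e$mol$left_end, virtual)) {
      add(close_circle(e$mol), e$comp)
    }
  }
  unname(products)
}

.join_exhaustive <- function(items, groups, copies, virtual) {
  ngroup <- length(copies)
  target <- copies
  seen <- new.env(parent = emptyenv())
  products <- list()
  steps <- 0L
  record <- function(mol) {
    h <- canonical_hash(mol)
    if (is.null(seen[[h]])) {
      assign(h, TRUE, envir = seen)
      products[[h]] <<- mol
    }
  }
  k <- length(items)
  # pre-computed orientations
  flips <- lapply(items, reverse_complement)
  # only groups actually present in the item set are required
  active <- sort(unique(groups))
  done <- function(gcount) all(gcount[active] == target[active])
  extend <- function(chain, gcount, njoin) {
    steps <<- steps + 1L
    if (steps > 200000L) stop("exhaustive assembly too large", call. = FALSE)
    if (done(gcount)) {
      if (ends_can_join(chain$right_end, chain$left_end, virtual)) {
        record(close_circle(chain))
      }
      if (njoin >= 1L) record(chain)
      return(invisible(NULL))
    }
    for (i in seq_len(k)) {
      g <- groups[i]
      if (gcount[g] + 1L > target[g]) next
      for (cand in list(items[[i]], flips[[i]])) {
        if (ends_can_join(chain$right_end, cand$left_end, virtual)) {
          g2 <- gcount
          g2[g] <- g2[g] + 1L
          extend(join_linear(chain, cand), g2, njoin + 1L)
        }
      }
    }
    invisible(NULL)
  }
  for (start in seq_len(k)) {
    g <- groups[start]
    for (orient in list(items[[start]], flips[[start]])) {
      gcount <- integer(ngroup)
      gcount[g] <- 1L
      extend(orient, gcount, 0L)
    }
  }
  unname(products)
}

#' Ligation
#'
#' Joins compatible ends among the substrate molecules (see the rules in the
#' package vignette): at least one 5' phosphate per junction, and either two
#' blunt ends or same-polarity reverse-complementary overhangs. Normal mode
#' runs a breadth-limited search for `rounds` joining rounds with per-fragment
#' copy limits and reports every distinct linear and circular product
#' (self-circularization included). Exhaustive mode reports only products
#' that consume exactly the specified copy count of every fragment.
#' Products are deduplicated by [canonical_hash()].
#'
#' @param mols a [dna_molecule()] or list of them (circular substrates are
#'   inert and ignored).
#' @param mode a [join_mode()].
#' @return list of product molecules (possibly empty).
#' @export
ligate <- function(mols, mode = join_mode("normal")) {
  mols <- as_molecule_list(mols)
  stopifnot(inherits(mode, "join_mode"))
  linear <- Filter(function(m) m$topology != "circular", mols)
  join_search(linear, mode, virtual = FALSE)
}

#' End-modification treatments
#'
#' * `CIAP` (calf intestinal alkaline phosphatase): removes all 5'
#'   phosphates.
#' * `PNK` (T4 polynucleotide kinase): adds 5' phosphates.
#' * `Klenow` / `T4_blunt`: blunting by polymerase — 5' overhangs are filled
#'   in (the fill-in becomes duplex; a bottom-strand 5' overhang at the right
#'   terminus extends the top strand), 3' overhangs are removed by the 3'->5'
#'   exonuclease. Phosphorylation state is preserved.
#'
#' @param mols a [dna_molecule()] or list of them.
#' @param treatment one of `"CIAP"`, `"Klenow"`, `"T4_blunt"`, `"PNK"`.
#' @return list of treated molecules.
#' @export
modify_ends <- function(mols, treatment = c("CIAP", "Klenow", "T4_blunt", "PNK")) {
  treatment <- match.arg(treatment)
  mols <- as_molecule_list(mols)
  lapply(mols, function(mol) {
    if (mol$topology == "circular") {
      if (treatment %in% c("Klenow", "T4_blunt")) {
        stop("blunting requires linear substrates", call. = FALSE)
      }
      return(mol)
    }
    if (treatment %in% c("CIAP", "PNK")) {
      ph <- treatment == "PNK"
      for (side in c("left_end", "right_end")) {
        if (!mol[[side]]$hairpin) mol[[side]]$phos <- ph
      }
      return(mol)
    }
    # blunting
    if (mol$left_end$hairpin || mol$right_end$hairpin) {
      stop("hairpin ends cannot be blunted", call. = FALSE)
    }
    le <- mol$left_end
    re <- mol$right_end
    seqs <- mol$seq
    if (re$overhang == "5ov") {      # bottom protrudes: fill in on top
      seqs <- paste0(seqs, revcomp(re$seq))
    } else if (re$overhang == "3ov") { # top protrudes: chewed back
      seqs <- substr(seqs, 1L, nchar(seqs) - nchar(re$seq))
    }
    # left 5' overhang (top protrudes) is filled on the bottom strand and
    # left 3' overhang (bottom protrudes) is chewed: top strand unchanged
    mol$seq <- seqs
    mol$left_end <- dna_end("blunt", phos = le$phos)
    mol$right_end <- dna_end("blunt", phos = re$phos)
    mol
  })
}
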