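# Secondary-structure screening and primer design.
#
# Structures are scored with the same nearest-neighbor table as Tm, at 37 C.
# The search is exhaustive over contiguous paired stems (>= 3 bp; hairpin
# loops >= 3 nt), which is tractable for oligos up to ~60 nt. Loop entropy
# beyond the minimum size is not modelled: the reported dG is the stem's
# duplex formation energy, a deliberate worst-case bound.

#' Minimum-free-energy secondary structures of one or two oligos
#'
#' Reports the minimum-dG hairpin and self-dimer of `p1` and, when `p2` is
#' given, their minimum-dG cross-dimer. Positions are 0-based indices into
#' the first (or only) oligo. Structures with dG above `cutoff` are omitted.
#'
#' @param p1 a [pcr_primer()] or sequence string.
#' @param p2 optional second oligo.
#' @param cutoff reporting threshold in kcal/mol (default 0: only stabilizing
#'   structures are reported).
#' @return list of duplex reports: `list(kind, delta_g, positions)`.
#' @export
analyze_oligos <- function(p1, p2 = NULL, cutoff = 0) {
  s1 <- if (inherits(p1, "pcr_primer")) p1$sequence else normalize_dna(p1, "oligo")
  .check_concrete(s1)
  out <- list()
  hp <- .best_hairpin(s1)
  if (!is.null(hp) && hp$delta_g <= cutoff) {
    out <- c(out, list(c(list(kind = "hairpin"), hp)))
  }
  sd <- .best_dimer(s1, s1)
  if (!is.null(sd) && sd$delta_g <= cutoff) {
    out <- c(out, list(c(list(kind = "self_dimer"), sd)))
  }
  if (!is.null(p2)) {
    s2 <- if (inherits(p2, "pcr_primer")) p2$sequence else normalize_dna(p2, "oligo")
    .check_concrete(s2)
    cd <- .best_dimer(s1, s2)
    if (!is.null(cd) && cd$delta_g <= cutoff) {
      out <- c(out, list(c(list(kind = "cross_dimer"), cd)))
    }
  }
  out
}

# minimum-dG hairpin: 5' arm [a, a+s) pairs 3' arm [b, b+s) antiparallel,
# stem s >= 3, loop b - (a+s) >= 3
.best_hairpin <- function(seq, min_stem = 3L, min_loop = 3L) {
  n <- nchar(seq)
  best <- NULL
  if (n < 2 * min_stem + min_loop) return(NULL)
  for (a in 0:(n - 2 * min_stem - min_loop)) {
    for (s in min_stem:((n - a - min_loop) %/% 2)) {
      arm5 <- substr0(seq, a, a + s)
      for (b in (a + s + min_loop):(n - s)) {
        arm3 <- substr0(seq, b, b + s)
        if (arm3 == revcomp(arm5)) {
          dg <- duplex_dg37(arm5)
          if (is.null(best) || dg < best$delta_g) {
            best <- list(delta_g = dg,
                         positions = c(a:(a + s - 1L), b:(b + s - 1L)))
          }
        }
      }
    }
  }
  best
}

# minimum-dG ungapped dimer between s1 and s2 (self-dimer when identical):
# in the antiparallel alignment of s1 against revcomp(s2), equal characters
# are paired bases; contiguous runs >= 3 form stems
.best_dimer <- function(s1, s2, min_stem = 3L) {
  w <- revcomp(s2)
  n1 <- nchar(s1); n2 <- nchar(w)
  a1 <- strsplit(s1, "")[[1]]
  a2 <- strsplit(w, "")[[1]]
  best <- NULL
  for (shift in -(n2 - 1L):(n1 - 1L)) {
    i1 <- max(1L, 1L + shift):min(n1, n2 + shift)
    if (length(i1) < min_stem) next
    eq <- a1[i1] == a2[i1 - shift]
    runs <- rle(eq)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values & runs$lengths >= min_stem)) {
      idx <- i1[starts[r]:ends[r]]
      stem <- paste(a1[idx], collapse = "")
      dg <- duplex_dg37(stem)
      if (is.null(best) || dg < best$delta_g) {
        best <- list(delta_g = dg, positions = idx - 1L)
      }
    }
  }
  best
}

# worst (most negative) structure dG of a primer pair, used for ranking
.pair_penalty <- function(f, r) {
  dgs <- vapply(c(analyze_oligos(f), analyze_oligos(r), analyze_oligos(f, r)),
                function(rep) rep$delta_g, numeric(1))
  if (length(dgs) == 0L) 0 else min(dgs)
}

#' Minimal-primer design
#'
#' `one_click` mode returns the primer whose 5' end sits at `position`
#' (0-based) on the given strand, extended 3'-wards base by base until its
#' Tm reaches `tm_min`; the one-base-shorter primer is below the threshold.
#' `pair_search` mode proposes primer pairs flanking `region`, each primer
#' the shortest extension with Tm >= `tm_min`, ranked by worst-case
#' secondary-structure penalty (fewest/weakest hairpins and dimers first);
#' alternative candidates with outward-shifted 5' ends are retained.
#'
#' @param mol template molecule.
#' @param mode `"pair_search"` or `"one_click"`.
#' @param region 0-based half-open interval to amplify (pair_search).
#' @param position,strand 5'-end anchor for one_click.
#' @param tm_min minimum melting temperature, degrees C (sane range 0-80).
#' @param params a [tm_params()] (Wallace rule by default: the classic
#'   minimal-primer heuristic).
#' @param max_len longest primer considered.
#' @param n_candidates alternative pairs to retain (pair_search).
#' @return one_click: a list `list(sequence, tm, position, strand)`.
#'   pair_search: data.frame of ranked candidate pairs.
#' @export
design_primers <- function(mol, mode = c("pair_search", "one_click"),
                           region = NULL, position = NULL, strand = "+",
                           tm_min = 55, params = tm_params("wallace"),
                           max_len = 40L, n_candidates = 5L) {
  stopifnot(inherits(mol, "dna_molecule"))
  mode <- match.arg(mode)
  if (tm_min > 80) stop("tm_min above the sane range (<= 80)", call. = FALSE)
  n <- nchar(mol$seq)
  circ <- mol$topology == "circular"
  top <- if (circ) paste0(mol$seq, mol$seq) else mol$seq

  grow <- function(anchor, strand) {
    # shortest primer with 5' end at `anchor` (0-based, top-strand coords)
    # and Tm >= tm_min
    min_len <- if (params$method == "nearest_neighbor") 6L else 1L
    for (L in min_len:max_len) {
      if (strand == "+") {
        if (!circ && anchor + L > n) return(NULL)
        cand <- substr0(top, anchor, anchor + L)
      } else {
        if (!circ && anchor - L + 1L < 0L) return(NULL)
        start <- if (circ) ((anchor - L + 1L) %% n + n) %% n else anchor - L + 1L
        cand <- revcomp(substr0(top, start, start + L))
      }
      tm <- melting_temperature(cand, params)
      if (tm >= tm_min) {
        return(list(sequence = cand, tm = tm, position = anchor,
                    strand = strand, length = L))
      }
    }
    NULL
  }

  if (mode == "one_click") {
    stopifnot(!is.null(position))
    res <- grow(position, strand)
    if (is.null(res)) {
      stop("no primer at this position reaches tm_min within ", max_len,
           " nt", call. = FALSE)
    }
    return(res)
  }

  stopifnot(!is.null(region), length(region) == 2L)
  a <- region[1]; b <- region[2]
  if (a < 0 || b > n || b <= a) stop("region outside molecule", call. = FALSE)
  pairs <- list()
  for (off_f in 0:n_candidates) {
    anchor_f <- a - off_f
    if (anchor_f < 0 && !circ) next
    f <- grow(if (circ) anchor_f %% n else anchor_f, "+")
    if (is.null(f)) next
    for (off_r in 0:n_candidates) {
      anchor_r <- b - 1L + off_r
      if (anchor_r >= n && !circ) next
      r <- grow(if (circ) anchor_r %% n else anchor_r, "-")
      if (is.null(r)) next
      pairs[[length(pairs) + 1L]] <- data.frame(
        forward = f$sequence, reverse = r$sequence,
        tm_forward = f$tm, tm_reverse = r$tm,
        start = anchor_f, end = anchor_r + 1L,
        penalty = .pair_penalty(f$sequence, r$sequence),
        stringsAsFactors = FALSE)
    }
  }
  if (length(pairs) == 0L) {
    stop("region too AT-rich to reach tm_min within ", max_len, " nt",
         call. = FALSE)
  }
  out <- do.call(rbind, pairs)
  out <- out[order(-out$penalty, nchar(out$forward) + nchar(out$reverse)), ]
  rownames(out) <- NULL
  utils::head(out, n_candidates)
}
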