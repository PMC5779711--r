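# Product selection: gel separation, feature screening, PCR screening, and
# ORF detection.

#' Gel separation
#'
#' Selects molecules whose length lies within `[min_len, max_len]`
#' (inclusive). Fragments shorter than 50 bp run off the gel and are
#' discarded unconditionally, whatever the requested range. Circular
#' molecules are compared by total length.
#'
#' @param mols a [dna_molecule()] or list of them.
#' @param min_len,max_len selection range in bp.
#' @return list of retained molecules.
#' @export
gel_select <- function(mols, min_len = 1L, max_len = Inf) {
  if (min_len > max_len) stop("min_len must be <= max_len", call. = FALSE)
  mols <- as_molecule_list(mols)
  Filter(function(m) {
    len <- nchar(m$seq)
    len >= 50L && len >= min_len && len <= max_len
  }, mols)
}

#' Screening condition
#'
#' @param require_circular optional: keep only circular (`TRUE`) or only
#'   non-circular (`FALSE`) molecules.
#' @param feature_counts list of criteria `list(name =, cmp = "gt"|"lt"|"eq",
#'   count =)` on per-name feature occurrences (any strand).
#' @return an object of class `screen_condition`.
#' @export
screen_condition <- function(require_circular = NULL, feature_counts = list()) {
  if (is.null(require_circular) && length(feature_counts) == 0L) {
    stop("at least one criterion required", call. = FALSE)
  }
  for (fc in feature_counts) {
    stopifnot(!is.null(fc$name), fc$cmp %in% c("gt", "lt", "eq"), fc$count >= 0)
  }
  structure(list(require_circular = require_circular,
                 feature_counts = feature_counts),
            class = "screen_condition")
}

#' Feature screening
#'
#' Keeps the molecules satisfying every criterion of the condition. Feature
#' counts are per-name occurrences regardless of strand; run
#' [annotate_features()] upstream so the features are present. A criterion
#' naming a feature that occurs nowhere in the substrate set yields zero
#' matches with a diagnostic attribute rather than silently.
#'
#' @param mols a [dna_molecule()] or list of them.
#' @param cond a [screen_condition()].
#' @return list of retained molecules (possibly with a `diagnostic`
#'   attribute).
#' @export
feature_screen <- function(mols, cond) {
  stopifnot(inherits(cond, "screen_condition"))
  mols <- as_molecule_list(mols)
  all_names <- unique(unlist(lapply(mols, function(m) {
    vapply(m$features, `[[`, character(1), "name")
  })))
  unknown <- setdiff(vapply(cond$feature_counts, `[[`, character(1), "name"),
                     all_names)
  out <- Filter(function(m) {
    if (!is.null(cond$require_circular) &&
        (m$topology == "circular") != cond$require_circular) return(FALSE)
    fnames <- vapply(m$features, `[[`, character(1), "name")
    for (fc in cond$feature_counts) {
      cnt <- sum(fnames == fc$name)
      ok <- switch(fc$cmp, gt = cnt > fc$count, lt = cnt < fc$count,
                   eq = cnt == fc$count)
      if (!ok) return(FALSE)
    }
    TRUE
  }, mols)
  if (length(unknown) > 0) {
    attr(out, "diagnostic") <- paste0(
      "feature(s) not annotated on any substrate: ",
      paste(unknown, collapse = ", "))
  }
  out
}

#' PCR screening
#'
#' Runs [simulate_pcr()] on each molecule and keeps those producing at least
#' one product whose length falls inside `len_range` (inclusive).
#'
#' @param mols a [dna_molecule()] or list of them.
#' @param primers two primers (see [as_primer_list()] conventions).
#' @param len_range inclusive product length range `c(min, max)`.
#' @param min_anneal_3p see [simulate_pcr()].
#' @return list of retained molecules.
#' @export
pcr_screen <- function(mols, primers, len_range, min_anneal_3p = 15L) {
  mols <- as_molecule_list(mols)
  primers <- as_primer_list(primers)
  if (length(primers) != 2L) stop("PCR screening uses two primers", call. = FALSE)
  Filter(function(m) {
    res <- simulate_pcr(m, primers, min_anneal_3p = min_anneal_3p)
    any(vapply(res$products, function(p) {
      L <- nchar(p$seq)
      L >= len_range[1] && L <= len_range[2]
    }, logical(1)))
  }, mols)
}

#' Open-reading-frame detection
#'
#' Scans all three frames (of both strands when requested) for
#' start-codon-to-in-frame-stop intervals of at least `min_len` bases (stop
#' codon included in the span). On circular molecules ORFs may wrap the
#' origin.
#'
#' @param mol a [dna_molecule()].
#' @param start_codons character vector of 3-mers (default `"ATG"`).
#' @param min_len minimum ORF length in bp, divisible by 3.
#' @param both_strands scan the minus strand too?
#' @return list of `ORF` features.
#' @export
detect_orfs <- function(mol, start_codons = "ATG", min_len = 90L,
                        both_strands = TRUE) {
  stopifnot(inherits(mol, "dna_molecule"))
  stopifnot(all(nchar(start_codons) == 3L), min_len >= 3L, min_len %% 3L == 0L)
  n <- nchar(mol$seq)
  circ <- mol$topology == "circular"
  stops <- c("TAA", "TAG", "TGA")
  scan_strand <- function(seq_top, strand) {
    subject <- if (circ) paste0(seq_top, seq_top) else seq_top
    limit <- nchar(subject)
    feats <- list()
    starts <- integer(0)
    for (sc in start_codons) starts <- c(starts, .exact_starts(subject, sc))
    starts <- sort(unique(starts))
    starts <- starts[starts < n]
    for (s in starts) {
      p <- s
      repeat {
        p <- p + 3L
        if (p + 3L > limit) break
        codon <- substr0(subject, p, p + 3L)
        if (codon %in% stops) {
          len <- p + 3L - s
          if (len >= min_len && len <= n) {
            if (strand == "+") {
              feats <- c(feats, list(feature("ORF", "ORF", s, s + len,
                                             strand = "+")))
            } else {
              # map back to top-strand coordinates
              st <- n - (s + len)
              if (circ) st <- ((st %% n) + n) %% n else st <- max(st, 0L)
              feats <- c(feats, list(feature("ORF", "ORF", st, st + len,
                                             strand = "-")))
            }
          }
          break
        }
      }
    }
    feats
  }
  out <- scan_strand(mol$seq, "+")
  if (both_strands) out <- c(out, scan_strand(revcomp(mol$seq), "-"))
  out
}
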