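# Cutting machinery. A "cut" is a pair of 0-based gap positions (top,
# bottom) on the substrate plus the end objects it creates on the two sides.
# Restriction digestion, CRISPR digestion and the virtual digestion used by
# recombination all funnel through apply_cuts().

# Build the two dna_end objects created by a real (restriction) cut.
# `ov_seq` is the top-strand sequence over [min(t,b), max(t,b)).
cut_ends <- function(t, b, ov_seq) {
  if (t < b) {
    list(left = dna_end("5ov", revcomp(ov_seq), phos = TRUE),
         right = dna_end("5ov", ov_seq, phos = TRUE))
  } else if (t > b) {
    list(left = dna_end("3ov", ov_seq, phos = TRUE),
         right = dna_end("3ov", revcomp(ov_seq), phos = TRUE))
  } else {
    list(left = dna_end("blunt", phos = TRUE),
         right = dna_end("blunt", phos = TRUE))
  }
}

# make a cut record; left_end/right_end are the ends of the LEFT piece's
# right terminus and the RIGHT piece's left terminus respectively
make_cut <- function(t, b, left_end, right_end, label = "") {
  list(t = as.integer(t), b = as.integer(b),
       left_end = left_end, right_end = right_end, label = label)
}

# top-strand substring over a possibly-wrapping 0-based interval
wrap_substr <- function(seq, start, end, circular = FALSE) {
  n <- nchar(seq)
  if (!circular || end <= n) return(substr0(seq, start, end))
  paste0(substr0(seq, start, n), substr0(seq, 0L, end - n))
}

.cut_conflicts <- function(a, b) {
  lo1 <- min(a$t, a$b); hi1 <- max(a$t, a$b)
  lo2 <- min(b$t, b$b); hi2 <- max(b$t, b$b)
  if (max(lo1, lo2) < min(hi1, hi2)) return(TRUE)
  if (lo1 == hi1 && lo2 < lo1 && lo1 < hi2) return(TRUE)  # blunt inside overhang
  if (lo2 == hi2 && lo1 < lo2 && lo2 < hi1) return(TRUE)
  FALSE
}

# Drop cuts that fall inside another cut's overhang region (geometrically
# impossible once the first cut is made); exact duplicates are merged
# silently. Returns list(cuts=, warnings=).
resolve_cut_conflicts <- function(cuts) {
  if (length(cuts) <= 1L) return(list(cuts = cuts, warnings = character(0)))
  key <- vapply(cuts, function(cu) paste(cu$t, cu$b), character(1))
  cuts <- cuts[!duplicated(key)]
  ord <- order(vapply(cuts, function(cu) min(cu$t, cu$b), integer(1)),
               vapply(cuts, function(cu) max(cu$t, cu$b), integer(1)))
  cuts <- cuts[ord]
  kept <- list()
  warnings <- character(0)
  for (cu in cuts) {
    clash <- FALSE
    for (kc in kept) {
      if (.cut_conflicts(kc, cu)) {
        warnings <- c(warnings, sprintf(
          "overlapping cut sites: %s (gap %d/%d) conflicts with %s (gap %d/%d); second cut dropped",
          kc$label, kc$t, kc$b, cu$label, cu$t, cu$b))
        clash <- TRUE
        break
      }
    }
    if (!clash) kept <- c(kept, list(cu))
  }
  list(cuts = kept, warnings = warnings)
}

# Apply a set of simultaneous cuts to one molecule. Circular substrates with
# k cuts yield k linear fragments; linear ones yield k+1. Features split at
# cut points are truncated and tagged.
apply_cuts <- function(mol, cuts) {
  n <- nchar(mol$seq)
  if (length(cuts) == 0L) return(list(mol))
  circular <- mol$topology == "circular"
  if (circular) {
    cuts <- lapply(cuts, function(cu) {
      shift <- (cu$t %% n) - cu$t
      cu$t <- cu$t + shift
      cu$b <- cu$b + shift
      cu
    })
  }
  cuts <- cuts[order(vapply(cuts, `[[`, integer(1), "t"),
                     vapply(cuts, `[[`, integer(1), "b"))]
  tops <- vapply(cuts, `[[`, integer(1), "t")
  frags <- list()
  emit <- function(lo, hi, left_end, right_end) {
    w <- hi - lo
    if (w <= 0L) return()
    seqf <- wrap_substr(mol$seq, lo, hi, circular)
    feats <- .features_in_window(mol, lo, hi, circular)
    topo <- if (mol$topology == "genomic_fragment") "genomic_fragment" else "linear"
    frags[[length(frags) + 1L]] <<- dna_molecule(
      seqf, topo, left_end = left_end, right_end = right_end,
      features = feats, note = paste0("fragment of ", mol$id))
  }
  k <- length(cuts)
  if (circular) {
    if (k == 1L) {
      cu <- cuts[[1]]
      emit(cu$t, cu$t + n, cu$right_end, cu$left_end)
    } else {
      for (j in seq_len(k)) {
        cu <- cuts[[j]]
        nxt <- cuts[[if (j == k) 1L else j + 1L]]
        hi <- if (j == k) nxt$t + n else nxt$t
        emit(cu$t, hi, cu$right_end, nxt$left_end)
      }
    }
  } else {
    bounds <- c(0L, tops, n)
    for (j in seq_len(k + 1L)) {
      left_end <- if (j == 1L) mol$left_end else cuts[[j - 1L]]$right_end
      right_end <- if (j == k + 1L) mol$right_end else cuts[[j]]$left_end
      emit(bounds[j], bounds[j + 1L], left_end, right_end)
    }
  }
  frags
}

# features overlapping window [lo, hi) (possibly wrapping on circles),
# truncated and rebased to the window
.features_in_window <- function(mol, lo, hi, circular) {
  n <- nchar(mol$seq)
  w <- hi - lo
  out <- list()
  for (f in mol$features) {
    len <- f$end - f$start
    offs <- if (circular) {
      fs <- ((f$start - lo) %% n + n) %% n
      unique(c(fs, fs - n))
    } else {
      f$start - lo
    }
    for (off in offs) {
      s <- max(off, 0L)
      e <- min(off + len, w)
      if (e <= s) next
      quals <- f$qualifiers
      if (e - s != len) quals$truncated <- "true"
      out <- c(out, list(feature(f$name, f$kind, s, e, strand = f$strand,
                                 qualifiers = quals)))
    }
  }
  out
}

# cut records for one enzyme on one molecule
.enzyme_cuts <- function(mol, enz) {
  n <- nchar(mol$seq)
  r <- nchar(enz$recognition)
  hits <- find_pattern(mol, enz$recognition, both_strands = TRUE)
  if (revcomp(enz$recognition) == enz$recognition) {
    hits <- hits[hits$strand == "+", , drop = FALSE]  # palindromes: one locus
  }
  circular <- mol$topology == "circular"
  cuts <- list()
  for (i in seq_len(nrow(hits))) {
    p <- hits$pos[i]
    if (hits$strand[i] == "+") {
      t <- p + enz$cut_top
      b <- p + enz$cut_bottom
    } else {
      t <- p + r - enz$cut_bottom
      b <- p + r - enz$cut_top
    }
    if (!circular && (min(t, b) < 0L || max(t, b) > n)) next  # off the end
    if (min(t, b) == max(t, b) && !circular && (t <= 0L || t >= n)) next
    lo <- min(t, b)
    ov <- wrap_substr(mol$seq, lo, lo + abs(t - b), circular)
    ends <- cut_ends(t, b, ov)
    cuts <- c(cuts, list(make_cut(t, b, ends$left, ends$right, enz$name)))
  }
  cuts
}

#' Restriction digestion
#'
#' Locates every recognition site of every enzyme on both strands and applies
#' all cuts simultaneously (complete digestion). Each fragment carries typed
#' ends derived from the cut geometry, with fresh 5' phosphates on both sides
#' of every cut. A circular substrate with k sites yields k linear fragments
#' (itself, unchanged, when k = 0); a linear substrate yields k + 1.
#' Overlapping sites of distinct enzymes emit a warning and the geometrically
#' impossible cut is dropped. Features split at cut points are truncated and
#' tagged with a `truncated` qualifier.
#'
#' @param mols a [dna_molecule()] or list of them.
#' @param enzymes a [restriction_enzyme()], a list of them, or a character
#'   vector of names resolved against `registry`.
#' @param registry named list of enzymes used to resolve names (bundled
#'   default table when `NULL`).
#' @return list with `fragments` (list of molecules) and `warnings`
#'   (character).
#' @export
digest <- function(mols, enzymes, registry = NULL) {
  mols <- as_molecule_list(mols)
  if (is.character(enzymes)) {
    if (is.null(registry)) registry <- read_enzyme_table()
    missing <- setdiff(enzymes, names(registry))
    if (length(missing) > 0) {
      stop("unknown enzyme(s): ", paste(missing, collapse = ", "), call. = FALSE)
    }
    enzymes <- registry[enzymes]
  }
  if (inherits(enzymes, "restriction_enzyme")) enzymes <- list(enzymes)
  if (length(enzymes) == 0L) stop("enzymes must be non-empty", call. = FALSE)
  fragments <- list()
  warnings <- character(0)
  for (mol in mols) {
    cuts <- list()
    for (enz in enzymes) cuts <- c(cuts, .enzyme_cuts(mol, enz))
    res <- resolve_cut_conflicts(cuts)
    warnings <- c(warnings, res$warnings)
    fragments <- c(fragments, apply_cuts(mol, res$cuts))
  }
  list(fragments = fragments, warnings = warnings)
}

as_molecule_list <- function(mols) {
  if (inherits(mols, "dna_molecule")) return(list(mols))
  stopifnot(is.list(mols), all(vapply(mols, inherits, logical(1), "dna_molecule")))
  mols
}

#' CRISPR digestion
#'
#' Each guide is converted into a temporary restriction enzyme whose
#' recognition sequence is protospacer + PAM and whose cut geometry comes
#' from the guide's offsets (SpCas9 default: blunt cut 3 bp 5' of the PAM),
#' then fed to the restriction digestion machinery. A protospacer without an
#' adjacent PAM is never cut.
#'
#' @param mols a [dna_molecule()] or list of them.
#' @param guides a [guide_rna()] or list of them.
#' @return list of fragment molecules.
#' @export
crispr_digest <- function(mols, guides) {
  if (inherits(guides, "guide_rna")) guides <- list(guides)
  if (length(guides) == 0L) stop("guides must be non-empty", call. = FALSE)
  enzymes <- lapply(guides, crispr_enzyme)
  digest(mols, enzymes)$fragments
}

#' Temporary restriction enzyme equivalent of a guide RNA
#' @param guide a [guide_rna()].
#' @return a [restriction_enzyme()].
#' @export
crispr_enzyme <- function(guide) {
  stopifnot(inherits(guide, "guide_rna"))
  ls <- nchar(guide$spacer)
  restriction_enzyme(
    name = paste0("gRNA:", guide$name),
    recognition = paste0(guide$spacer, guide$pam),
    cut_top = ls - guide$cut_offset,
    cut_bottom = ls - guide$cut_offset_bottom
  )
}

#' Count distinct cut loci of one enzyme on one molecule
#' @param mol a [dna_molecule()].
#' @param enz a [restriction_enzyme()].
#' @param region optional 0-based half-open interval `c(start, end)`; only
#'   sites whose recognition start lies inside it are counted (may wrap on
#'   circular molecules when `end > length`).
#' @return integer site count.
#' @export
count_sites <- function(mol, enz, region = NULL) {
  hits <- find_pattern(mol, enz$recognition, both_strands = TRUE)
  if (revcomp(enz$recognition) == enz$recognition) {
    hits <- hits[hits$strand == "+", , drop = FALSE]
  }
  if (!is.null(region)) {
    n <- nchar(mol$seq)
    a <- region[1]; b <- region[2]
    pos <- hits$pos
    inside <- if (b > n && mol$topology == "circular") {
      pos >= a | pos < (b %% n)
    } else {
      pos >= a & pos < b
    }
    hits <- hits[inside, , drop = FALSE]
  }
  nrow(unique(hits[, "pos", drop = FALSE]))
}

#' Enzyme-condition analysis
#'
#' Returns every registry enzyme whose site counts satisfy all the given
#' conditions. A condition compares the site count on a selected subset of
#' the substrate molecules (all of them by default) against a number using
#' `gt`, `lt` or `eq`; for multi-molecule subsets the counts are summed.
#'
#' @param mols a [dna_molecule()] or list of them.
#' @param conditions list of conditions, each
#'   `list(cmp = "eq"|"gt"|"lt", count =, mols = <indices, default all>,
#'   enzymes = <optional name subset>)`.
#' @param registry named list of enzymes (bundled default when `NULL`).
#' @param region optional interval applied to all counts (see
#'   [count_sites()]).
#' @return character vector of enzyme names meeting all conditions.
#' @export
enzyme_analysis <- function(mols, conditions, registry = NULL, region = NULL) {
  mols <- as_molecule_list(mols)
  if (is.null(registry)) registry <- read_enzyme_table()
  if (length(registry) == 0L) stop("enzyme registry is empty", call. = FALSE)
  for (cond in conditions) {
    stopifnot(cond$cmp %in% c("gt", "lt", "eq"), cond$count >= 0)
  }
  ok <- vapply(names(registry), function(nm) {
    enz <- registry[[nm]]
    all(vapply(conditions, function(cond) {
      if (!is.null(cond$enzymes) && !nm %in% cond$enzymes) return(TRUE)
      idx <- if (is.null(cond$mols)) seq_along(mols) else cond$mols
      cnt <- sum(vapply(mols[idx], count_sites, integer(1), enz = enz,
                        region = region))
      switch(cond$cmp, gt = cnt > cond$count, lt = cnt < cond$count,
             eq = cnt == cond$count)
    }, logical(1)))
  }, logical(1))
  names(registry)[ok]
}

#' Optimal-buffer search over a vendor alias system
#'
#' Each queried enzyme name is resolved to its canonical enzyme through the
#' alias table, then the activity of every product of the buffer system's
#' vendor mapping to that canonical enzyme is read from the buffer table
#' (best product per buffer when a vendor sells several versions). Buffers
#' are ranked by descending minimum activity across the queried enzymes,
#' ties broken alphabetically; entries whose minimum falls below `threshold`
#' are flagged.
#'
#' @param enzyme_names canonical or vendor product names.
#' @param system a [read_buffer_table()] result (bundled default when
#'   `NULL`); must be restricted to one vendor.
#' @param threshold activity percentage below which a buffer is flagged.
#' @param aliases alias table (bundled default when `NULL`).
#' @return data.frame ranked by buffer quality with one activity column per
#'   enzyme, `min_activity` and `below_threshold`.
#' @export
find_buffer <- function(enzyme_names, system = NULL, threshold = 75,
                        aliases = NULL) {
  if (is.null(aliases)) aliases <- read_alias_table()
  if (is.null(system)) system <- read_buffer_table(vendor = "Thermofisher")
  tab <- system$table
  vendor <- unique(tab$vendor)
  if (length(vendor) != 1L) stop("buffer system must be one vendor", call. = FALSE)
  canon <- vapply(enzyme_names, function(nm) {
    i <- match(nm, aliases$alias)
    if (!is.na(i)) aliases$canonical[i]
    else if (nm %in% aliases$canonical) nm
    else stop("unknown enzyme name: ", nm, call. = FALSE)
  }, character(1))
  buffers <- sort(unique(tab$buffer))
  act <- matrix(NA_real_, nrow = length(buffers), ncol = length(enzyme_names),
                dimnames = list(buffers, enzyme_names))
  for (j in seq_along(enzyme_names)) {
    vendor_aliases <- aliases$alias[aliases$canonical == canon[j] &
                                      aliases$vendor == vendor]
    if (length(vendor_aliases) == 0L) {
      stop("enzyme ", enzyme_names[j], " has no ", vendor, " product",
           call. = FALSE)
    }
    for (bu in buffers) {
      rows <- tab[tab$buffer == bu & tab$alias %in% vendor_aliases, ]
      if (nrow(rows) > 0) act[bu, j] <- max(rows$activity)
    }
  }
  minact <- apply(act, 1, function(x) if (anyNA(x)) -Inf else min(x))
  ord <- order(-minact, buffers)
  data.frame(buffer = buffers[ord],
             act[ord, , drop = FALSE],
             min_activity = minact[ord],
             below_threshold = minact[ord] < threshold,
             row.names = NULL, check.names = FALSE,
             stringsAsFactors = FALSE)
}
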