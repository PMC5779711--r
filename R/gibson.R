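# Gibson assembly designer: chooses junction overlaps, extends the non-fixed
# primers of PCR-derived fragments with the corresponding linkers, and
# verifies the design by running the in vivo annealing recombination in
# exhaustive mode.

#' Declare an assembly source fragment
#'
#' @param mol the fragment (one molecule per source).
#' @param is_pcr is the fragment the product of a PCR whose primers may be
#'   extended?
#' @param fwd,rev the fragment's primers ([pcr_primer()]; required when
#'   `is_pcr`). A primer with `fixed = TRUE` is never modified.
#' @return an object of class `gibson_source`.
#' @export
gibson_source <- function(mol, is_pcr = FALSE, fwd = NULL, rev = NULL) {
  stopifnot(inherits(mol, "dna_molecule"))
  if (mol$topology == "circular") {
    stop("assembly sources must be linear fragments", call. = FALSE)
  }
  if (is_pcr) {
    stopifnot(inherits(fwd, "pcr_primer"), inherits(rev, "pcr_primer"))
  }
  structure(list(mol = mol, is_pcr = isTRUE(is_pcr), fwd = fwd, rev = rev),
            class = "gibson_source")
}

# longest exact suffix(a)/prefix(b) overlap
.natural_overlap <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  for (L in seq.int(min(na, nb), 1L)) {
    if (substr(a, na - L + 1L, na) == substr(b, 1L, L)) return(L)
  }
  0L
}

# shortest overlap, grown base by base from the junction-proximal neighbour
# sequence, meeting both the length and Tm thresholds
.grow_overlap <- function(donor_terminal, min_overlap, tm_threshold,
                          max_extension) {
  for (L in seq.int(min_overlap, min(nchar(donor_terminal), max_extension))) {
    ov <- substr(donor_terminal, nchar(donor_terminal) - L + 1L,
                 nchar(donor_terminal))
    if (melting_temperature(ov, tm_params("nearest_neighbor")) >= tm_threshold) {
      return(ov)
    }
  }
  NULL
}

#' Gibson assembly design
#'
#' For each junction of the (circular) assembly order, an overlap sequence is
#' chosen from the neighbouring fragment's terminal sequence and prepended as
#' a 5' extension to the non-fixed primer of the adjacent PCR fragment, such
#' that the overlap's melting temperature and length both meet the
#' thresholds. Non-PCR fragments are never altered: their neighbours'
#' primers carry the full linker. Junctions that already share a qualifying
#' terminal overlap are left untouched. The predicted product is computed by
#' running [recombine()] in `in_vivo_annealing` exhaustive mode on the
#' extended fragments and must be a single circle containing every source
#' exactly once.
#'
#' @param sources ordered list of [gibson_source()] objects (assembly
#'   proceeds source 1 -> 2 -> ... -> 1).
#' @param tm_threshold minimum overlap melting temperature, degrees C.
#' @param min_overlap minimum overlap length, bp.
#' @param max_extension longest linker considered, bp.
#' @return list with `sources` (primers extended), `linkers` (one per
#'   junction; `""` where untouched), `fragments` (the extended fragments)
#'   and `product` (the verified circular assembly).
#' @export
design_gibson <- function(sources, tm_threshold = 48, min_overlap = 15L,
                          max_extension = 60L) {
  stopifnot(length(sources) >= 2L,
            all(vapply(sources, inherits, logical(1), "gibson_source")))
  ns <- length(sources)
  # working copies of fragment sequences; extensions accumulate
  ext5 <- character(ns)   # linker prepended at the fragment 5' end
  ext3 <- character(ns)   # linker (revcomp of primer tail) appended at 3'
  ext5[] <- ""; ext3[] <- ""
  linkers <- character(ns)
  tm_ok <- function(ov) {
    nchar(ov) >= min_overlap &&
      melting_temperature(ov, tm_params("nearest_neighbor")) >= tm_threshold
  }
  for (j in seq_len(ns)) {
    up <- sources[[j]]
    dn <- sources[[if (j == ns) 1L else j + 1L]]
    di <- if (j == ns) 1L else j + 1L
    ov_len <- .natural_overlap(up$mol$seq, dn$mol$seq)
    if (ov_len > 0L) {
      ov <- substr(dn$mol$seq, 1L, ov_len)
      if (tm_ok(ov)) {
        linkers[j] <- ""
        next
      }
    }
    dn_mod <- dn$is_pcr && !dn$fwd$fixed
    up_mod <- up$is_pcr && !up$rev$fixed
    if (!dn_mod && !up_mod) {
      stop("junction ", j, ": all primers fixed and no qualifying natural ",
           "overlap", call. = FALSE)
    }
    if (dn_mod) {
      # take the linker from the upstream fragment's terminal sequence
      linker <- .grow_overlap(up$mol$seq, min_overlap, tm_threshold,
                              max_extension)
      if (is.null(linker)) {
        stop("junction ", j, ": thresholds unsatisfiable within ",
             max_extension, " bp", call. = FALSE)
      }
      sources[[di]]$fwd$sequence <- paste0(linker, sources[[di]]$fwd$sequence)
      ext5[di] <- paste0(linker, ext5[di])
      linkers[j] <- linker
    } else {
      # extend the upstream reverse primer with the downstream leading
      # sequence (reverse-complemented on the primer)
      linker <- .grow_overlap(revcomp(dn$mol$seq), min_overlap, tm_threshold,
                              max_extension)
      if (is.null(linker)) {
        stop("junction ", j, ": thresholds unsatisfiable within ",
             max_extension, " bp", call. = FALSE)
      }
      sources[[j]]$rev$sequence <- paste0(linker, sources[[j]]$rev$sequence)
      ext3[j] <- paste0(ext3[j], revcomp(linker))
      linkers[j] <- linker
    }
  }
  fragments <- lapply(seq_len(ns), function(i) {
    s <- sources[[i]]$mol
    newseq <- paste0(ext5[i], s$seq, ext3[i])
    dna_molecule(newseq, "linear",
                 left_end = dna_end("blunt",
                                    phos = if (sources[[i]]$is_pcr)
                                      sources[[i]]$fwd$phosphorylated else
                                        s$left_end$phos),
                 right_end = dna_end("blunt",
                                     phos = if (sources[[i]]$is_pcr)
                                       sources[[i]]$rev$phosphorylated else
                                         s$right_end$phos),
                 features = shift_features(s$features, nchar(ext5[i])),
                 note = paste0("extended ", s$id))
  })
  params <- homology_params("in_vivo_annealing",
                            min_homology_len = max(8L, min_overlap))
  prods <- recombine(fragments, params,
                     mode = join_mode("exhaustive", copies = 1L))
  circles <- Filter(function(m) m$topology == "circular", prods)
  if (length(circles) != 1L) {
    stop("assembly verification failed: expected one circular product, got ",
         length(circles), call. = FALSE)
  }
  list(sources = sources, linkers = linkers, fragments = fragments,
       product = circles[[1]])
}
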