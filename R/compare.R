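# Sequence comparison: align queries (e.g. sequencing reads) to a template
# and present the alignments as features on the template.
#
# Alignment is semi-global (whole query against part of the template) with
# affine gaps via Biostrings::pairwiseAlignment, scores match 2 / mismatch
# -3 / gap open -5 / gap extend -2. Circular templates are searched over a
# doubled sequence and coordinates mapped back.

ALIGN_MATCH <- 2
ALIGN_MISMATCH <- -3
ALIGN_GAP_OPEN <- 5
ALIGN_GAP_EXTEND <- 2

#' Align query sequences onto a template as features
#'
#' Each query is aligned to the template on both strands (the better strand
#' is kept). Maximal exactly-matching runs become `alignment_match`
#' features; substitutions, insertions (extra query bases) and deletions
#' (missing template bases) become `alignment_mismatch`,
#' `alignment_insertion` and `alignment_deletion` features, each carrying
#' the query name in its qualifiers. Multiple queries stack on one
#' template. A query whose score falls below `score_floor` is reported
#' unaligned in the `unaligned` attribute.
#'
#' @param template a [dna_molecule()].
#' @param queries named character vector or list of molecules.
#' @param score_floor minimum alignment score to accept.
#' @return the template with alignment features appended.
#' @export
compare_sequences <- function(template, queries, score_floor = 20) {
  stopifnot(inherits(template, "dna_molecule"))
  if (is.list(queries)) {
    nm <- vapply(queries, function(q) {
      if (inherits(q, "dna_molecule")) q$id else ""
    }, character(1))
    queries <- stats::setNames(vapply(queries, function(q) {
      if (inherits(q, "dna_molecule")) q$seq else as.character(q)
    }, character(1)), nm)
  }
  if (is.null(names(queries)) || any(!nzchar(names(queries)))) {
    names(queries) <- paste0("query", seq_along(queries))
  }
  n <- nchar(template$seq)
  circ <- template$topology == "circular"
  subject_seq <- if (circ) paste0(template$seq, template$seq) else template$seq
  subject <- Biostrings::DNAString(subject_seq)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = ALIGN_MATCH, mismatch = ALIGN_MISMATCH, baseOnly = TRUE)
  unaligned <- character(0)
  feats <- list()
  for (qi in seq_along(queries)) {
    qname <- names(queries)[qi]
    best <- NULL
    best_strand <- "+"
    for (strand in c("+", "-")) {
      qseq <- if (strand == "+") queries[[qi]] else revcomp(queries[[qi]])
      aln <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAString(qseq), subject = subject,
        type = "global-local", substitutionMatrix = mat,
        gapOpening = ALIGN_GAP_OPEN, gapExtension = ALIGN_GAP_EXTEND)
      if (is.null(best) || Biostrings::score(aln) > Biostrings::score(best)) {
        best <- aln
        best_strand <- strand
      }
    }
    if (Biostrings::score(best) < score_floor) {
      unaligned <- c(unaligned, qname)
      next
    }
    feats <- c(feats, .alignment_features(best, best_strand, qname, n, circ))
  }
  template$features <- c(template$features, feats)
  if (length(unaligned) > 0) attr(template, "unaligned") <- unaligned
  template
}

# walk the alignment columns and emit features in template coordinates
.alignment_features <- function(aln, strand, qname, n, circ) {
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  spos <- Biostrings::start(Biostrings::subject(aln)) - 1L  # 0-based
  quals <- list(query = qname)
  wrap <- function(x) if (circ) x %% n else x
  feats <- list()
  run_start <- NA_integer_
  tpos <- spos
  flush_run <- function(end_pos) {
    if (!is.na(run_start) && end_pos > run_start) {
      feats[[length(feats) + 1L]] <<- feature(
        qname, "alignment_match", wrap(run_start),
        wrap(run_start) + (end_pos - run_start), strand = strand,
        qualifiers = quals)
    }
    run_start <<- NA_integer_
  }
  i <- 1L
  while (i <= length(pat)) {
    pc <- pat[i]; sc <- sub[i]
    if (pc != "-" && sc != "-") {
      if (pc == sc) {
        if (is.na(run_start)) run_start <- tpos
      } else {
        flush_run(tpos)
        feats[[length(feats) + 1L]] <- feature(
          qname, "alignment_mismatch", wrap(tpos), wrap(tpos) + 1L,
          strand = strand, qualifiers = quals)
      }
      tpos <- tpos + 1L
    } else if (sc == "-") {
      # extra query bases: insertion at this template junction
      flush_run(tpos)
      j <- i
      while (j <= length(pat) && sub[j] == "-") j <- j + 1L
      ins_len <- j - i
      feats[[length(feats) + 1L]] <- feature(
        qname, "alignment_insertion", wrap(max(tpos - 1L, 0L)),
        wrap(max(tpos - 1L, 0L)) + 1L, strand = strand,
        qualifiers = c(quals, list(length = as.character(ins_len))))
      i <- j - 1L
    } else {
      # template bases missing from the query: deletion
      flush_run(tpos)
      j <- i
      while (j <= length(pat) && pat[j] == "-") j <- j + 1L
      del_len <- j - i
      feats[[length(feats) + 1L]] <- feature(
        qname, "alignment_deletion", wrap(tpos), wrap(tpos) + del_len,
        strand = strand, qualifiers = quals)
      tpos <- tpos + del_len
      i <- j - 1L
    }
    i <- i + 1L
  }
  flush_run(tpos)
  feats
}
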