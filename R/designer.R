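# Code-based sequence design: bracket-token expansion, sequence merging,
# reverse translation and codon-usage computation.

#' Expand designer text into a DNA sequence
#'
#' Replaces name tokens by registry sequences: `[name]` inserts the forward
#' sequence; `[name:pattern>` inserts the forward sequence with its
#' degenerate (N) positions filled, in order, from `pattern`;
#' `<name:pattern]` inserts the reverse complement thereof. Names are looked
#' up in the restriction-enzyme registry (recognition sequence), the
#' recombination-site registry, and the feature library, in that order.
#' Literal IUPAC runs pass through unchanged.
#'
#' @param text designer text.
#' @param enzymes enzyme registry (bundled default when `NULL`).
#' @param sites site registry (bundled default when `NULL`).
#' @param features a [feature_library()] (empty default).
#' @return the expanded DNA string.
#' @export
expand_designer_text <- function(text, enzymes = NULL, sites = NULL,
                                 features = feature_library()) {
  if (is.null(enzymes)) enzymes <- read_enzyme_table()
  if (is.null(sites)) sites <- read_site_table()
  lookup <- function(name) {
    if (name %in% names(enzymes)) return(enzymes[[name]]$recognition)
    if (name %in% names(sites)) return(sites[[name]]$sequence)
    e <- library_lookup(features, name)
    if (!is.null(e)) return(e$seq)
    stop("unknown designer name: ", name, call. = FALSE)
  }
  fill_pattern <- function(seq, pattern) {
    if (!nzchar(pattern)) return(seq)
    pattern <- normalize_dna(pattern, "fill pattern")
    chars <- strsplit(seq, "")[[1]]
    slots <- which(chars == "N")
    if (length(slots) != nchar(pattern)) {
      stop("pattern length ", nchar(pattern), " does not match ",
           length(slots), " N position(s) in the site", call. = FALSE)
    }
    chars[slots] <- strsplit(pattern, "")[[1]]
    paste(chars, collapse = "")
  }
  token_re <- "\\[([^]\\[:<>]+):([A-Za-z]*)>|<([^]\\[:<>]+):([A-Za-z]*)\\]|\\[([^]\\[:<>]+)\\]"
  out <- ""
  rest <- text
  repeat {
    m <- regexpr(token_re, rest, perl = TRUE)
    if (m == -1L) {
      out <- paste0(out, rest)
      break
    }
    out <- paste0(out, substr(rest, 1L, m - 1L))
    tok <- substr(rest, m, m + attr(m, "match.length") - 1L)
    rest <- substr(rest, m + attr(m, "match.length"), nchar(rest))
    if (startsWith(tok, "<")) {
      body <- sub("^<(.+):([A-Za-z]*)\\]$", "\\1\x1f\\2", tok)
      parts <- strsplit(body, "\x1f")[[1]]
      pat <- if (length(parts) > 1L) parts[2] else ""
      out <- paste0(out, revcomp(fill_pattern(lookup(parts[1]), pat)))
    } else if (grepl(">$", tok)) {
      body <- sub("^\\[(.+):([A-Za-z]*)>$", "\\1\x1f\\2", tok)
      parts <- strsplit(body, "\x1f")[[1]]
      pat <- if (length(parts) > 1L) parts[2] else ""
      out <- paste0(out, fill_pattern(lookup(parts[1]), pat))
    } else {
      name <- sub("^\\[(.+)\\]$", "\\1", tok)
      out <- paste0(out, lookup(name))
    }
  }
  normalize_dna(gsub("[ \t\r\n0-9]", "", out), "designer output")
}

#' Merge sequences with overlapping ends
#'
#' Every exact suffix-prefix overlap of at least `min_overlap` bases between
#' any ordered pair of sequences (second sequence in either orientation)
#' yields a merged candidate; all distinct outcomes are returned (useful for
#' joining overlapping sequencing reads).
#'
#' @param seqs character vector (>= 2) or list of molecules.
#' @param min_overlap minimum exact overlap, bp.
#' @return character vector of merged candidates (empty when none overlap).
#' @export
merge_sequences <- function(seqs, min_overlap = 15L) {
  if (is.list(seqs)) seqs <- vapply(seqs, function(m) {
    if (inherits(m, "dna_molecule")) m$seq else as.character(m)
  }, character(1))
  seqs <- vapply(seqs, normalize_dna, character(1), USE.NAMES = FALSE)
  if (length(seqs) < 2L) stop("need at least 2 sequences", call. = FALSE)
  out <- character(0)
  for (i in seq_along(seqs)) {
    for (j in seq_along(seqs)) {
      if (i == j) next
      a <- seqs[i]
      for (b in c(seqs[j], revcomp(seqs[j]))) {
        na <- nchar(a); nb <- nchar(b)
        for (L in seq.int(min(na, nb), min_overlap)) {
          if (substr(a, na - L + 1L, na) == substr(b, 1L, L)) {
            out <- c(out, paste0(a, substr(b, L + 1L, nb)))
          }
        }
      }
    }
  }
  unique(out)
}

# standard genetic code, codon -> one-letter amino acid (stop = "*")
.genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

#' Codon usage from a CDS set
#'
#' Counts codons across the coding sequences and normalizes per amino acid.
#'
#' @param cds_set character vector of coding sequences, each a multiple of
#'   3 nt long. A terminal stop codon is counted under `"*"`; an internal
#'   stop is an error.
#' @return named list: amino acid -> named numeric vector of relative codon
#'   frequencies summing to 1.
#' @export
codon_usage <- function(cds_set) {
  code <- .genetic_code()
  counts <- stats::setNames(numeric(length(code)), names(code))
  for (cds in cds_set) {
    cds <- normalize_dna(cds, "CDS")
    .check_concrete(cds)
    if (nchar(cds) %% 3 != 0) stop("CDS length not divisible by 3", call. = FALSE)
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    aas <- code[codons]
    internal_stop <- which(aas == "*" & seq_along(aas) < length(aas))
    if (length(internal_stop) > 0) {
      stop("internal stop codon at codon ", internal_stop[1], call. = FALSE)
    }
    for (cd in codons) counts[cd] <- counts[cd] + 1
  }
  aas <- code[names(counts)]
  out <- list()
  for (aa in unique(aas)) {
    sub <- counts[aas == aa]
    tot <- sum(sub)
    if (tot > 0) out[[aa]] <- sub / tot
  }
  out
}

#' Reverse translation
#'
#' `one_codon`: every residue is encoded by its single most frequent codon
#' (deterministic; alphabetical tie-break). `guided_random`: each codon is
#' sampled proportionally to its usage, reproducibly under `seed`.
#' Translating the output always recovers the input protein.
#'
#' @param protein amino-acid string (standard one-letter alphabet; `*`
#'   allowed as terminal stop).
#' @param table codon usage map as produced by [codon_usage()].
#' @param algorithm `"one_codon"` or `"guided_random"`.
#' @param seed RNG seed for `guided_random`.
#' @return DNA string.
#' @export
reverse_translate <- function(protein, table,
                              algorithm = c("one_codon", "guided_random"),
                              seed = 1L) {
  algorithm <- match.arg(algorithm)
  protein <- toupper(protein)
  residues <- strsplit(protein, "")[[1]]
  missing <- setdiff(residues, names(table))
  if (length(missing) > 0) {
    stop("residue(s) absent from codon table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pick <- if (algorithm == "one_codon") {
    function(freqs) names(freqs)[order(-freqs, names(freqs))][1]
  } else {
    function(freqs) sample(names(freqs), 1L, prob = freqs)
  }
  if (algorithm == "guided_random") {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  codons <- vapply(residues, function(aa) {
    freqs <- table[[aa]]
    freqs <- freqs[order(names(freqs))]   # stable order for reproducibility
    pick(freqs)
  }, character(1))
  paste(codons, collapse = "")
}
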