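# GenBank flatfile reader/writer. Coordinates convert between the internal
# 0-based half-open convention and GenBank's 1-based inclusive locations;
# `complement(a..b)` maps to a minus-strand feature and an origin-wrapping
# `join(a..b,1..c)` on a circular record maps to a single wrapped feature.
# Topology comes from the LOCUS line ("circular"/"linear"; absent = linear).

#' Read a GenBank flatfile
#'
#' @param path file path.
#' @return list of [dna_molecule()] objects (one per record).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  records <- list()
  rec_start <- which(startsWith(lines, "LOCUS"))
  if (length(rec_start) == 0L) stop("malformed GenBank file: no LOCUS line",
                                    call. = FALSE)
  rec_end <- c(rec_start[-1] - 1L, length(lines))
  for (ri in seq_along(rec_start)) {
    chunk <- lines[rec_start[ri]:rec_end[ri]]
    records[[length(records) + 1L]] <- .parse_gb_record(chunk)
  }
  records
}

.parse_gb_record <- function(lines) {
  locus <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  name <- if (length(locus) >= 2) locus[2] else "unnamed"
  topology <- if (any(tolower(locus) == "circular")) "circular" else "linear"
  ori_at <- grep("^ORIGIN", lines)
  if (length(ori_at) == 0L) stop("malformed GenBank record: no ORIGIN",
                                 call. = FALSE)
  seq_lines <- lines[(ori_at[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seqs <- gsub("[^A-Za-z]", "", paste(seq_lines, collapse = ""))
  if (!nzchar(seqs)) stop("malformed GenBank record: empty ORIGIN",
                          call. = FALSE)
  n <- nchar(seqs)
  feats <- list()
  fstart <- grep("^FEATURES", lines)
  if (length(fstart) == 1L) {
    flines <- lines[(fstart + 1L):(ori_at[1] - 1L)]
    feats <- .parse_gb_features(flines, n, topology == "circular")
  }
  dna_molecule(seqs, topology, features = feats, id = name,
               note = paste0("read from GenBank"))
}

.parse_gb_features <- function(flines, n, circular) {
  # group continuation lines: a new feature starts with a key at column 6
  keys <- grepl("^ {5}\\S", flines)
  idx <- cumsum(keys)
  feats <- list()
  for (g in unique(idx[idx > 0])) {
    block <- flines[idx == g]
    header <- block[1]
    kind <- trimws(substr(header, 1, 20))
    loc <- trimws(substr(header, 21, nchar(header)))
    qlines <- block[-1]
    # location may continue onto lines before the first qualifier
    qstart <- grep("^\\s*/", qlines)
    if (length(qstart) == 0L) {
      loc <- paste0(loc, paste(trimws(qlines), collapse = ""))
      qlines <- character(0)
    } else if (qstart[1] > 1L) {
      loc <- paste0(loc, paste(trimws(qlines[1:(qstart[1] - 1L)]), collapse = ""))
      qlines <- qlines[qstart[1]:length(qlines)]
    }
    parsed <- .parse_gb_location(loc, n, circular)
    if (is.null(parsed)) next
    quals <- .parse_gb_qualifiers(qlines)
    nm <- quals$label %||% quals$gene %||% quals$name %||% kind
    quals$label <- NULL
    feats <- c(feats, list(feature(nm, kind, parsed$start, parsed$end,
                                   strand = parsed$strand,
                                   qualifiers = quals)))
  }
  feats
}

.parse_gb_location <- function(loc, n, circular) {
  strand <- "+"
  loc <- gsub(" ", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    body <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(body, ",")[[1]]
    ivals <- lapply(parts, .parse_gb_span)
    if (any(vapply(ivals, is.null, logical(1)))) return(NULL)
    # origin-wrapping join on a circular record: (a..n, 1..c)
    if (circular && length(ivals) == 2L &&
        ivals[[1]]$end == n && ivals[[2]]$start == 0L) {
      return(list(start = ivals[[1]]$start,
                  end = n + ivals[[2]]$end, strand = strand))
    }
    # otherwise take the envelope
    return(list(start = min(vapply(ivals, `[[`, integer(1), "start")),
                end = max(vapply(ivals, `[[`, integer(1), "end")),
                strand = strand))
  }
  sp <- .parse_gb_span(loc)
  if (is.null(sp)) return(NULL)
  list(start = sp$start, end = sp$end, strand = strand)
}

.parse_gb_span <- function(s) {
  s <- gsub("[<>]", "", s)
  if (grepl("^[0-9]+\\.\\.[0-9]+$", s)) {
    ab <- as.integer(strsplit(s, "\\.\\.")[[1]])
    list(start = ab[1] - 1L, end = ab[2])
  } else if (grepl("^[0-9]+$", s)) {
    a <- as.integer(s)
    list(start = a - 1L, end = a)
  } else {
    NULL
  }
}

.parse_gb_qualifiers <- function(qlines) {
  quals <- list()
  cur_key <- NULL
  cur_val <- NULL
  flush <- function() {
    if (!is.null(cur_key)) {
      v <- gsub("^\"|\"$", "", cur_val)
      quals[[cur_key]] <<- v
    }
  }
  for (l in qlines) {
    l <- trimws(l)
    m <- regmatches(l, regexec("^/([A-Za-z_0-9]+)=?(.*)$", l))[[1]]
    if (length(m) == 3 && startsWith(l, "/")) {
      flush()
      cur_key <- m[2]
      cur_val <- m[3]
    } else if (!is.null(cur_key)) {
      cur_val <- paste0(cur_val, l)
    }
  }
  flush()
  quals
}

#' Write molecules to a GenBank flatfile
#'
#' @param mols a [dna_molecule()] or list of them.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_genbank <- function(mols, path) {
  mols <- as_molecule_list(mols)
  out <- character(0)
  for (mol in mols) {
    n <- nchar(mol$seq)
    topo <- if (mol$topology == "circular") "circular" else "linear"
    out <- c(out, sprintf("LOCUS       %-16s %d bp    DNA     %-8s SYN",
                          substr(mol$id, 1, 16), n, topo))
    out <- c(out, "FEATURES             Location/Qualifiers")
    for (f in mol$features) {
      loc <- .format_gb_location(f, n, mol$topology == "circular")
      out <- c(out, sprintf("     %-16s%s", substr(f$kind, 1, 15), loc))
      out <- c(out, sprintf("                     /label=\"%s\"", f$name))
      for (qn in sort(names(f$qualifiers))) {
        if (qn == "label") next
        out <- c(out, sprintf("                     /%s=\"%s\"", qn,
                              f$qualifiers[[qn]]))
      }
    }
    out <- c(out, "ORIGIN")
    for (i in seq(1L, n, 60L)) {
      blockseq <- substr(mol$seq, i, min(i + 59L, n))
      tens <- substring(blockseq, seq(1, nchar(blockseq), 10),
                        pmin(seq(10, nchar(blockseq) + 9, 10), nchar(blockseq)))
      out <- c(out, sprintf("%9d %s", i, paste(tolower(tens), collapse = " ")))
    }
    out <- c(out, "//")
  }
  writeLines(out, path)
  invisible(path)
}

.format_gb_location <- function(f, n, circular) {
  s <- f$start; e <- f$end
  body <- if (circular && e > n) {
    sprintf("join(%d..%d,%d..%d)", s + 1L, n, 1L, e - n)
  } else {
    sprintf("%d..%d", s + 1L, e)
  }
  if (f$strand == "-") sprintf("complement(%s)", body) else body
}

#' Read FASTA or plain-text sequence files
#'
#' FASTA records become linear, blunt, unphosphorylated molecules. Plain
#' text is cleaned of whitespace and digits (line numbers) and upper-cased.
#'
#' @param path file path.
#' @param format `"auto"` (by extension / leading `>`), `"fasta"`,
#'   `"genbank"` or `"plain"`.
#' @return list of [dna_molecule()] objects.
#' @export
read_sequences <- function(path, format = NULL) {
  if (is.null(format) || identical(format, "auto")) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gb", "gbk", "genbank")) "genbank"
    else if (ext %in% c("fa", "fasta", "fna")) "fasta"
    else if (startsWith(readLines(path, n = 1L, warn = FALSE), ">")) "fasta"
    else "plain"
  }
  switch(format,
    genbank = read_genbank(path),
    fasta = {
      set <- Biostrings::readDNAStringSet(path)
      if (length(set) == 0L) stop("empty FASTA file", call. = FALSE)
      lapply(seq_along(set), function(i) {
        dna_molecule(as.character(set[[i]]), "linear",
                     id = sub("\\s.*$", "", names(set)[i]),
                     note = paste0("read from ", basename(path)))
      })
    },
    plain = {
      txt <- paste(readLines(path, warn = FALSE), collapse = "")
      seqs <- toupper(gsub("[^A-Za-z]", "", txt))
      if (!nzchar(seqs)) stop("empty sequence file", call. = FALSE)
      list(dna_molecule(seqs, "linear",
                        note = paste0("read from ", basename(path))))
    },
    stop("unknown format: ", format, call. = FALSE))
}
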