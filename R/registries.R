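# Registries for restriction enzymes, vendor aliases, digestion buffers,
# guide RNAs and recombination sites, with tab-separated readers and bundled
# defaults under inst/extdata/.

#' Define a restriction enzyme
#'
#' Cut offsets are 0-based gap positions relative to the recognition-site
#' start on the top strand: `cut_top` is where the top strand is cleaved and
#' `cut_bottom` where the bottom strand is cleaved.  `cut_top < cut_bottom`
#' implies a 5' overhang, `>` a 3' overhang, `==` blunt.  Offsets may lie
#' outside the site (Type IIS enzymes such as BsaI).
#'
#' @param name canonical enzyme name.
#' @param recognition IUPAC recognition sequence.
#' @param cut_top,cut_bottom integer cut offsets (see Details).
#' @param notes free text.
#' @return an object of class `restriction_enzyme`.
#' @export
restriction_enzyme <- function(name, recognition, cut_top, cut_bottom,
                               notes = "") {
  recognition <- normalize_dna(recognition, "recognition site")
  structure(
    list(name = name, recognition = recognition,
         cut_top = as.integer(cut_top), cut_bottom = as.integer(cut_bottom),
         notes = notes),
    class = "restriction_enzyme"
  )
}

#' Read an enzyme table
#'
#' Tab-separated columns: `name  recognition  cut_top  cut_bottom`.
#'
#' @param path file path; the bundled default table when `NULL`.
#' @return named list of [restriction_enzyme()] records.
#' @export
read_enzyme_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "enzymes.tsv", package = "clonesim")
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    restriction_enzyme(tab$name[i], tab$recognition[i],
                       tab$cut_top[i], tab$cut_bottom[i])
  })
  names(out) <- tab$name
  out
}

#' Read an enzyme alias table
#'
#' Tab-separated columns: `alias  canonical  vendor`.  Every vendor product
#' name maps to exactly one canonical enzyme (e.g. Thermofisher's BcuI maps
#' to SpeI).
#'
#' @param path file path; the bundled default when `NULL`.
#' @return data.frame with columns `alias`, `canonical`, `vendor`.
#' @export
read_alias_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "enzyme_aliases.tsv", package = "clonesim")
  }
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a digestion buffer system
#'
#' Tab-separated columns: `vendor  buffer  alias  activity` with activity a
#' percentage in `[0, 100]` for the vendor's product name in that buffer.
#'
#' @param path file path; the bundled default when `NULL`.
#' @param vendor optional vendor filter.
#' @return an object of class `buffer_system`: list(vendor, table).
#' @export
read_buffer_table <- function(path = NULL, vendor = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "buffers.tsv", package = "clonesim")
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (any(tab$activity < 0 | tab$activity > 100)) {
    stop("buffer activities must lie in [0, 100]", call. = FALSE)
  }
  if (!is.null(vendor)) tab <- tab[tab$vendor == vendor, , drop = FALSE]
  structure(list(vendor = vendor, table = tab), class = "buffer_system")
}

#' Define a guide RNA
#'
#' @param name guide name.
#' @param spacer protospacer-matching sequence (>= 16 nt).
#' @param pam IUPAC PAM pattern (e.g. `"NGG"` for SpCas9), located 3' of the
#'   protospacer.
#' @param cut_offset position of the cut measured in bp from the PAM-proximal
#'   end of the protospacer (SpCas9 default 3: blunt cut 3 bp 5' of the PAM).
#' @param cut_offset_bottom bottom-strand offset for staggered cutters
#'   (defaults to `cut_offset`, i.e. blunt).
#' @return an object of class `guide_rna`.
#' @export
guide_rna <- function(name, spacer, pam = "NGG", cut_offset = 3L,
                      cut_offset_bottom = cut_offset) {
  spacer <- normalize_dna(spacer, "spacer")
  if (nchar(spacer) < 16L) stop("spacer must be >= 16 nt", call. = FALSE)
  pam <- normalize_dna(pam, "PAM")
  if (!nzchar(pam)) stop("PAM must be non-empty", call. = FALSE)
  structure(
    list(name = name, spacer = spacer, pam = pam,
         cut_offset = as.integer(cut_offset),
         cut_offset_bottom = as.integer(cut_offset_bottom)),
    class = "guide_rna"
  )
}

#' Read a gRNA table
#'
#' Tab-separated columns: `name  spacer  pam  cut_offset`.
#'
#' @param path file path; the bundled default when `NULL`.
#' @return named list of [guide_rna()] records.
#' @export
read_grna_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "grnas.tsv", package = "clonesim")
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    guide_rna(tab$name[i], tab$spacer[i], tab$pam[i], tab$cut_offset[i])
  })
  names(out) <- tab$name
  out
}

#' Define a recombination site
#'
#' Sites carry a shared core; recombination cuts at the core and rejoins via
#' virtual overhangs.  Reversible sites (loxP, FRT, ...) use the core
#' sequence itself as the marker, so excision products can re-integrate.
#' Irreversible pairs (attB/attP of serine integrases such as PhiC31) carry
#' two distinct markers for the exchanged halves, which blocks reassembly of
#' the original substrates.
#'
#' @param name site name.
#' @param sequence IUPAC site sequence.
#' @param core_start,core_end 0-based half-open core interval within the site.
#' @param reversible logical.
#' @param partners names of sites this one can recombine with (including
#'   itself for homotypic sites such as loxP).
#' @param marker_left,marker_right distinct markers for the two exchanged
#'   halves of an irreversible pair; ignored for reversible sites.
#' @return an object of class `recombination_site`.
#' @export
recombination_site <- function(name, sequence, core_start, core_end,
                               reversible = TRUE, partners = name,
                               marker_left = "", marker_right = "") {
  sequence <- normalize_dna(sequence, "site sequence")
  core_start <- as.integer(core_start)
  core_end <- as.integer(core_end)
  if (core_start < 0 || core_end <= core_start || core_end > nchar(sequence)) {
    stop("core interval must be non-empty and inside the site", call. = FALSE)
  }
  if (!reversible && (!nzchar(marker_left) || !nzchar(marker_right))) {
    stop("irreversible sites need two distinct markers", call. = FALSE)
  }
  structure(
    list(name = name, sequence = sequence,
         core_start = core_start, core_end = core_end,
         reversible = isTRUE(reversible), partners = partners,
         marker_left = marker_left, marker_right = marker_right),
    class = "recombination_site"
  )
}

#' Read a recombination-site table
#'
#' Tab-separated columns: `name  sequence  core_start  core_end  reversible
#' partners  marker_left  marker_right` (partners comma-separated).
#'
#' @param path file path; the bundled default when `NULL`.
#' @return named list of [recombination_site()] records.
#' @export
read_site_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "recombination_sites.tsv",
                        package = "clonesim")
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  unmask <- function(x) if (is.na(x) || x == ".") "" else x  # "." = none
  out <- lapply(seq_len(nrow(tab)), function(i) {
    recombination_site(tab$name[i], tab$sequence[i], tab$core_start[i],
                       tab$core_end[i],
                       reversible = as.logical(tab$reversible[i]),
                       partners = strsplit(unmask(tab$partners[i]), ",")[[1]],
                       marker_left = unmask(tab$marker_left[i]),
                       marker_right = unmask(tab$marker_right[i]))
  })
  names(out) <- tab$name
  out
}
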