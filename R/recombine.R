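# Recombination by virtual digestion / virtual ligation.
#
# Stage 1 (virtual digestion): recombination sites, or shared homologous
# blocks, are treated as virtual restriction sites. Cutting a site at its
# shared core (or a homology block over its whole length) yields ends that
# carry virtual markers instead of base-pairable overhangs: reversible sites
# and homology blocks use the core/block sequence itself as the marker (its
# complement is the reverse complement, so directionality works exactly like
# a sticky end), while irreversible site pairs (serine integrases: attB/attP)
# carry distinct tag markers for the two exchanged halves, which blocks
# reassembly of the original substrates.
#
# Stage 2 (virtual ligation): the ligation search runs on the cut pieces
# with marker equality replacing base-pair complementarity and the phosphate
# rule waived.
#
# Stage 3: every intermediate still carrying a virtual end is disposed of;
# only fully resolved molecules are returned.

HOMOLOGY_FAMILIES <- c("homologous", "lambda_red", "in_vitro_annealing",
                       "in_vivo_annealing")

#' Homology-search parameters for the recombination families
#'
#' Defaults encode the family semantics: lambda Red uses homology arms of at
#' least 20 bp lying within the terminal 100 bp of a linear cassette;
#' SLIC/Gibson-style in vitro and in vivo annealing use homology lying
#' entirely within 250 bp of a fragment end; plain homologous recombination
#' searches anywhere.
#'
#' @param family one of `"homologous"`, `"lambda_red"`,
#'   `"in_vitro_annealing"`, `"in_vivo_annealing"`.
#' @param min_homology_len minimum shared-block length in bp (>= 8).
#' @param terminal_window how far from a linear fragment's terminus the
#'   distal edge of a block may lie (bp; `Inf` = unbounded).
#' @param min_arm_len minimum arm length for lambda Red (bp).
#' @return an object of class `homology_params`.
#' @export
homology_params <- function(family = HOMOLOGY_FAMILIES,
                            min_homology_len = NULL,
                            terminal_window = NULL,
                            min_arm_len = 20L) {
  family <- match.arg(family)
  if (is.null(terminal_window)) {
    terminal_window <- switch(family,
      homologous = Inf,
      lambda_red = 100,
      in_vitro_annealing = 250,
      in_vivo_annealing = 250)
  }
  if (is.null(min_homology_len)) {
    min_homology_len <- if (family == "lambda_red") min_arm_len else 15L
  }
  if (min_homology_len < 8L) stop("min_homology_len must be >= 8", call. = FALSE)
  if (terminal_window <= 0) stop("terminal_window must be positive", call. = FALSE)
  structure(list(family = family,
                 min_homology_len = as.integer(min_homology_len),
                 terminal_window = terminal_window,
                 min_arm_len = as.integer(min_arm_len)),
            class = "homology_params")
}

# maximal exact common substrings >= min_len between two strings, via k-mer
# seeding and diagonal-run merging. Returns data.frame(xa, xb, len, strand),
# xa/xb 0-based starts (xb on the plus strand of b). self = the two strings
# are the same molecule (suppresses the trivial identity diagonal).
maximal_matches <- function(a, b, min_len, self = FALSE) {
  res <- list()
  one_strand <- function(bs, strand) {
    k <- min_len
    na <- nchar(a); nb <- nchar(bs)
    if (na < k || nb < k) return(NULL)
    ak <- substring(a, 1:(na - k + 1L), k:na)
    bk <- substring(bs, 1:(nb - k + 1L), k:nb)
    idx <- split(seq_along(ak), ak)
    hits_i <- integer(0); hits_j <- integer(0)
    common <- intersect(names(idx), unique(bk))
    for (km in common) {
      js <- which(bk == km)
      is <- idx[[km]]
      hits_i <- c(hits_i, rep(is, each = length(js)))
      hits_j <- c(hits_j, rep(js, times = length(is)))
    }
    if (length(hits_i) == 0L) return(NULL)
    d <- hits_j - hits_i
    out <- list()
    for (dd in unique(d)) {
      ii <- sort(hits_i[d == dd])
      runs <- split(ii, cumsum(c(1L, diff(ii) != 1L)))
      for (r in runs) {
        i0 <- r[1]; i1 <- r[length(r)]
        L <- i1 - i0 + k
        out[[length(out) + 1L]] <- c(xa = i0 - 1L, xb = i0 + dd - 1L, len = L)
      }
    }
    m <- do.call(rbind, out)
    data.frame(xa = m[, "xa"], xb = m[, "xb"], len = m[, "len"],
               strand = strand, stringsAsFactors = FALSE)
  }
  plus <- one_strand(b, "+")
  if (!is.null(plus)) {
    if (self) plus <- plus[plus$xa != plus$xb, , drop = FALSE]
    res <- c(res, list(plus))
  }
  minus <- one_strand(revcomp(b), "-")
  if (!is.null(minus)) {
    nb <- nchar(b)
    minus$xb <- nb - minus$xb - minus$len   # map back to plus-strand start
    res <- c(res, list(minus))
  }
  if (length(res) == 0L) {
    return(data.frame(xa = integer(0), xb = integer(0), len = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  unique(out)
}

# does a block [x, x+len) qualify for the family on a molecule of length n
# with the given topology? windows bind only linear fragments (cassettes /
# assembly pieces); circular and genomic substrates are the unrestricted
# targets.
.block_allowed <- function(params, topology, n, x, len) {
  if (len < params$min_homology_len) return(FALSE)
  if (topology != "linear") return(TRUE)
  if (params$family == "lambda_red" && len < params$min_arm_len) return(FALSE)
  edge <- min(x + len, n - x)   # distal-edge distance from nearer terminus
  if (edge > params$terminal_window) return(FALSE)
  if (params$family == "in_vitro_annealing") {
    # no non-matching tail distal to the joined homology: block flush
    return(x == 0L || x + len == n)
  }
  TRUE
}

# virtual cut for a block [x, x+len) on `mol`: geometry of a 3' overhang
# spanning the block (the upstream piece keeps the block), with the block's
# top-strand sequence as the marker
.block_cut <- function(mol, x, len) {
  circular <- mol$topology == "circular"
  blk <- wrap_substr(mol$seq, x, x + len, circular)
  make_cut(x + len, x,
           left_end = dna_end("virtual", marker = blk),
           right_end = dna_end("virtual", marker = revcomp(blk)),
           label = paste0("hom:", x))
}

# all qualifying homology cuts per molecule for a fragment set
.homology_cuts <- function(mols, params) {
  nmol <- length(mols)
  cuts <- rep(list(list()), nmol)
  keys <- rep(list(character(0)), nmol)
  add_block <- function(m, x, len) {
    mol <- mols[[m]]
    n <- nchar(mol$seq)
    if (mol$topology == "circular") x <- x %% n
    if (!.block_allowed(params, mol$topology, n, x, len)) return(invisible())
    key <- paste(x, len)
    if (key %in% keys[[m]]) return(invisible())
    keys[[m]] <<- c(keys[[m]], key)
    cuts[[m]][[length(cuts[[m]]) + 1L]] <<- .block_cut(mol, x, len)
    invisible()
  }
  seq_of <- function(mol) {
    if (mol$topology == "circular") paste0(mol$seq, mol$seq) else mol$seq
  }
  for (i in seq_len(nmol)) {
    for (j in i:nmol) {
      mm <- maximal_matches(seq_of(mols[[i]]), seq_of(mols[[j]]),
                            params$min_homology_len, self = i == j)
      ni <- nchar(mols[[i]]$seq); nj <- nchar(mols[[j]]$seq)
      for (r in seq_len(nrow(mm))) {
        len <- min(mm$len[r], ni, nj)
        xa <- mm$xa[r]; xb <- mm$xb[r]
        if (mols[[i]]$topology == "circular" && xa >= ni) next  # doubled copy
        if (mols[[j]]$topology == "circular" && xb >= nj) next
        if (mols[[i]]$topology != "circular" && xa + len > ni) next
        if (mols[[j]]$topology != "circular" && xb + len > nj) next
        add_block(i, xa, len)
        add_block(j, xb, len)
      }
    }
  }
  cuts
}

# site-specific virtual cuts for one molecule against a site list
.site_cuts <- function(mol, sites) {
  cuts <- list()
  for (site in sites) {
    Ls <- nchar(site$sequence)
    hits <- find_pattern(mol, site$sequence, both_strands = TRUE)
    for (r in seq_len(nrow(hits))) {
      p <- hits$pos[r]
      if (hits$strand[r] == "+") {
        t <- p + site$core_end
        b <- p + site$core_start
        if (site$reversible) {
          core <- wrap_substr(mol$seq, b, t, mol$topology == "circular")
          ml <- core; mr <- revcomp(core)
        } else {
          ml <- paste0(site$marker_left, ">")
          mr <- paste0(site$marker_right, "<")
        }
      } else {
        t <- p + Ls - site$core_start
        b <- p + Ls - site$core_end
        if (site$reversible) {
          core <- wrap_substr(mol$seq, b, t, mol$topology == "circular")
          ml <- core; mr <- revcomp(core)
        } else {
          # strand flip exchanges the two pieces; markers are physical
          ml <- paste0(site$marker_right, "<")
          mr <- paste0(site$marker_left, ">")
        }
      }
      if (mol$topology != "circular" &&
          (min(t, b) < 0L || max(t, b) > nchar(mol$seq))) next
      cuts[[length(cuts) + 1L]] <- make_cut(
        t, b,
        left_end = dna_end("virtual", marker = ml),
        right_end = dna_end("virtual", marker = mr),
        label = site$name)
    }
  }
  cuts
}

# enumerate maximal non-conflicting subsets of possibly-overlapping cuts
# (alternative homologies at overlapping positions are explored separately)
.cut_scenarios <- function(cuts, cap = 32L) {
  if (length(cuts) <= 1L) return(list(cuts))
  conflict <- outer(seq_along(cuts), seq_along(cuts), Vectorize(function(i, j) {
    i != j && .cut_conflicts(cuts[[i]], cuts[[j]])
  }))
  if (!any(conflict)) return(list(cuts))
  scenarios <- list()
  recurse <- function(chosen, rest) {
    if (length(scenarios) >= cap) return(invisible())
    if (length(rest) == 0L) {
      scenarios[[length(scenarios) + 1L]] <<- chosen
      return(invisible())
    }
    i <- rest[1]
    rest <- rest[-1]
    ok <- !any(vapply(chosen, function(c0) .cut_conflicts(cuts[[i]], c0),
                      logical(1)))
    if (ok) recurse(c(chosen, list(cuts[[i]])), rest)
    # skip i only if it conflicts with something (otherwise always take it)
    if (!ok || any(conflict[i, rest])) recurse(chosen, rest)
    invisible()
  }
  recurse(list(), seq_along(cuts))
  unique(scenarios)
}

#' Recombination (site-specific and homologous)
#'
#' Runs the virtual digestion / virtual ligation algorithm. For site-specific
#' recombination, pass a list of [recombination_site()] records (or names
#' resolved against the bundled table); every site occurrence is cut at its
#' shared core. For homologous families, pass a family name or a
#' [homology_params()] object; shared blocks of at least `min_homology_len`
#' are located (subject to each family's terminal windows) and cut over their
#' whole length. Virtual ligation then joins marker-complementary ends, and
#' every intermediate still carrying a virtual end is discarded, so only real
#' DNA molecules are returned. `in_vitro_annealing` joins only flush terminal
#' homology (it cannot cut off non-matching tails), whereas
#' `in_vivo_annealing` removes such tails.
#'
#' @param mols a [dna_molecule()] or list of them.
#' @param spec a family name, a [homology_params()], a list of
#'   [recombination_site()] records, or a character vector of site names.
#' @param mode a [join_mode()]; the default runs the normal-mode search with
#'   enough rounds to resolve every junction, one copy of each substrate.
#'   Exhaustive mode requires every substrate to be represented exactly
#'   `copies` times in a product.
#' @param site_registry site table for name resolution (bundled default when
#'   `NULL`).
#' @return list of product molecules; empty, with a `diagnostic` attribute,
#'   when no site or homology is found.
#' @export
recombine <- function(mols, spec, mode = NULL, site_registry = NULL) {
  mols <- as_molecule_list(mols)
  site_mode <- FALSE
  if (inherits(spec, "homology_params")) {
    params <- spec
  } else if (is.character(spec) && length(spec) == 1L &&
             spec %in% HOMOLOGY_FAMILIES) {
    params <- homology_params(spec)
  } else {
    site_mode <- TRUE
    if (is.character(spec)) {
      if (is.null(site_registry)) site_registry <- read_site_table()
      missing <- setdiff(spec, names(site_registry))
      if (length(missing) > 0) {
        stop("unknown recombination site(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
      spec <- site_registry[spec]
    }
    if (inherits(spec, "recombination_site")) spec <- list(spec)
    stopifnot(all(vapply(spec, inherits, logical(1), "recombination_site")))
  }
  cuts_by_mol <- if (site_mode) {
    lapply(mols, .site_cuts, sites = spec)
  } else {
    .homology_cuts(mols, params)
  }
  if (all(vapply(cuts_by_mol, length, integer(1)) == 0L)) {
    out <- list()
    attr(out, "diagnostic") <- if (site_mode) {
      "no recombination site found in the substrates"
    } else {
      "no shared homology found in the substrates"
    }
    return(out)
  }
  scen_by_mol <- lapply(cuts_by_mol, .cut_scenarios)
  # cartesian product of per-molecule scenarios (capped)
  combos <- list(integer(0))
  for (m in seq_along(mols)) {
    ns <- length(scen_by_mol[[m]])
    combos <- unlist(lapply(combos, function(cb) {
      lapply(seq_len(ns), function(s) c(cb, s))
    }), recursive = FALSE)
    if (length(combos) > 256L) combos <- combos[1:256]
  }
  if (is.null(mode)) mode <- join_mode("normal", rounds = 1L)  # rounds set below
  seen <- new.env(parent = emptyenv())
  products <- list()
  for (cb in combos) {
    items <- list()
    groups <- integer(0)
    for (m in seq_along(mols)) {
      scen <- scen_by_mol[[m]][[cb[m]]]
      pieces <- if (length(scen) == 0L) list() else apply_cuts(mols[[m]], scen)
      items <- c(items, pieces)
      groups <- c(groups, rep(m, length(pieces)))
    }
    if (length(items) == 0L) next
    run_mode <- mode
    if (run_mode$mode == "normal") {
      run_mode$rounds <- max(run_mode$rounds, length(items))
    }
    res <- join_search(items, run_mode, virtual = TRUE, groups = groups)
    for (p in res) {
      if (.has_virtual_end(p)) next   # dispose of unresolved intermediates
      h <- canonical_hash(p)
      if (is.null(seen[[h]])) {
        assign(h, TRUE, envir = seen)
        products[[length(products) + 1L]] <- p
      }
    }
  }
  products
}

.has_virtual_end <- function(mol) {
  if (mol$topology == "circular") return(FALSE)
  is_virtual_end(mol$left_end) || is_virtual_end(mol$right_end)
}
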