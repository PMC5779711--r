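# Melting temperature and duplex free-energy calculations.
#
# Two Tm methods are offered: the Wallace rule 2(A+T) + 4(G+C) for quick
# short-oligo estimates, and unified nearest-neighbor thermodynamics
# (SantaLucia 1998 parameter set: dH in kcal/mol, dS in cal/(mol K), with
# the entropic salt correction 0.368 * Nstacks * ln[Na+] and the duplex
# initiation terms for terminal A.T / G.C pairs). Free energies for
# hairpin/dimer scoring are evaluated at 37 C from the same table.

NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)

NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

NN_INIT_DH <- c(GC = 0.1, AT = 2.3)   # per terminal pair
NN_INIT_DS <- c(GC = -2.8, AT = 4.1)

GAS_CONSTANT <- 1.987  # cal / (K mol)

#' Melting-temperature parameters
#'
#' @param method `"nearest_neighbor"` or `"wallace"`.
#' @param oligo_conc total oligonucleotide concentration, molar (default
#'   0.5 uM).
#' @param salt_conc monovalent cation concentration, molar (default 50 mM).
#' @return an object of class `tm_params`.
#' @export
tm_params <- function(method = c("nearest_neighbor", "wallace"),
                      oligo_conc = 5e-7, salt_conc = 0.05) {
  method <- match.arg(method)
  stopifnot(oligo_conc > 0, salt_conc > 0)
  structure(list(method = method, oligo_conc = oligo_conc,
                 salt_conc = salt_conc), class = "tm_params")
}

.check_concrete <- function(seq) {
  if (!is_concrete_dna(seq)) {
    stop("Tm is defined for concrete ACGT sequences only", call. = FALSE)
  }
}

.terminal_class <- function(base) if (base %in% c("G", "C")) "GC" else "AT"

# sum of stack and initiation dH/dS for a perfect duplex of `seq`
nn_sums <- function(seq) {
  n <- nchar(seq)
  stacks <- substring(seq, 1:(n - 1L), 2:n)
  first <- .terminal_class(substr(seq, 1L, 1L))
  last <- .terminal_class(substr(seq, n, n))
  list(dh = sum(NN_DH[stacks]) + NN_INIT_DH[[first]] + NN_INIT_DH[[last]],
       ds = sum(NN_DS[stacks]) + NN_INIT_DS[[first]] + NN_INIT_DS[[last]],
       nstacks = n - 1L)
}

#' Oligonucleotide melting temperature
#'
#' Wallace rule: `2(A+T) + 4(G+C)` degrees C, any length. Nearest-neighbor:
#' unified duplex parameters with salt-corrected entropy,
#' `Tm = 1000 dH / (dS + 0.368 (n-1) ln[Na+] + R ln(Ct/x)) - 273.15`,
#' with `x = 1` for self-complementary oligos and 4 otherwise; valid for
#' 6-60 nt.
#'
#' @param seq primer sequence (ACGT only).
#' @param params a [tm_params()].
#' @return melting temperature in degrees C.
#' @export
melting_temperature <- function(seq, params = tm_params()) {
  seq <- normalize_dna(seq, "primer")
  .check_concrete(seq)
  n <- nchar(seq)
  if (params$method == "wallace") {
    at <- sum(strsplit(seq, "")[[1]] %in% c("A", "T"))
    return(2 * at + 4 * (n - at))
  }
  if (n < 6L || n > 60L) {
    stop("nearest-neighbor Tm is defined for 6-60 nt", call. = FALSE)
  }
  s <- nn_sums(seq)
  self_comp <- seq == revcomp(seq)
  ds_salt <- s$ds + 0.368 * s$nstacks * log(params$salt_conc)
  if (self_comp) ds_salt <- ds_salt - 1.4
  x <- if (self_comp) 1 else 4
  1000 * s$dh / (ds_salt + GAS_CONSTANT * log(params$oligo_conc / x)) - 273.15
}

# dG at 37 C (kcal/mol) of a perfect duplex region (both-end initiation)
duplex_dg37 <- function(seq) {
  s <- nn_sums(seq)
  s$dh - 310.15 * s$ds / 1000
}

#' Sliding-window melting-temperature profile
#'
#' The Tm of every window of `window_len` nucleotides: `length - window_len
#' + 1` values for a linear molecule, `length` values (wrapping the origin)
#' for a circular one.
#'
#' @param mol a [dna_molecule()] (ACGT only).
#' @param window_len window length in bp (>= 6).
#' @param params a [tm_params()].
#' @return numeric vector of temperatures, one per window start.
#' @export
tm_profile <- function(mol, window_len, params = tm_params("wallace")) {
  stopifnot(inherits(mol, "dna_molecule"))
  if (window_len < 6L) stop("window_len must be >= 6", call. = FALSE)
  n <- nchar(mol$seq)
  if (window_len > n) stop("window_len exceeds molecule length", call. = FALSE)
  subject <- if (mol$topology == "circular") {
    paste0(mol$seq, substr(mol$seq, 1L, window_len - 1L))
  } else {
    mol$seq
  }
  nwin <- if (mol$topology == "circular") n else n - window_len + 1L
  vapply(seq_len(nwin), function(i) {
    melting_temperature(substr(subject, i, i + window_len - 1L), params)
  }, numeric(1))
}
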