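---
title: "clonesim: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{clonesim: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonesim)
```

clonesim simulates molecular-cloning workflows mechanistically: every
wet-lab operation is a pure function from DNA molecules (and host cells) to
product sets, and a project is a directed acyclic graph of such operations
that can be recalculated top-down after any edit. This vignette documents
the underlying models, the tunable parameters and their defaults, the
numerical and design choices, and what the synthetic test substrates do and
do not emulate.

## The DNA molecule model

A `dna_molecule` is the top strand written 5'→3' plus a topology
(`linear`, `circular`, or `genomic_fragment`) and, for non-circular
molecules, two typed ends. An end records its overhang polarity (blunt, 5',
or 3'), the protruding-strand sequence written 5'→3', a 5'-phosphorylation
flag, and a hairpin flag. Writing overhangs on the protruding strand makes
them physical: a strand flip swaps the two ends but changes neither their
polarity nor their sequence.

Coordinates are 0-based half-open everywhere inside the package; GenBank
input/output converts to and from the format's 1-based inclusive locations.
On circular molecules a feature may wrap the origin, represented by an end
coordinate beyond the sequence length.

The representation ties ends to the sequence so that joining is plain
concatenation: a left 5' overhang and a right 3' overhang protrude on the
top strand and are part of `seq`; a left 3' and a right 5' overhang protrude
on the bottom strand and are not. Under this convention the total top-strand
length of digestion fragments always equals that of the substrate, which the
test suite asserts as a mass-conservation property.

Molecule identity is a SHA-256 digest of (topology, canonical sequence
representative, end codes): circular molecules are canonicalized over all
rotations of both strands (Booth's least-rotation algorithm), linear ones
over the two strands. Hash-based deduplication is what makes product-set
enumeration terminate and lets screening nodes select products that length
or features cannot distinguish.

## Cutting

A restriction enzyme is a recognition pattern plus two cut offsets —
0-based gap positions for the top and bottom strand relative to the site
start. `cut_top < cut_bottom` yields a 5' overhang, the converse a 3'
overhang, equality a blunt cut; offsets may lie outside the site, which is
all that is needed for Type IIS enzymes and Golden Gate. Site search treats
IUPAC degeneracy asymmetrically: a degenerate pattern symbol matches its
base set, but a degenerate *substrate* base never satisfies a more specific
pattern symbol, so no product is fabricated from ambiguous sequence. All
cuts of all enzymes are applied simultaneously (complete digestion;
partial digests are out of scope). When the overhang regions of two cuts
overlap, the geometrically impossible cut is dropped and a warning is
emitted — the conflict is reported rather than silently resolved. Both new
ends at a cut carry fresh 5' phosphates.

CRISPR digestion reuses the same machinery: each guide becomes a temporary
enzyme whose recognition sequence is protospacer + PAM and whose cut
geometry comes from the guide record. The bundled default is SpCas9
geometry — PAM `NGG`, blunt cut 3 bp 5' of the PAM — but both are plain
columns of the gRNA table, so staggered cutters (Cpf1-style) are expressed
by giving the two strands different offsets.

## Joining

Two ends ligate iff (1) at least one of them carries a 5' phosphate and
(2) both are blunt, or both overhangs have the same polarity and exactly
reverse-complementary sequences. Hairpin ends never ligate; overhangs
containing degenerate bases never match.

The product search has two modes. *Normal* mode is a breadth-limited
search: each round joins every pair of molecules built so far, in all four
orientation combinations, subject to per-fragment copy limits, with
self-circularization attempted throughout and canonical-hash deduplication.
The pool is capped (2000 molecules) so pathological inputs terminate.
*Exhaustive* mode models one-pot assembly (Golden Gate): a depth-first
enumeration returns only products that consume exactly the specified copy
count of every fragment. Both modes report every distinct linear and
circular product; unreacted inputs are not products.

## Recombination by virtual digestion and ligation

All recombination chemistries reduce to the same two-stage algorithm.

*Stage 1 — virtual digestion.* Recombination sites, or shared homologous
blocks, are treated as virtual restriction sites. Cutting yields ends
carrying *markers* instead of base-pairable overhangs. Reversible sites
(loxP, FRT) and homology blocks use the core/block sequence itself as the
marker; its complement is the reverse complement, so marker matching
behaves exactly like sticky-end matching, directionality included (direct
lox repeats excise, inverted repeats invert). Irreversible pairs — serine
integrases such as PhiC31, or integrase-only att reactions without the
excision factors — carry two distinct tag markers for the exchanged halves,
so attB × attP yields attL/attR but the products cannot react back.

*Stage 2 — virtual ligation.* The ligation search runs on the cut pieces
with marker complementarity in place of base pairing and the phosphate rule
waived (no free ends exist in vivo at a recombination junction).

*Stage 3 — disposal.* Any molecule still carrying a virtual end is an
unresolved intermediate and is discarded; only real DNA is returned.

The homology families differ only in where stage 1 may cut a linear
fragment (circular and genomic substrates are unrestricted targets):

| family | block length | placement |
|---|---|---|
| `homologous` | ≥ 15 bp (default) | anywhere |
| `lambda_red` | ≥ 20 bp (arm minimum) | distal edge within 100 bp of a terminus |
| `in_vitro_annealing` | ≥ 15 bp | within 250 bp of a terminus, flush at the end |
| `in_vivo_annealing` | ≥ 15 bp | distal edge within 250 bp of a terminus |

The in vitro family cannot remove a non-matching tail distal to the joined
homology, so it only uses blocks flush with a fragment end; the in vivo
family cuts anywhere in its window and the displaced tails are discarded as
unresolved intermediates. Homology detection is by maximal exact common
substrings (k-mer seeding plus diagonal-run merging); mismatched homology
is out of scope. When alternative homologies overlap, each maximal
non-conflicting cut subset is explored and the product sets are unioned.

Copy accounting differs between the modes on purpose. In normal mode the
limits are per cut piece, so intramolecular outcomes that need both pieces
of one substrate (inversion, wild-type regeneration) are reachable. In
exhaustive mode the accounting is per input molecule: a product must
represent every substrate exactly its copy count, while leftover pure-block
or tail pieces are not demanded — that is what "uses up all fragments"
means for an assembly whose junction blocks are shared between neighbours.

## PCR by single-strand enumeration

Stage 1 enumerates single-strand extension products: a primer whose
3'-terminal `min_anneal_3p` bases (default 15, exact match — mismatch
annealing is out of scope) match a template strand is extended to the
template's 5' end, 5' tail retained verbatim; on circular templates the
polymerase runs one full turn. New strands re-enter the pool as templates,
to a fixed point (capped at 10 rounds, pool capped at 200 strands), which
is how overlap-extension products arise. Stage 2 anneals every pair of
strands with mutually reverse-complementary 3' regions of at least
`min_anneal_3p` bases and fills both in. A duplex is an exponential
*product* when each strand begins with a primer sequence — a structural
check, so a primer that coincides with a template end still counts — and a
*by-product* otherwise; re-formed input templates are dropped. For circular
templates the enumeration also reports the long first-turn duplex alongside
the origin-spanning amplicon; screening by length separates them, as a gel
would.

Sequencing simulation is the one-primer special case: the read is the
template-directed extension downstream of a primer that must anneal exactly
once; zero or multiple sites are an error, never a guess.

## Thermodynamics

Two melting-temperature methods are provided. The Wallace rule
`2(A+T) + 4(G+C)` serves the classic minimal-primer design (and is the
default for `design_primers`, so "minimal primer above a Tm" retains its
textbook meaning down to very short oligos). The nearest-neighbor method
uses the unified duplex parameter set (dH in kcal/mol, dS in cal/mol/K),
duplex-initiation terms for terminal A·T and G·C pairs, the entropic salt
correction `0.368 · n_stacks · ln[Na+]`, and the hybridization equation
`Tm = 1000·dH / (dS_salt + R·ln(Ct/x)) − 273.15` with `x = 4` (1 for
self-complementary oligos). Defaults are 0.5 µM total oligo and 50 mM
monovalent salt. Hairpin/dimer screening scores contiguous stems (≥ 3 bp,
hairpin loops ≥ 3 nt) with the same table at 37 °C; loop entropy beyond the
minimum size is not modelled, so the reported ΔG is a worst-case stem
energy. The exhaustive stem search is quadratic-to-cubic in oligo length
and intended for oligos up to ~60 nt.

The Gibson assembly designer grows each junction overlap base by base from
the junction-proximal neighbour sequence, starting at `min_overlap`
(default 15 bp), until the nearest-neighbor Tm reaches the threshold
(default 48 °C), and prepends it to the adjacent non-fixed primer —
preferring the downstream fragment's forward primer, falling back to the
upstream reverse primer when the former is fixed or the fragment is not a
PCR product. The design is verified by running the in vivo annealing
recombination in exhaustive mode and demanding a single circle containing
every source exactly once.

## Screening, hosts, and the workflow graph

Gel separation keeps molecules inside an inclusive length range after
unconditionally discarding anything shorter than 50 bp (fragments below the
floor run off the simulated gel whatever range is requested). Feature
screening counts per-name occurrences regardless of strand; all criteria
must hold. PCR screening keeps molecules for which a simulated reaction
yields a product inside a strict inclusive length range.

Host simulation is deliberately rule-based: a plasmid persists through
incubation iff one of its `ori` features names an origin in the host's
primase commands (exact name matching — the contract is the name, not a
sequence model), and under overnight selection a cell survives iff every
antibiotic is countered by a resistance feature on a persisting plasmid, an
integrated genome copy, or an intrinsic resistance. Transformation offers
all-into-one-cell, one-DNA-per-cell, and combinational modes; combinational
enumerates all 2^n − 1 non-empty subsets (an empty transformation is not a
transformant). Extraction returns hosted plasmids, never genome fragments,
and does not mutate the cell.

Sequence comparison aligns each query semi-globally (whole query, local
template window) with affine gaps, match 2 / mismatch −3 / gap open 5 /
gap extend 2 — fixed, documented scores chosen to favour contiguous
matches on high-identity sequencing reads. Exactly matching runs become
`alignment_match` features; substitutions and indels become their own
feature kinds with the query name in the qualifiers, so several reads stack
on one template.

Workflow nodes cache their results under a content key (operation kind,
parameters, source result hashes); recalculation walks the edited node and
its descendants in Kahn topological order, skips nodes whose key is
unchanged, marks failing nodes and their descendants stale, and continues
with siblings, returning the list of nodes actually run. Projects persist
to a canonical JSON schema (fixed field order, scalar-array normal form),
so save → load → save is byte-identical.

## Synthetic substrates and what the tests show

Every test input is generated by `generate_fixture()` from a seed, with a
manifest carrying the designed ground truth (site counts, product lengths,
planted coordinates), and tests assert against manifests. Two details
matter for interpreting the window tests. First, random padding is scrubbed
of the restriction sites and markers under test, so "unique site" claims
hold by construction. Second, homology fixtures place single mismatching
guard bases at block boundaries so the maximal exact match is exactly the
designed block — without guards, a 1-in-4 base coincidence silently extends
the homology and shifts a window scan by a base. Scales are desk-sized
(plasmids of a few kb, genomic loci of ~2 kb, 1,000-case oracle
equivalence runs on ≤ 4 fragments of 20–60 bp), chosen so the whole suite
enumerates product sets exhaustively in well under a minute per property.

The fixtures emulate topology, end chemistry, site geometry and homology
placement. They do not emulate sequence composition biases, repeats at
genomic scale, methylation, star activity, recombination efficiency, or
mismatched annealing — all of which are explicit non-goals of the
simulator, so green tests certify the combinatorial rules, not quantitative
yields on real constructs.

The bundled registries follow the same philosophy: the ~40 restriction
enzymes carry standard recognition/cut geometries, loxP and FRT are the
canonical published sequences, while the att site entries are
representative stand-ins with the documented core layout (the table is
data; replace the entries with your integrase's sites for real designs).
The digestion-buffer activity table is likewise a synthetic illustrative
default, and the vendor alias system (e.g. Thermofisher's BcuI ↦ SpeI;
NEB's SpeI and SpeI-HF ↦ SpeI) is the part under test: the buffer search
resolves queries through canonical names and ranks buffers by maximizing
the minimum activity across the enzyme combination, ties broken
alphabetically.

## Known limitations

Partial digestion, star activity and methylation sensitivity are not
modelled. Ligation treats all compatible joins as equally likely — there is
no kinetics, so "products" means "reachable products". Homology detection
is exact-match only. PCR annealing requires an exact 3' match and reports
no mispriming. The normal-mode search and the PCR strand pool are bounded
(2000 molecules / 200 strands, 10 rounds), so extremely repetitive inputs
may be truncated rather than enumerated; the caps are deliberate
determinism guards, generous for bench-scale constructs. Tm values follow
the unified nearest-neighbor table with a single salt correction;
divalent-cation and dNTP corrections are not applied.
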