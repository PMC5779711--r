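# clonesim

In silico molecular cloning and recombineering for R.

Cloning strategies fail at the bench for reasons that are perfectly
predictable on paper: an overhang that cannot ligate, a dephosphorylated
junction, a homology arm that is one cut-site short, an att reaction run in
the wrong direction, a screen that cannot distinguish the right clone from
a religated vector. clonesim is for molecular biologists and synthetic
biologists who want to validate a whole construction route — digestions,
end modifications, ligations, site-specific and homologous recombination,
PCR, screening, transformation and selection — before ordering a single
primer.

The simulator is mechanistic rather than heuristic. A DNA molecule is a
top strand with a topology (linear, circular, or genomic fragment) and two
typed ends: overhang polarity and protruding-strand sequence,
5'-phosphorylation, hairpin state. Every operation maps substrate molecules
to the complete set of reachable products, including intermediates and
by-products, deduplicated by a rotation- and strand-invariant canonical
hash.

Two ideas carry most of the weight:

* **Ligation as the universal joining engine.** Two ends join iff at least
  one carries a 5' phosphate and the ends are both blunt or bear
  same-polarity, reverse-complementary overhangs. A *normal* mode runs a
  bounded breadth search with per-fragment copy limits; an *exhaustive*
  mode returns only products consuming exactly the specified copies of
  every fragment (one-pot assemblies such as Golden Gate).

* **Recombination as virtual digestion + virtual ligation.** Recombination
  sites and shared homologies are cut like restriction sites into ends
  carrying markers instead of base-pairable overhangs: reversible sites
  (loxP, FRT) mark with their core sequence, irreversible pairs (attB/attP
  of serine integrases) with distinct tags that block reassembly of the
  substrates, and homologous families (plain homologous, lambda Red with
  its ≥ 20 bp arms within 100 bp of a cassette end, Gibson/SLIC-style
  annealing within 250 bp of an end) cut at maximal exact shared blocks.
  The ligation engine then joins marker-complementary ends, and every
  unresolved intermediate is discarded.

On top sit PCR simulation by single-strand enumeration and 3'-anchored
annealing (with Wallace and unified nearest-neighbor Tm, hairpin/dimer
ΔG screening, minimal-primer and Gibson-linker design), product screening
(gel with its 50-bp floor, feature counts, PCR screening), rule-based host
simulation (origin support, antibiotic selection, three transformation
modes), and a workflow DAG whose nodes cache results content-addressed and
recalculate in topological order after any edit. Projects round-trip
through a canonical JSON schema; sequences through GenBank, FASTA and
plain text.

## A worked example

Clone a kanamycin-resistance gene into the EcoRI/BamHI sites of a 3-kb
ampicillin vector, then screen the ligation mix:

```r
library(clonesim)

vector <- generate_fixture("toy_plasmid", seed = 4)$molecules[[1]]
lib    <- fixture_library()
donor  <- dna_molecule(paste0(random_dna(20, seed = 41), "GAATTC",
                              lib$entries$kanR$seq, "GGATCC",
                              random_dna(20, seed = 42)), id = "donor")

res <- digest(list(vector, donor), c("EcoRI", "BamHI"))
for (f in res$fragments) print(f)
#> <dna_molecule mol000001> linear, 16 bp,   ends P-5ov:AATT | P-5ov:GATC, 0 feature(s)
#> <dna_molecule mol000002> linear, 2984 bp, ends P-5ov:GATC | P-5ov:AATT, 2 feature(s)
#> <dna_molecule mol000003> linear, 21 bp,   ends blunt | P-5ov:AATT, 0 feature(s)
#> <dna_molecule mol000004> linear, 126 bp,  ends P-5ov:AATT | P-5ov:GATC, 0 feature(s)
#> <dna_molecule mol000005> linear, 25 bp,   ends P-5ov:GATC | blunt, 0 feature(s)

prods <- ligate(res$fragments, join_mode("normal", rounds = 3))
length(prods)
#> [1] 54

clones <- feature_screen(lapply(prods, annotate_features, lib = lib),
                         screen_condition(
                           require_circular = TRUE,
                           feature_counts = list(
                             list(name = "ampR", cmp = "eq", count = 1),
                             list(name = "kanR", cmp = "eq", count = 1))))
length(clones); print(clones[[1]])
#> [1] 1
#> <dna_molecule mol000139> circular, 3110 bp, 3 feature(s)
```

Reading the output: the two digests release the 2,984-bp vector backbone
(asymmetric `GATC`/`AATT` sticky ends, both phosphorylated, so the insert
is forced into one orientation) and the 126-bp kanR cassette, along with
the small polylinker and donor-arm fragments. The 54 ligation products are
everything the mix can form — religations, concatemers, the works — and
the feature screen pins down the single 3,110-bp double-resistant clone
(2,984 + 126 bp), exactly what a transformation plus double selection
would isolate.

The same route runs as a recalculable workflow (`new_project()`,
`add_node()`, `execute_node()`, `recalculate_children()`): edit an upstream
primer or enzyme and every downstream product updates in topological order.

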