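# colligator

Discovering candidate regulatory small RNAs processed from noncoding
RNAs, by *triple colligation* of three independent lines of evidence:

1. **Sequencing abundance** — adapter/poly-A-trimmed small-RNA reads are
   collapsed to exact copies and clustered into shared **core
   sequences** of ≥ 16 nt, with a permutation-null control for the
   specificity of each core;
2. **Hairpin structure** — noncoding RNAs are scanned with sliding
   windows for stable stem-loops, scored by a nearest-neighbour
   free-energy model with the stability ratio −dG/L and the minimal
   folding free energy index MFEI = −dG/(G+C nucleotides);
3. **Target complementarity** — 3'UTRs are scanned for maximal exact
   reverse-complement blocks of each core, miRNA-style, with a
   seed-redundancy check against mature miRNAs.

A colligation record is emitted when one core sits inside a stable
hairpin of an ncRNA *and* has a reverse-complement site in the 3'UTR of
a protein complexed with that same ncRNA (via a user-supplied
ribonucleoprotein table) — the geometry of a feedback loop in which a
fragment of an RNA machine down-regulates a protein of that same
machine.  The motivating instance is the 16-nt fragment
`UUCGCGCUUUCCCCUG` of the spliceosomal snRNA RNU1 and the 3'UTR of the
splicing factor gene SFRS1.

The package is intended for bioinformaticians analysing small-RNA
sequencing libraries against curated ncRNA, 3'UTR and RNP-complex
tables.  A synthetic-data generator with planted ground truth makes
every stage testable offline.

## The statistics at the core

*Permutation null.*  The probability that none of `K` random k-mers
occurs in any of `M` random L-mers under a uniform base model is

    p_none(K, M, L, k) = (1 - 4^-k)^(K * M * (L - k + 1))

At `K = 1000, M = 1e6, L = 30, k = 16` this is **0.0304**: even by
chance one would usually see at least one shuffle, so an abundant
original whose 1000 shuffles are all absent is doubly distinctive.  A
Monte-Carlo companion validates the independence approximation.

*Hairpin scores.*  For a perfect stem-loop of span `L` with free energy
`dG`: stability ratio = `-dG/L`, MFEI = `-dG/n_GC` (G+C nucleotides),
with the identity `ratio * L = MFEI * n_GC`.  Energies are
nearest-neighbour sums over the published Turner 2004 constants shipped
as plain-text tables; externally computed energies can be substituted.

## Worked example

```r
library(colligator)

cfg <- simulation_config(rng_seed = 7L)   # planted-truth synthetic inputs
sim <- simulate_dataset(cfg)
res <- run_pipeline(sim$reads, sim$ncrna, sim$utr, sim$rnp_links)

attr(res$trimmed, "summary")
#>             reads_in             retained discarded_no_adapter
#>                 2000                  300                 1700
#>     discarded_length
#>                    0
```

Of 2000 reads, the 300 planted ones had an adapter anchor and a 16–29 nt
insert; the uniform-random background was discarded.  The retained
inserts collapse to a single core at its planted abundance:

```r
res$cores[, c("core_id", "sequence", "instance_count", "n_members")]
#>   core_id         sequence instance_count n_members
#> 1  core_1 UUCGCGCUUUCCCCUG            300         1
```

The ncRNA scan finds one stable hairpin — the planted 28-nt stem-loop,
12 pairs (8 C-G), ratio 0.74, MFEI 1.14:

```r
res$hairpins[, c("parent_id", "start", "end", "L", "n_stem_pairs",
                 "gc_pair_count", "dG", "stability_ratio", "mfei")]
#>   parent_id start end  L n_stem_pairs gc_pair_count    dG stability_ratio  mfei
#> 1    RNU1L1    23  50 28           12             8 -20.6            0.74  1.14
```

and the join links the core, the hairpin and the two planted 3'UTR
sites (11 and 9 nt) through the RNP table:

```r
res$records[, c("core_id", "ncrna_id", "protein_gene_id",
                "utr_start", "utr_end", "match_len", "core_side")]
#>   core_id ncrna_id protein_gene_id utr_start utr_end match_len core_side
#> 1  core_1   RNU1L1         SFRS1L1        51      61        11   3'-side
#> 2  core_1   RNU1L1         SFRS1L1       100     108         9   3'-side
```

The reconstruction of the core's source hairpin (loop = first 4 bases,
3' side = remaining 12, 5' side = strict reverse complement):

```r
h <- reconstruct_hairpin("UUCGCGCUUUCCCCUG")
h$sequence;  h$structure
#> [1] "CAGGGGAAAGCGUUCGCGCUUUCCCCUG"
#> [1] "((((((((((((....))))))))))))"
```

A command-line wrapper with the same stages (`simulate`, `trim`,
`cores`, `permtest`, `hairpins`, `targets`, `colligate`) is installed at
`system.file("scripts", "colligator", package = "colligator")`.

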