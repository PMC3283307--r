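# syntenyTeams

Unordered, gap-tolerant, paralog-aware conserved gene clusters across
multiple genomes — and synteny-based refinement of homologous families into
orthologous and paralogous subgroups.

## What it does

Comparative genomics often starts from a protein-family classification in
which orthologs (related by speciation) and paralogs (related by
duplication) are mixed.  Positional conservation can separate them: genes
that sit in a neighbourhood whose *content* is conserved across genomes are
likely orthologs, while copies outside any conserved neighbourhood are
likely paralogs.  `syntenyTeams` implements this idea for gene-order data:

* A **δ-segment** is a set of genes on one chromosome in which every pair is
  closer than δ positions; a family set induced exactly by such a segment on
  one chromosome is a **δ-subset**, the segment being its *witness*.
* A **δ-cluster** is a family set that is a δ-subset on ≥ 2 chromosomes,
  with the union of witnessing genes as its witness `S`.
* A **δ-synteny** is a maximal δ-cluster: clusters whose witnesses are fully
  covered by a strictly larger cluster are merged into it.
* A **δ-zone** agglomerates syntenies transitively whenever their witnesses
  share ≥ 2 genes (`|S_i ∩ S_j| ≥ 2`).
* A **weak bond** (`|S_i ∩ S_j| = 1`) is resolved against a total species
  order ≺ by divergence time: with `|S_i| > |S_j|` and `g = S_i ∩ S_j`, if
  `g` comes from the ≺-biggest species present in `S_j`, `S_i` witnesses the
  maximal *orthologous* synteny and `S_j \ {g}` a *paralogous* one.
* Per family, only the largest orthologous zone and the non-intersecting
  paralogous zones are kept; leftover members become singletons.

The scan is local: only the −δ..+δ neighbourhoods of family members are
examined with a sliding window of width δ (default δ = 7).  Unassigned genes
(`"*"`) occupy positions — they count toward distances — but never join a
family set.  The package also provides a brute-force oracle, a synthetic
generator with planted clusters, a split/merge comparator for two
classifications, and a command-line interface.

## Worked example

The weak-bond fixture: two chromosomes (each in its own species, with `c3`
diverged more recently than `c2`), scanned around family `f8` at δ = 3.

```r
library(syntenyTeams)
ex <- loadExample(6)
res <- synsRun(ex$genomes, delta = 3, focalFamilies = "f8")
res
#> SynsResult (delta = 3): 2 syntenies, 2 zones, 1 weak bonds
#> Zone (paralogous) {f2,f8}: 1 synteny(ies), 3 witness genes
#> Zone (orthologous) {f4,f8}: 1 synteny(ies), 6 witness genes
#> FamilyPartition: 7 families, 9 subgroups ( 6 ortholog / 3 paralog / 5 singleton gene rows )

weakBonds(res)[[1]]
#> WeakBond between {f2,f8} and {f4,f8}; witness gene (9,f8)c2

subset(partitionTable(res), family_id == "f8")
#>    family_id   subgroup_id subgroup_type gene_id species chromosome position
#> 10        f8     f8:ortho1      ortholog    c2:9      c2         c2        9
#> 11        f8     f8:ortho1      ortholog    c3:2      c3         c3        2
#> 12        f8     f8:ortho1      ortholog    c3:5      c3         c3        5
#> 13        f8      f8:para1       paralog    c3:8      c3         c3        8
#> 14        f8 f8:singleton1     singleton    c3:6      c3         c3        6
```

Reading this: the two syntenies `{f4,f8}` and `{f2,f8}` share exactly one
witness gene, `(9,f8)` on `c2` — a weak bond.  Because that gene lies in the
earliest-diverged species present in the smaller witness, the larger witness
defines the orthologous synteny; the copy of `f8` shared with `{f2,f8}` is
treated as a paralog and removed from the smaller witness.  Family `f8` is
accordingly split into an orthologous subgroup of three genes, a paralogous
subgroup of one, and one singleton that no conserved neighbourhood covers.

From the shell, the same run is:

```sh
Rscript inst/scripts/syns.R detect --genes genes.tsv \
    --species-order species_order.txt --delta 3 --families f8 --out out/
```

which writes `out/zones.tsv` and `out/partition.tsv` (see
`inst/scripts/syns.R --help`-style usage lines for `compare`, `simulate`
and `oracle`).

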