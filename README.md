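# xgaptab

Data management for genotype-to-phenotype experiments: an extensible
object model, a tab-delimited exchange format with full referential
validation, a transactional embedded store, and converters to the
formats QTL mappers actually use.

## Who this is for

Genetical-genomics studies (eQTL/mQTL/pQTL mapping on panels of
individuals or inbred strains) juggle marker annotations, probe
annotations, subject pedigrees, genotype matrices and molecular
phenotype matrices that must stay mutually consistent. `xgaptab` is for
the lab bioinformatician who needs to exchange, check and store such
investigations without a server deployment, and to customize the data
model when a new profiling technology arrives.

## The model in brief

Everything rests on four core types plus provenance:

* **Trait** — what is measured (a `Marker`, `Probe`, `Gene`,
  `Metabolite`, or classical phenotype);
* **Subject** — what it is measured on (`Individual`, `Strain`,
  `InbredStrain`, `Sample`, `PairedSample`);
* **Data** — a named matrix declaration (row type, column type, value
  type), with one *DataElement* per cell;
* **Investigation / Protocol / ProtocolApplication** — provenance,
  following the FuGE pattern.

Traits and subjects both extend **DimensionElement** (id, name, type),
so any matrix over any Trait/Subject combination is representable
without new cell types. Genomic traits implement the `Locus` interface
(`chromosome`, `bp_start`, `bp_end`, `cm`). New variants are added in a
few lines of a declarative model DSL; the bundle format, relational
schema and load order are all derived from the model
(`derive_format_spec()`, `derive_relational_schema()`, `load_order()`).

On disk, an investigation is an **XGAP-TAB bundle**: one tab-delimited
annotation file per entity (`marker.txt`, `probe.txt`,
`individual.txt`, ...), matrix files under `data/`, matrix declarations
in `data.txt`, constants in `constant.properties`, and raw files kept
verbatim under `original/` — as a directory or a zip.

## Worked example

Generate a deterministic synthetic investigation (30 recombinant inbred
strains × 100 markers × 200 expression probes, 10 true eQTL), validate
it, and load it into an embedded store:

```r
library(xgaptab)

b <- generate_investigation(synth_params(seed = 42))
b
#> <xg_bundle>
#>   records: Investigation(1) Protocol(3) ProtocolApplication(3) Data(2) Marker(100) Probe(200) OntologyTerm(1) DatabaseEntry(1) InbredStrain(30)
#>   matrix 'genotypes': 100 x 30 (text)
#>   matrix 'expressions': 200 x 30 (decimal)
#>   constants: species_name

validate_bundle(b)
#> <validation report> 0 error(s), 0 warning(s)

write_bundle(b, "my_study")          # or "my_study.zip"

s <- open_store("my_study.sqlite")
import_bundle(s, b)$records
#>       Investigation            Protocol ProtocolApplication                Data
#>                   1                   3                   3                   2
#>              Marker               Probe        InbredStrain        OntologyTerm
#>                 100                 200                  30                   1
#>       DatabaseEntry
#>                   1
```

Every cross-reference was checked before a single row was written (a
genotype matrix whose row names don't all match `marker.txt` is
rejected with located findings, and a failed import rolls back
completely). Queries span the inheritance hierarchy — markers and
probes both answer a `Trait` query:

```r
store_find(s, "Data", list(investigation_name = "synthetic_ggx"))[,
  c("name", "rowtype", "coltype", "valuetype")]
#>          name rowtype      coltype valuetype
#> 1   genotypes  Marker InbredStrain      text
#> 2 expressions   Probe InbredStrain   decimal

table(store_find(s, "Trait")$entity_class)
#> Marker  Probe
#>    100    200
```

Hand the genotypes and expression phenotypes to a QTL mapper as a cross
CSV (two map header rows: chromosome and cM under each marker column),
or pull PLINK-style files in:

```r
writeLines(to_rqtl(b, "genotypes", "expressions"), "cross.csv")
trio <- from_pedmap("trio.ped", "trio.map")
```

Extending the model for a new technology is a few lines of DSL; the
derived format gains `nmrbin.txt` and matrices typed `NmrBin` validate
and import with no further changes:

```r
m2 <- extend_model(builtin_model(),
  "entity NmrBin extends Trait
     ppm_low: decimal
     ppm_high: decimal")
```

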