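---
title: "Managing genotype and phenotype experiment data with xgaptab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Managing genotype and phenotype experiment data with xgaptab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xgaptab)
```

## The problem

Genetical-genomics studies — eQTL, mQTL, pQTL mapping — produce a small
zoo of tightly linked tables: subjects (individuals, strains, samples),
traits (markers, microarray probes, metabolites, classical phenotypes),
and data matrices connecting the two (genotype calls, expression
intensities, QTL statistics). Keeping these consistent across tools,
collaborators and profiling technologies is where most data-management
effort in such projects goes: a genotype matrix is worthless if its row
names silently drift out of sync with the marker annotation, and a
database that accepts half an investigation before failing is worse than
one that accepts none of it.

`xgaptab` implements the XGAP approach to this problem at library scale:
a deliberately minimal object model in which *everything measured* is a
`Trait`, *everything measured on* is a `Subject`, and every observation
is a cell of a `Data` matrix whose row and column names refer to those
records. Experimental provenance hangs off the same skeleton
(`Investigation`, `Protocol`, `ProtocolApplication`), and domain detail
enters only by *extending* `Trait` and `Subject` — never by inventing new
matrix types. A single uniform cell type avoids the combinatorial
explosion of "expression element", "mass-peak element", "QTL element"
variants while keeping every matrix a plain rectangle of numbers or
codes.

## The meta-model and its derivations

Everything the package does is derived from an explicit entity model: an
ordered set of entities, each with typed fields, single inheritance
(`extends`), interfaces (`implements`, used for cross-cutting field
bundles such as the genome-location interface `Locus`), and typed
references — `xref` for one-to-many, `mref` for many-to-many. Models are
written in a small line-oriented text syntax:

```{r dsl}
m <- parse_model("
entity Compound extends Trait
  mass: decimal
  formula: string
")
```

From a model the package derives, deterministically:

* the **bundle format** (`derive_format_spec()`): one tab-delimited
  annotation file per concrete entity, named by the lowercased entity
  name, with columns equal to the entity's *flattened* fields — all
  ancestors' fields root-first, then interface fields, then the entity's
  own. Interfaces get no file.
* the **relational schema** (`derive_relational_schema()`): one table per
  concrete entity with primary key `molgenisid`; a subclass row implies a
  superclass row under the same key (so a `Gene` occupies rows in
  `gene`, `trait` and `dimensionelement`); `xref` fields become integer
  foreign keys and each `mref` field becomes a two-foreign-key link
  table. `schema_ddl()` renders this as SQLite DDL.
* the **load order** (`load_order()`): a topological order over the
  reference graph so every referenced record is inserted before its
  referers. Edges that cannot be ordered — self-references such as
  `Individual.mother`, or reference cycles — are returned as *deferred*
  and are written as missing in a first pass and patched in a second.
  Deferred edges are exactly the reference edges lying on cycles
  (computed via strongly connected components); mref links always
  resolve in the second pass.

The internal record id deserves a note: annotation files carry no id
column. The record **name** is the business key of the tab format
(unique per concrete entity per investigation), and the numeric
`molgenisid` exists only in the relational mapping, where shared-key
inheritance needs it.

Field order in derived artifacts is ancestry-then-declaration order.
That choice is arbitrary in principle (nothing downstream depends on
column order, since files are read by header name); it is fixed so that
the canonical writer is deterministic.

## The bundle format

A bundle is one investigation on disk: annotation files, matrix files
under `data/`, matrix declarations in `data.txt` (columns `name`,
`investigation_name`, `rowtype`, `coltype`, `valuetype`), constants in
`constant.properties`, and raw instrument output preserved unparsed
under `original/`. The dialect is UTF-8, tab-delimited, LF-terminated,
no quoting; in-cell tab, newline and backslash are escaped `\t`, `\n`,
`\\`; an empty cell is a missing value (the token `NA` is additionally
accepted in lax mode, never emitted). Matrix `valuetype` is `decimal` or
`text` — genotype codes are *data*, not schema, so a two-letter genotype
alphabet needs no model change.

Decimals are serialized with the shortest representation that parses
back to the identical double, which gives the central format guarantee:
**write → read → write is byte-identical**. The writer always emits the
canonical form — entities in load order, records in input order, matrix
rows and columns in annotation-file order, constants sorted — so
canonical bytes are also a meaningful equality test between bundles
(`bundle_equal()`). Zip archives are first-class: reading uses R's
built-in extraction, and writing embeds a small deterministic ZIP writer
(deflate payloads via `memCompress()`, fixed timestamps) so archives of
equal content are equal files.

## Validation

`validate_bundle()` is the gatekeeper that keeps orphaned data out of
the store. It checks, deterministically and exhaustively: required
fields; value types (`int`, `decimal`, `bool`, `date`); name uniqueness
per concrete entity and investigation; resolution of every `xref`, every
`mref` member and every annotation target (against the bundle plus,
optionally, an open store); agreement between declared and present
matrices; matrix dimension names against records of the declared
row/column type; and declared matrix value types cell by cell. Findings
are data (severity, kind, location, message), not exceptions; a bundle
is valid iff it has no error-severity findings, and warnings (such as
`bp_start > bp_end`) never block.

Two finding kinds are deliberately distinct: `unresolved_reference` is a
*field value* that resolves nowhere, while `matrix_name_mismatch` is a
*matrix dimension name* with no matching record. Both are failures of
the same linkage discipline, but they live in different places and are
repaired differently, so they are reported differently.

The defect injector (`corrupt_bundle()`) exists to test this validator
honestly: it plants a requested number of defects of requested kinds and
returns exact ground truth. Each kind draws from its own pool of
corruption sites, chosen so that a defect yields exactly one finding and
defects cannot mask one another — duplicates are injected by *appending*
a copy of a record (renaming one would also orphan matrix rows),
unresolved references rewrite investigation links that nothing else
depends on, and required-field blanking avoids fields whose dependent
checks would then skip other injected defects. This makes
"validator findings = injected defects, one-to-one by kind and location"
a meaningful property rather than a fuzzy count.

## The store

The store realizes the derived relational schema in a single SQLite
file with engine-enforced foreign keys. Matrix cells are not spread
over per-technology tables; they live in one `dataelement` relation
(data id, row index, column index, row element, column element, value),
one row per cell, which preserves the uniform-cell philosophy at the
storage layer and makes "number of persisted cells = rows × columns"
directly checkable. Bundle constants go to a `bundle_constant` table
keyed by investigation.

`import_bundle()` validates first, then inserts in load order inside a
savepoint, patches deferred references and mref links in a second pass,
persists matrices and constants, and releases — or rolls back to the
exact pre-call state on any failure. Because validation precedes
insertion, a corrupt matrix aborts the import before any row is written;
the savepoint additionally guards against constraint violations during
insertion itself. `store_add()` is all-or-nothing per call and uses
batched parameter binding, so inserting tens of thousands of records is
a single round trip per table. `store_find()` queries an entity *and its
subtypes* (a `Gene` answers a `Trait` query), returning flattened fields
with references resolved back to names. Reference scope is
per-investigation by name; cross-investigation references are not
resolved.

Export (`export_investigation()`) reassembles one investigation's
records, matrices and constants into a bundle; import-then-export
returns the canonical form of the input. Files under `original/` are
carried by bundles on disk but are not persisted in the store —
round-trip fidelity through the store is defined over records, matrices
and constants.

## Converters

`to_rqtl()`/`from_rqtl()` speak the single-file cross CSV layout:
individuals as rows, an `id` column, phenotype columns, then one column
per marker with two extra header rows carrying chromosome and cM
position. The genotype code map defaults to `AA→A`, `AB/BA→H`, `BB→B`
with single-letter codes passing through unchanged and `-` for missing;
the import inverse prefers fixed points, so codes the exporter emits
recode losslessly and unmappable codes fail loudly. `from_pedmap()`
builds a bundle from PLINK-style PED/MAP files, storing genotypes as
unphased `a1/a2` text (no information-losing numeric recoding at
import), marker map positions in the `Locus` fields, pedigree links as
deferred `mother`/`father` references, and PED family/sex columns as
free-text `Description` annotations rather than schema fields.

## The synthetic generator

`generate_investigation()` produces the test and demonstration workload:
a complete, valid, deterministic investigation in the canonical
genetical-genomics shape. Defaults are the classic small recombinant
inbred panel — 30 subjects, 100 markers on 5 chromosomes of 100 cM, 200
probes, 10 true eQTL of 2 expression units, unit Gaussian noise.
Genotypes use a two-state homozygote alphabet (A/B, RIL-like) simulated
as a Markov chain along each chromosome with recombination probability
between adjacent markers given by the Haldane map function
$r = \tfrac12\,(1 - e^{-2d/100})$ for spacing $d$ cM — no crossover
interference. Marker bp positions assume 1 cM ≈ 1 Mb. Expression is a
per-probe baseline (Normal(8, 1), a log2-intensity scale) plus the QTL
shift for B-allele carriers plus noise. The same seed yields a
byte-identical written bundle.

What the generator does *not* emulate: linkage disequilibrium beyond
the marker chain, population structure, heterozygosity, dominance,
epistasis, intensity-dependent microarray noise. Tests passing on this
workload therefore demonstrate the correctness of the data machinery —
formats, validation, transactions, conversions — not robustness to the
full messiness of real intensity data.

### Calibration checks and multiplicity

Calibration is asserted at 1,000 subjects: each marker's allele
frequency must lie within 3 binomial standard errors of ½, and the
adjacent-marker recombination fraction must match the Haldane
expectation within 3 standard errors. For the recombination check the
*pooled* fraction across adjacent pairs is tested (all pairs share one
spacing by construction, so they estimate a single $r$; the pooled
standard error is $\sqrt{r(1-r)/(n_{\text{pairs}} \cdot
n_{\text{subjects}})}$). Requiring every one of ~95 pair-level
fractions to sit within 3 SE simultaneously would reject a perfectly
calibrated simulator roughly 40% of the time — a multiplicity artifact,
not a statement about calibration — so the per-pair form is deliberately
not used.

## Problem sizes

The test suite runs the full pipeline at the reference shape (30 × 100
× 200, seed 42) for round trips, import/export fidelity, rollback and
defect injection; load-order properties over 100 random models of up to
8 entities; batched adds at 10,000 records; and calibration at 1,000
subjects × 100 markers. These sizes exercise every code path at the
scale the format targets (desk-scale investigations) while keeping the
suite fast.

## Known limitations

* One writer at a time: the store is an embedded single-file database
  with no concurrency story, by design.
* Reference resolution is name-based within an investigation; bundles
  holding several investigations with colliding record names are not
  supported.
* `store_update()` does not edit mref link sets.
* The cross CSV reader accepts only the layout the writer emits (no
  `csvr`/`csvs` rotations, no quoting).
* Model identifiers are ASCII-ish (`[A-Za-z_][A-Za-z0-9_]*`); two
  entities whose names differ only by case would collide at the file
  and table level and are rejected in practice.
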