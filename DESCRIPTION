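Package: xgaptab
Title: Extensible Genotype and Phenotype Data Bundles, Validation and Storage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for managing genotype and phenotype experiment data as
    XGAP-TAB bundles: a minimal, extensible entity meta-model with a
    declarative text syntax, the built-in XGAP object model (Investigation,
    Protocol, Data, Trait and Subject variants such as Marker, Probe, Gene,
    Metabolite, Sample, Individual, Strain), a tab-delimited bundle format
    with full referential validation, a transactional dependency-ordered
    import/export engine over an embedded SQLite store, converters to and
    from R/qtl cross CSV and PED/MAP genotype files, and a deterministic
    synthetic genetical-genomics data generator with defect injection for
    testing validators and importers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    DBI,
    RSQLite,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
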