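# Entity meta-model: DSL parsing, flattening, derivations, load order.

test_that("the model DSL parses entities, inheritance and references", {
  m <- parse_model("
entity Trait
  name: string, required

entity Metabolite extends Trait
  mass: decimal
  formula: string
  structure: text

entity Data
  name: string

entity ProtocolApplication
  inputdata: mref -> Data
")
  met <- m$entities$Metabolite
  expect_identical(met$extends, "Trait")
  expect_named(met$fields, c("mass", "formula", "structure"))
  expect_identical(met$fields$mass$valuetype, "decimal")
  f <- m$entities$ProtocolApplication$fields$inputdata
  expect_identical(f$valuetype, "mref")
  expect_identical(f$target_entity, "Data")
  # declaration order preserved
  expect_identical(names(m$entities),
                   c("Trait", "Metabolite", "Data", "ProtocolApplication"))
})

test_that("an empty document yields a model with zero entities", {
  expect_length(parse_model("")$entities, 0)
  expect_length(parse_model("# only a comment\n")$entities, 0)
})

test_that("malformed models are rejected with located errors", {
  expect_error(parse_model("entity A\n  bad field line"), "line 2")
  expect_error(parse_model("entity A extends Nope\n  name: string"),
               "unknown entity 'Nope'")
  expect_error(parse_model("entity A\n  r: xref -> Nope"), "Nope")
  expect_error(parse_model(
    "entity A extends B\n  name: string\nentity B extends A\n  id: string"),
    "cycle")
  expect_error(parse_model("entity A\n  x: nonsense"), "valuetype")
  expect_error(parse_model("entity A\n  name: xref"), "target")
  expect_error(
    parse_model("entity A implements B\n  name: string\nentity B"),
    "non-interface")
})

test_that("serializing and reparsing a model is the identity", {
  m <- builtin_model()
  expect_identical(parse_model(write_model(m)), m)
  for (seed in 1:5) {
    rm_ <- random_model(6, seed)
    expect_identical(parse_model(write_model(rm_)), rm_)
  }
})

test_that("flatten_fields puts root-ancestor fields first and own last", {
  m <- builtin_model()
  ff <- names(flatten_fields(m, "Metabolite"))
  expect_identical(ff, c("name", "type", "investigation_name",
                         "mass", "formula", "structure"))
  # entity with no parent: own fields unchanged
  expect_identical(names(flatten_fields(m, "Investigation")),
                   c("name", "description"))
})

test_that("flattening matches a brute-force ancestry walk, incl. diamonds", {
  m <- builtin_model()
  for (e in concrete_entities(m))
    expect_identical(names(flatten_fields(m, e)),
                     oracle_flatten_names(m, e), info = e)
  # diamond: extends chain and interface sharing a field name
  dm <- parse_model("
interface Locatable
  chromosome: text
  note: string

entity Base
  name: string
  note: string

entity Mid extends Base implements Locatable
  extra: int

entity Leaf extends Mid
  chromosome: text
  own: decimal
")
  expect_identical(names(flatten_fields(dm, "Leaf")),
                   oracle_flatten_names(dm, "Leaf"))
  # no duplicates ever
  for (e in names(dm$entities))
    expect_false(anyDuplicated(names(flatten_fields(dm, e))) > 0)
})

test_that("format spec covers concrete entities only, monotonically", {
  m <- builtin_model()
  fs <- derive_format_spec(m)
  expect_true(all(c("probe.txt", "individual.txt", "data.txt") %in%
                    vapply(fs$files, `[[`, character(1), "file")))
  expect_false("Locus" %in% names(fs$files))
  expect_identical(fs$files$Probe$columns,
                   names(flatten_fields(m, "Probe")))
  # monotone under extension: existing entries unchanged, new entry added
  m2 <- extend_model(m, "entity NmrBin extends Trait\n  ppm_low: decimal\n  ppm_high: decimal")
  fs2 <- derive_format_spec(m2)
  for (nm in names(fs$files))
    expect_identical(fs2$files[[nm]], fs$files[[nm]])
  expect_identical(fs2$files$NmrBin$file, "nmrbin.txt")
  # interface-only model: no files
  fs3 <- derive_format_spec(parse_model("interface I\n  x: string"))
  expect_length(fs3$files, 0)
})

test_that("relational schema maps inheritance, xrefs and mrefs", {
  m <- builtin_model()
  rs <- derive_relational_schema(m)
  # Gene extends Trait extends DimensionElement: 3 tables share the key
  expect_true(all(c("gene", "trait", "dimensionelement") %in%
                    names(rs$tables)))
  expect_identical(rs$tables$gene$parent, "trait")
  expect_identical(rs$tables$trait$parent, "dimensionelement")
  expect_identical(rs$tables$gene$primary_key, "molgenisid")
  # mref link tables: one per mref field in the model
  n_mref <- sum(vapply(concrete_entities(m), function(e)
    length(mrefs <- Filter(function(f) f$valuetype == "mref",
                           m$entities[[e]]$fields)), integer(1)))
  expect_identical(length(rs$link_tables), n_mref)
  lt <- rs$link_tables$mref_protocolapplication_inputdata
  expect_identical(lt$references, c("protocolapplication", "data"))
  # entity with no relations: single table, no foreign keys
  rs1 <- derive_relational_schema(parse_model("entity Solo\n  name: string"))
  expect_length(rs1$tables, 1)
  expect_length(rs1$tables$solo$foreign_keys, 0)
  expect_length(rs1$link_tables, 0)
  # DDL mentions each table once
  ddl <- schema_ddl(rs)
  expect_identical(length(gregexpr("CREATE TABLE", ddl)[[1]]),
                   length(rs$tables) + length(rs$link_tables))
})

test_that("load order puts referenced entities first and defers cycles", {
  m <- builtin_model()
  lo <- load_order(m)
  expect_lt(match("Investigation", lo$order), match("Data", lo$order))
  expect_lt(match("Trait", lo$order), match("Gene", lo$order))
  def <- lo$deferred
  expect_true(all(c("mother", "father") %in%
                    def$field[def$entity == "Individual"]))
  # single entity, no relations
  lo1 <- load_order(parse_model("entity Solo\n  name: string"))
  expect_identical(lo1$order, "Solo")
  expect_identical(nrow(lo1$deferred), 0L)
})

test_that("load order satisfies every non-deferred edge on random models", {
  for (seed in 1:30) {
    mdl <- random_model(sample(2:8, 1), seed)
    lo <- load_order(mdl)
    edges <- oracle_model_edges(mdl)
    pos <- match(names(mdl$entities), lo$order)
    names(pos) <- names(mdl$entities)
    for (i in seq_len(nrow(edges))) {
      deferred <- edges$field[i] != "extends" &&
        any(lo$deferred$entity == edges$to[i] &
              lo$deferred$field == edges$field[i])
      if (!deferred)
        expect_lte(pos[edges$from[i]], pos[edges$to[i]] -
                     as.integer(edges$from[i] != edges$to[i]))
      # deferred edges are exactly those on cycles
      if (edges$field[i] != "extends") {
        on_cycle <- oracle_reachable(edges, edges$to[i], edges$from[i])
        expect_identical(deferred, on_cycle,
                         info = sprintf("seed %d edge %s.%s", seed,
                                        edges$to[i], edges$field[i]))
      }
    }
  }
})
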