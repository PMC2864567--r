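# Embedded store: import, export, find/add/update/remove, transactions.

test_that("import persists all records and matrices with correct counts", {
  s <- open_store(":memory:")
  on.exit(close_store(s))
  b <- small_synth()
  sm <- import_bundle(s, b)
  expect_identical(sm$records[["Marker"]], 20L)
  expect_identical(sm$records[["Probe"]], 15L)
  expect_identical(sm$records[["InbredStrain"]], 10L)
  expect_identical(sm$records[["Data"]], 2L)
  expect_identical(sm$matrices, 2L)
  # matrix conservation: one stored cell per matrix cell
  expect_identical(sm$cells, 20L * 10L + 15L * 10L)
  per_data <- DBI::dbGetQuery(s$con,
    "SELECT data, COUNT(*) AS n FROM dataelement GROUP BY data")
  expect_setequal(per_data$n, c(200L, 150L))
})

test_that("importing an empty bundle changes nothing", {
  s <- open_store(":memory:")
  on.exit(close_store(s))
  snap <- store_snapshot(s)
  sm <- import_bundle(s, xg_bundle())
  expect_identical(sum(sm$records), 0L)
  expect_identical(store_snapshot(s), snap)
})

test_that("a corrupted bundle leaves the store bit-identical", {
  s <- open_store(":memory:")
  on.exit(close_store(s))
  import_bundle(s, small_synth(seed = 1))
  snap <- store_snapshot(s)
  b <- small_synth(seed = 2)
  b2 <- rename_investigation(b, "second")
  # corrupt the last-loaded matrix (expressions): non-numeric cell
  v <- b2$matrices$expressions$values
  storage.mode(v) <- "character"
  v[nrow(v), 1] <- "garbage"
  b2$matrices$expressions <- data_matrix("expressions", v, "text")
  err <- tryCatch(import_bundle(s, b2), error = function(e) e)
  expect_s3_class(err, "xg_validation_error")
  expect_match(conditionMessage(err), "expressions")
  expect_identical(store_snapshot(s), snap)
})

test_that("exports cover exactly one investigation", {
  s <- open_store(":memory:")
  on.exit(close_store(s))
  m <- builtin_model()
  b1 <- small_synth(seed = 1)
  b2 <- rename_investigation(small_synth(seed = 2), "other_study")
  import_bundle(s, b1)
  import_bundle(s, b2)
  e1 <- export_investigation(s, "synthetic_ggx")
  e2 <- export_investigation(s, "other_study")
  expect_true(bundle_equal(b1, e1, m, ignore_original = TRUE))
  expect_true(bundle_equal(b2, e2, m, ignore_original = TRUE))
  expect_false("other_study" %in% e1$records$Investigation$name)
  expect_identical(nrow(e1$records$Marker), 20L)
  expect_error(export_investigation(s, "nope"), "unknown investigation")
})

test_that("exporting an empty investigation yields just its record", {
  s <- open_store(":memory:")
  on.exit(close_store(s))
  import_bundle(s, xg_bundle(records = list(
    Investigation = data.frame(name = "bare", description = NA,
                               stringsAsFactors = FALSE))))
  e <- export_investigation(s, "bare")
  expect_identical(names(e$records), "Investigation")
  expect_length(e$matrices, 0)
})

test_that("find filters records and spans the inheritance hierarchy", {
  s <- open_store(":memory:")
  on.exit(close_store(s))
  import_bundle(s, small_synth())
  d <- store_find(s, "Data", list(investigation_name = "synthetic_ggx"))
  expect_identical(nrow(d), 2L)
  expect_setequal(d$name, c("genotypes", "expressions"))
  # supertype queries return subtype records
  tr <- store_find(s, "Trait")
  expect_identical(nrow(tr), 35L)  # 20 markers + 15 probes
  expect_setequal(unique(tr$entity_class), c("Marker", "Probe"))
  expect_identical(nrow(store_find(s, "DimensionElement")), 45L)
  expect_identical(nrow(store_find(s, "Marker", list(name = "m01"))), 1L)
  expect_identical(nrow(store_find(s, "Marker",
                                   list(name = "no_such"))), 0L)
  expect_error(store_find(s, "Marker", list(bogus = "x")), "bogus")
  expect_error(store_find(s, "NoEntity"), "unknown entity")
})

test_that("subtype table keys are a subset of supertype table keys", {
  s <- open_store(":memory:")
  on.exit(close_store(s))
  import_bundle(s, small_synth())
  q <- function(sql) DBI::dbGetQuery(s$con, sql)
  for (pair in list(c("marker", "trait"), c("trait", "dimensionelement"),
                    c("inbredstrain", "strain"),
                    c("strain", "subject"))) {
    expect_lte(q(paste0("SELECT COUNT(*) n FROM ", pair[1]))$n,
               q(paste0("SELECT COUNT(*) n FROM ", pair[2]))$n)
    orphans <- q(sprintf(
      "SELECT COUNT(*) n FROM %s a LEFT JOIN %s b USING (molgenisid)
       WHERE b.molgenisid IS NULL", pair[1], pair[2]))$n
    expect_identical(orphans, 0L)
  }
  # referential closure: every foreign key resolves
  fk <- q("PRAGMA foreign_key_check")
  expect_identical(nrow(fk), 0L)
})

test_that("adds are batched and all-or-nothing", {
  s <- open_store(":memory:")
  on.exit(close_store(s))
  import_bundle(s, xg_bundle(records = list(
    Investigation = data.frame(name = "big", description = NA,
                               stringsAsFactors = FALSE))))
  n <- 10000L
  mk <- data.frame(name = sprintf("mk%05d", seq_len(n)),
                   type = NA_character_, investigation_name = "big",
                   chromosome = "1",
                   bp_start = as.character(seq_len(n)),
                   bp_end = as.character(seq_len(n)),
                   cm = NA_character_, stringsAsFactors = FALSE)
  t0 <- Sys.time()
  store_add(s, "Marker", mk)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 30)
  expect_identical(nrow(store_find(s, "Marker")), n)
  # one bad record in a batch of 100: zero rows added
  bad <- data.frame(name = sprintf("x%03d", 1:100),
                    type = NA_character_,
                    investigation_name = c(rep("big", 57), "ghost",
                                           rep("big", 42)),
                    stringsAsFactors = FALSE)
  expect_error(store_add(s, "Gene", bad), "ghost")
  expect_identical(nrow(store_find(s, "Gene")), 0L)
})

test_that("update matches by name and refuses unknown records", {
  s <- open_store(":memory:")
  on.exit(close_store(s))
  import_bundle(s, tiny_bundle())
  store_update(s, "Probe", data.frame(name = "p1", sequence = "GGGG",
                                      stringsAsFactors = FALSE))
  p <- store_find(s, "Probe", list(name = "p1"))
  expect_identical(p$sequence, "GGGG")
  expect_error(store_update(s, "Probe",
                            data.frame(name = "none",
                                       sequence = "A",
                                       stringsAsFactors = FALSE)),
               "no existing")
})

test_that("remove refuses to orphan referencing records", {
  s <- open_store(":memory:")
  on.exit(close_store(s))
  import_bundle(s, tiny_bundle())
  # markers are referenced by matrix cells: removal must fail cleanly
  expect_error(store_remove(s, "Marker", "m1"))
  expect_identical(nrow(store_find(s, "Marker")), 2L)
})

test_that("transactions commit durably and roll back completely", {
  path <- tempfile(fileext = ".sqlite")
  s <- open_store(path)
  import_bundle(s, tiny_bundle())
  snap <- store_snapshot(s)
  store_begin(s)
  expect_error(store_begin(s), "already active")
  store_add(s, "Gene", data.frame(name = "g1",
                                  investigation_name = "inv1",
                                  stringsAsFactors = FALSE))
  store_rollback(s)
  expect_identical(store_snapshot(s), snap)
  expect_error(store_rollback(s), "no active")
  expect_error(store_commit(s), "no active")
  store_begin(s)
  store_add(s, "Gene", data.frame(name = "g2",
                                  investigation_name = "inv1",
                                  stringsAsFactors = FALSE))
  store_commit(s)
  close_store(s)
  s2 <- open_store(path)
  expect_identical(store_find(s2, "Gene")$name, "g2")
  close_store(s2)
  unlink(path)
})

test_that("mid-import failures inside a transaction leave no partial rows", {
  s <- open_store(":memory:")
  on.exit(close_store(s))
  snap <- store_snapshot(s)
  # bypass validation to force a failure during insertion itself:
  # an mref member that resolves nowhere blows up in the link pass
  b <- tiny_bundle()
  b$records$ProtocolApplication <- data.frame(
    name = "pa1", investigation_name = "inv1", protocol = NA_character_,
    inputdata = "expressions", outputdata = NA_character_,
    stringsAsFactors = FALSE)
  bad <- b
  bad$records$ProtocolApplication$inputdata <- "nonexistent_data"
  v <- validate_bundle(bad)  # validation does catch it...
  expect_false(is_valid(v))
  # ...so drive the insert path directly to prove the savepoint works
  expect_error(
    xgaptab:::with_savepoint(s, "forced", {
      DBI::dbExecute(s$con,
        "INSERT INTO investigation (molgenisid, entity_class, name)
         VALUES (1, 'Investigation', 'tmp')")
      stop("forced failure")
    }),
    "forced failure")
  expect_identical(store_snapshot(s), snap)
})
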