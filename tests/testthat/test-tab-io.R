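# XGAP-TAB dialect: entity files, matrix files, whole bundles.

test_that("entity files round-trip records, incl. awkward cells", {
  cols <- c("name", "type", "sequence")
  recs <- data.frame(name = c("p1", "p2"),
                     type = c(NA_character_, "probe"),
                     sequence = c("AC\tGT", "line1\nline2\\x"),
                     stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".txt")
  write_entity_file(recs, cols, path)
  expect_length(readLines(path), 3)  # header + 2 records
  back <- read_entity_file(path, cols)
  expect_identical(back, recs)
})

test_that("a header-only file reads as zero records", {
  path <- tempfile()
  write_entity_file(data.frame(name = character(),
                               stringsAsFactors = FALSE),
                    c("name", "type"), path)
  back <- read_entity_file(path, c("name", "type"))
  expect_identical(nrow(back), 0L)
  expect_named(back, c("name", "type"))
})

test_that("ragged rows, unknown and missing columns are located errors", {
  path <- tempfile()
  writeLines(c("name\ttype", "a\tx", "b"), path)
  expect_error(read_entity_file(path, c("name", "type")), "line 3")
  writeLines(c("name\tbogus", "a\tx"), path)
  expect_error(read_entity_file(path, c("name", "type")), "bogus")
  expect_warning(
    lax <- read_entity_file(path, c("name", "type"), lax = TRUE),
    "bogus")
  expect_identical(lax$name, "a")
  expect_true(is.na(lax$type[1]))
  writeLines(c("type", "x"), path)
  expect_error(read_entity_file(path, c("name", "type"),
                                required = "name"), "name")
})

test_that("matrix files round-trip decimal and text payloads exactly", {
  set.seed(1)
  v <- matrix(rnorm(20), 5, 4,
              dimnames = list(paste0("r", 1:5), paste0("c", 1:4)))
  v[2, 3] <- NA
  v[1, 1] <- 1 / 3
  v[5, 4] <- 1e-300
  m <- data_matrix("dm", v, "decimal")
  path <- tempfile()
  write_matrix(m, path)
  back <- read_matrix(path, valuetype = "decimal")
  expect_identical(back$values, m$values)
  g <- matrix(sample(c("A", "B", "H", NA), 12, replace = TRUE), 3, 4,
              dimnames = list(paste0("m", 1:3), paste0("i", 1:4)))
  gm <- data_matrix("g", g, "text")
  write_matrix(gm, path)
  expect_identical(read_matrix(path, valuetype = "text")$values, g)
  # 1x1 and 0x0 (corner cell only)
  one <- data_matrix("one", matrix(2.5, 1, 1,
                                   dimnames = list("r", "c")), "decimal")
  write_matrix(one, path)
  expect_identical(read_matrix(path, valuetype = "decimal")$values,
                   one$values)
  writeLines("", path)
  empty <- read_matrix(path, valuetype = "decimal")
  expect_identical(dim(empty$values), c(0L, 0L))
})

test_that("matrix defects are rejected with their location", {
  path <- tempfile()
  writeLines(c("\ti1\ti2", "m1\t1.5\tabc"), path)
  err <- tryCatch(read_matrix(path, valuetype = "decimal"),
                  error = conditionMessage)
  expect_match(err, "abc")
  expect_match(err, "m1")
  expect_match(err, "i2")
  writeLines(c("\ti1\ti2", "m1\t1\t2", "m1\t3\t4"), path)
  expect_error(read_matrix(path, valuetype = "text"), "duplicate row")
  writeLines(c("\ti1\ti1", "m1\t1\t2"), path)
  expect_error(read_matrix(path, valuetype = "text"), "duplicate column")
  writeLines(c("\ti1\ti2", "m1\t1"), path)
  expect_error(read_matrix(path, valuetype = "text"), "ragged")
})

test_that("a bundle survives write -> read -> write byte-identically", {
  m <- builtin_model()
  b <- tiny_bundle()
  d1 <- tempfile(); d2 <- tempfile()
  write_bundle(b, d1, m)
  expect_true(file.exists(file.path(d1, "probe.txt")))
  expect_true(file.exists(file.path(d1, "data", "expressions.txt")))
  expect_true(file.exists(file.path(d1, "constant.properties")))
  b2 <- read_bundle(d1, m)
  expect_true(bundle_equal(b, b2, m))
  write_bundle(b2, d2, m)
  expect_dirs_identical(d1, d2)
  # original/ files pass through untouched, unparsed
  expect_identical(b2$original_files[["raw/chip1.cel.txt"]],
                   charToRaw("raw bytes"))
})

test_that("zip and directory forms of a bundle read equally", {
  m <- builtin_model()
  b <- tiny_bundle()
  d <- tempfile(); z <- tempfile(fileext = ".zip")
  write_bundle(b, d, m)
  write_bundle(b, z, m, zip = TRUE)
  expect_true(bundle_equal(read_bundle(d, m), read_bundle(z, m), m))
})

test_that("an empty directory reads as an empty bundle", {
  d <- tempfile(); dir.create(d)
  b <- read_bundle(d, builtin_model())
  expect_length(b$records, 0)
  expect_length(b$matrices, 0)
  expect_length(b$constants, 0)
})

test_that("matrix declarations and files must agree on read", {
  m <- builtin_model()
  b <- tiny_bundle()
  d <- tempfile()
  write_bundle(b, d, m)
  file.remove(file.path(d, "data", "expressions.txt"))
  expect_error(read_bundle(d, m), "expressions")
  lx <- read_bundle(d, m, lax = TRUE)
  expect_false("expressions" %in% names(lx$matrices))
  # undeclared matrix file
  d2 <- tempfile()
  write_bundle(b, d2, m)
  write_matrix(data_matrix("stray",
                           matrix("x", 1, 1, dimnames = list("r", "c")),
                           "text"),
               file.path(d2, "data", "stray.txt"))
  expect_error(read_bundle(d2, m), "stray")
  lx2 <- read_bundle(d2, m, lax = TRUE)
  expect_true("stray" %in% names(lx2$matrices))
})

test_that("constants parse as key=value properties", {
  p <- tempfile()
  writeLines(c("# comment", "species_name=Mus musculus",
               "panel = BXD "), p)
  k <- xgaptab:::read_constants(p)
  expect_identical(k[["species_name"]], "Mus musculus")
  expect_identical(k[["panel"]], "BXD")
})
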