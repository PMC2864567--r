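# Cross-format conversion: R/qtl cross CSV and PED/MAP.

test_that("the cross CSV carries map header rows under the marker names", {
  b <- generate_investigation(synth_params(
    n_subjects = 4, n_markers = 3, n_chromosomes = 1, n_probes = 2,
    n_qtl = 1, seed = 5))
  csv <- to_rqtl(b, "genotypes", "expressions")
  rows <- strsplit(csv, ",", fixed = TRUE)
  # field-by-field assembly: header, chr row, cM row, then individuals
  expect_identical(rows[[1]], c("id", "p01", "p02", "m01", "m02", "m03"))
  mk <- b$records$Marker
  expect_identical(rows[[2]], c("", "", "", mk$chromosome))
  expect_identical(rows[[3]], c("", "", "", mk$cm))
  expect_length(csv, 3 + 4)
  g <- b$matrices$genotypes$values
  for (i in 1:4) {
    r <- rows[[3 + i]]
    expect_identical(r[1], colnames(g)[i])
    expect_identical(r[4:6], unname(g[, i]))  # A/B pass through the map
  }
})

test_that("a bundle without phenotypes yields a genotype-only CSV", {
  b <- small_synth()
  csv <- to_rqtl(b, "genotypes")
  expect_identical(strsplit(csv[1], ",")[[1]],
                   c("id", b$records$Marker$name))
})

test_that("XGAP -> R/qtl -> XGAP preserves genotypes and the marker map", {
  m <- builtin_model()
  b <- small_synth()
  csv <- to_rqtl(b, "genotypes", "expressions")
  b2 <- from_rqtl(csv, "synthetic_ggx")
  expect_bundle_valid(b2)
  expect_identical(b2$matrices$genotypes$values,
                   b$matrices$genotypes$values)
  mk1 <- b$records$Marker; mk2 <- b2$records$Marker
  expect_identical(mk2$name, mk1$name)
  expect_identical(mk2$chromosome, mk1$chromosome)
  expect_identical(mk2$cm, mk1$cm)
  # and the expression phenotypes survive numerically
  expect_equal(b2$matrices$phenotypes$values,
               b$matrices$expressions$values, tolerance = 0)
})

test_that("missing genotypes and single individuals are handled", {
  csv <- c("id,m1,m2", ",1,1", ",0,7.5", "only_one,A,-")
  b <- from_rqtl(csv, "mini")
  expect_identical(nrow(b$records$Individual), 1L)
  g <- b$matrices$genotypes$values
  expect_identical(g["m1", "only_one"], "A")
  expect_true(is.na(g["m2", "only_one"]))
  expect_bundle_valid(b)
})

test_that("markers without a map position refuse to export", {
  b <- small_synth()
  b$records$Marker$cm[3] <- NA_character_
  expect_error(to_rqtl(b, "genotypes"), "cM")
  b2 <- small_synth()
  g <- b2$matrices$genotypes$values
  g[1, 1] <- "Z"
  b2$matrices$genotypes <- data_matrix("genotypes", g, "text")
  expect_error(to_rqtl(b2, "genotypes"), "unmappable")
})

test_that("diplotype codes recode through the default map and back", {
  cm <- genotype_code_map()
  expect_identical(unname(cm$forward[c("AA", "AB", "BA", "BB")]),
                   c("A", "H", "H", "B"))
  v <- c("AA", "AB", "BB", NA)
  out <- xgaptab:::recode_forward(v, cm)
  expect_identical(out, c("A", "H", "B", "-"))
  back <- xgaptab:::recode_inverse(out, cm)
  # the inverse is a right inverse for emitted codes
  expect_identical(xgaptab:::recode_forward(back, cm),
                   c("A", "H", "B", "-"))
})

test_that("a trio PED/MAP becomes the hand-computed bundle", {
  files <- write_trio_pedmap(tempdir())
  b <- from_pedmap(files$ped, files$map, "trio")
  expect_bundle_valid(b)
  mk <- b$records$Marker
  expect_identical(mk$name, c("rs1", "rs2"))
  expect_identical(mk$chromosome, c("1", "1"))
  expect_identical(mk$cm, c("0", "10.5"))
  expect_identical(mk$bp_start, c("1000", "250000"))
  ind <- b$records$Individual
  expect_identical(ind$name, c("c1", "f1", "m1"))
  expect_identical(ind$mother, c("m1", NA, NA))
  expect_identical(ind$father, c("f1", NA, NA))
  g <- b$matrices$genotypes$values
  expect_identical(dim(g), c(2L, 3L))
  expect_identical(g["rs1", ], c(c1 = "A/A", f1 = "A/G", m1 = "G/G"))
  expect_identical(g["rs2", ], c(c1 = "A/C", f1 = "C/C", m1 = "A/C"))
  # -9 phenotype is missing; the others carried over
  ph <- b$matrices$phenotypes$values
  expect_identical(unname(ph[1, ]), c(2.5, NA, 3.5))
  # family and sex kept as annotations
  expect_identical(nrow(b$records$Description), 3L)
  expect_match(b$records$Description$description[1], "family=F1")
})

test_that("trio parent references resolve after the two-pass import", {
  files <- write_trio_pedmap(tempdir())
  b <- from_pedmap(files$ped, files$map, "trio")
  s <- open_store(":memory:")
  on.exit(close_store(s))
  import_bundle(s, b)
  ind <- store_find(s, "Individual")
  expect_identical(ind$mother[ind$name == "c1"], "m1")
  expect_identical(ind$father[ind$name == "c1"], "f1")
  expect_identical(nrow(DBI::dbGetQuery(s$con,
                                        "PRAGMA foreign_key_check")), 0L)
})

test_that("PED defects are refused or downgraded as documented", {
  dir <- tempdir()
  mapf <- file.path(dir, "bad.map"); pedf <- file.path(dir, "bad.ped")
  writeLines(c("1 rs1 0 1000", "1 rs2 10 2000"), mapf)
  writeLines("F1 i1 0 0 1 1.0 A A", pedf)  # 1 marker's worth of alleles
  expect_error(from_pedmap(pedf, mapf), "allele")
  writeLines("F1 i1 ghost 0 1 1.0 A A C C", pedf)
  expect_warning(b <- from_pedmap(pedf, mapf), "ghost")
  expect_true(is.na(b$records$Individual$father[1]))
  expect_bundle_valid(b)
  # all-missing genotypes ("0 0") become missing cells
  writeLines("F1 i1 0 0 1 -9 0 0 A C", pedf)
  b2 <- from_pedmap(pedf, mapf)
  expect_true(is.na(b2$matrices$genotypes$values["rs1", "i1"]))
})
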