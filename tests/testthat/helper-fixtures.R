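# Shared fixtures and independent oracles.

# A small hand-assembled investigation: 2 probes x 3 individuals
# expression matrix plus a 2-marker genotype matrix.
tiny_bundle <- function() {
  inv <- data.frame(name = "inv1", description = "tiny demo",
                    stringsAsFactors = FALSE)
  probes <- data.frame(name = c("p1", "p2"), type = NA_character_,
                       investigation_name = "inv1",
                       sequence = c("ACGT", "TTGA"), chromosome = "1",
                       bp_start = c("1", "100"), bp_end = c("10", "200"),
                       cm = NA_character_, stringsAsFactors = FALSE)
  markers <- data.frame(name = c("m1", "m2"), type = NA_character_,
                        investigation_name = "inv1", chromosome = "1",
                        bp_start = c("50", "5000"),
                        bp_end = c("50", "5000"),
                        cm = c("0", "12.5"), stringsAsFactors = FALSE)
  inds <- data.frame(name = c("i1", "i2", "i3"), type = NA_character_,
                     investigation_name = "inv1", mother = NA_character_,
                     father = NA_character_, strain = NA_character_,
                     stringsAsFactors = FALSE)
  dat <- data.frame(name = c("expressions", "genotypes"),
                    investigation_name = "inv1",
                    rowtype = c("Probe", "Marker"),
                    coltype = "Individual",
                    valuetype = c("decimal", "text"),
                    stringsAsFactors = FALSE)
  ev <- matrix(c(1.5, NA, 1 / 3, 2, 0.1, 1e-10), 2, 3,
               dimnames = list(c("p1", "p2"), c("i1", "i2", "i3")))
  gv <- matrix(c("A", "B", "H", "A", NA, "B"), 2, 3,
               dimnames = list(c("m1", "m2"), c("i1", "i2", "i3")))
  xg_bundle(
    records = list(Investigation = inv, Probe = probes, Marker = markers,
                   Individual = inds, Data = dat),
    matrices = list(
      expressions = data_matrix("expressions", ev, "decimal"),
      genotypes = data_matrix("genotypes", gv, "text")),
    constants = c(species_name = "Mus musculus"),
    original_files = list("raw/chip1.cel.txt" = charToRaw("raw bytes")))
}

small_synth <- function(seed = 7, ...)
  generate_investigation(synth_params(
    n_subjects = 10, n_markers = 20, n_chromosomes = 2, n_probes = 15,
    n_qtl = 3, seed = seed, ...))

# rename the investigation of a generated bundle (all records reference
# the investigation by name)
rename_investigation <- function(bundle, new) {
  old <- bundle$records$Investigation$name[1]
  bundle$records$Investigation$name[1] <- new
  for (e in names(bundle$records)) {
    df <- bundle$records[[e]]
    if ("investigation_name" %in% names(df)) {
      df$investigation_name[df$investigation_name %in% old] <- new
      bundle$records[[e]] <- df
    }
    if ("target_name" %in% names(df)) {
      hit <- df$target_entity %in% "Investigation" &
        df$target_name %in% old
      df$target_name[hit] <- new
      bundle$records[[e]] <- df
    }
  }
  bundle
}

# Brute-force flattening oracle: walk the ancestry explicitly and collect
# field names (ancestors root-first, then interface fields, then own),
# dropping later duplicates. Independent of flatten_fields().
oracle_flatten_names <- function(model, entity) {
  chain <- character()
  e <- entity
  while (!is.null(e)) {
    chain <- c(e, chain)
    e <- model$entities[[e]]$extends
  }
  declared <- unlist(lapply(chain, function(nm)
    names(model$entities[[nm]]$fields)))
  ifaces <- unique(unlist(lapply(chain, function(nm)
    model$entities[[nm]]$implements)))
  iface_names <- unlist(lapply(ifaces, function(i)
    oracle_flatten_names(model, i)))
  own <- names(model$entities[[entity]]$fields)
  inherited <- declared[seq_len(length(declared) - length(own))]
  all <- c(inherited, iface_names, own)
  all[!duplicated(all)]
}

# Random model generator for load-order properties: entities E1..En,
# random single inheritance from earlier entities, random xref fields to
# arbitrary entities (self-references and cycles allowed).
random_model <- function(n_entities, seed) {
  set.seed(seed)
  ents <- list()
  nm <- paste0("E", seq_len(n_entities))
  for (i in seq_len(n_entities)) {
    fields <- list(xg_field("name", "string"))
    n_xref <- rbinom(1, 3, 0.4)
    for (k in seq_len(n_xref)) {
      tgt <- nm[sample.int(n_entities, 1)]
      fields[[length(fields) + 1]] <-
        xg_field(paste0("ref", k), "xref", target_entity = tgt)
    }
    ext <- if (i > 1 && runif(1) < 0.3) nm[sample.int(i - 1, 1)] else NULL
    ents[[i]] <- xg_entity(nm[i], fields, extends = ext)
  }
  xg_model(ents)
}

# Brute-force cycle oracle: an edge (prerequisite -> dependent) lies on a
# cycle iff the prerequisite is reachable from the dependent.
oracle_model_edges <- function(model) {
  ef <- character(); et <- character(); lab <- character()
  for (e in model$entities) {
    if (!is.null(e$extends)) {
      ef <- c(ef, e$extends); et <- c(et, e$name)
      lab <- c(lab, "extends")
    }
    for (f in e$fields)
      if (identical(f$valuetype, "xref")) {
        ef <- c(ef, f$target_entity); et <- c(et, e$name)
        lab <- c(lab, f$name)
      }
  }
  data.frame(from = ef, to = et, field = lab, stringsAsFactors = FALSE)
}

oracle_reachable <- function(edges, from, to) {
  seen <- from
  repeat {
    nxt <- unique(edges$to[edges$from %in% seen])
    new <- setdiff(nxt, seen)
    if (!length(new)) return(to %in% seen)
    seen <- c(seen, new)
  }
}

# write a tiny PED/MAP pair; returns the two paths
write_trio_pedmap <- function(dir = tempdir()) {
  mapf <- file.path(dir, "trio.map")
  pedf <- file.path(dir, "trio.ped")
  writeLines(c("1 rs1 0 1000", "1 rs2 10.5 250000"), mapf)
  writeLines(c("F1 c1 f1 m1 1 2.5 A A A C",
               "F1 f1 0 0 1 -9 A G C C",
               "F1 m1 0 0 2 3.5 G G A C"), pedf)
  list(ped = pedf, map = mapf)
}

expect_bundle_valid <- function(bundle, model = builtin_model()) {
  rep <- validate_bundle(bundle, model)
  expect_true(is_valid(rep))
  expect_identical(nrow(rep[rep$severity == "error", ]), 0L)
  invisible(rep)
}

# byte-level comparison of two bundle directories
expect_dirs_identical <- function(d1, d2) {
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     info = paste("file differs:", f))
}
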