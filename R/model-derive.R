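# Derivations from a model: tabular format spec, relational schema, load
# order. These are the "generator" operations: everything the I/O, store
# and validator layers know about a model is derived here.

#' Derive the tabular bundle format of a model
#'
#' Every concrete entity maps to one tab-delimited annotation file named
#' after the lowercased entity name, whose columns are the entity's
#' flattened fields in canonical order. Interfaces get no file. Matrices
#' live under the `data/` directory.
#'
#' @inheritParams entity_ancestors
#' @return An object of class `xg_format_spec`: `$files` is a named list
#'   (entity -> list(file, columns)), `$matrix_dir` is `"data"`.
#' @export
derive_format_spec <- function(model) {
  files <- list()
  for (nm in concrete_entities(model)) {
    files[[nm]] <- list(
      file = paste0(tolower(nm), ".txt"),
      columns = names(flatten_fields(model, nm)))
  }
  structure(list(files = files, matrix_dir = "data"),
            class = "xg_format_spec")
}

#' Render a format spec as a human-readable document
#'
#' The plain-text description of the expected bundle layout that a data
#' submitter would read: one section per annotation file listing its
#' columns, types and required flags.
#'
#' @inheritParams entity_ancestors
#' @param spec Optionally a precomputed [derive_format_spec()] result.
#' @return Character scalar.
#' @export
format_spec_doc <- function(model, spec = derive_format_spec(model)) {
  out <- c("XGAP-TAB bundle layout",
           "======================", "",
           "Tab-delimited UTF-8 files, one per data type; header row of",
           "column names; one row per record; empty cell = missing value.",
           paste0("Matrices are stored under '", spec$matrix_dir,
                  "/<name>.txt' with row and column name headers."), "")
  for (nm in names(spec$files)) {
    ff <- flatten_fields(model, nm)
    out <- c(out, paste0(spec$files[[nm]]$file, "  (", nm, ")"))
    for (f in ff) {
      out <- c(out, sprintf("  %-20s %s%s%s", f$name, f$valuetype,
        if (!is.null(f$target_entity))
          paste0(" -> ", tolower(f$target_entity), ".txt") else "",
        if (f$required) "  [required]" else ""))
    }
    out <- c(out, "")
  }
  paste(out, collapse = "\n")
}

sql_type <- function(valuetype) {
  switch(valuetype,
         int = "INTEGER", bool = "INTEGER", decimal = "REAL",
         xref = "INTEGER", "TEXT")
}

#' Derive the relational schema of a model
#'
#' Mapping rules: one table per concrete entity with primary key
#' `molgenisid`; a subclass table shares its primary key with (and holds a
#' foreign key to) its superclass table, so a subclass row always implies a
#' superclass row; each `xref` field becomes an integer foreign-key column;
#' each `mref` field becomes a link table `mref_<entity>_<field>` holding
#' two foreign keys. Interface fields materialize as columns of the
#' declaring entity's table. Root tables additionally carry an
#' `entity_class` discriminator column recording each row's concrete type.
#'
#' @inheritParams entity_ancestors
#' @return An object of class `xg_relational_schema`: `$tables` (named
#'   list with `columns`, `types`, `primary_key`, `parent`, `foreign_keys`)
#'   and `$link_tables`.
#' @export
derive_relational_schema <- function(model) {
  tables <- list()
  links <- list()
  for (nm in concrete_entities(model)) {
    e <- model$entities[[nm]]
    own <- e$fields
    for (i in e$implements) own <- c(own, flatten_fields(model, i))
    own <- own[!duplicated(names(own))]
    # inherited fields live in ancestor tables
    inh <- unlist(lapply(entity_ancestors(model, nm), function(a)
      names(model$entities[[a]]$fields)))
    own <- own[!names(own) %in% inh]
    cols <- "molgenisid"; types <- "INTEGER"; fks <- list()
    if (is.null(e$extends)) {
      cols <- c(cols, "entity_class"); types <- c(types, "TEXT")
    } else {
      fks[[length(fks) + 1]] <- list(column = "molgenisid",
                                     references = tolower(e$extends))
    }
    for (f in own) {
      if (f$valuetype == "mref") {
        tname <- tolower(paste0("mref_", nm, "_", f$name))
        links[[tname]] <- list(
          entity = nm, field = f$name, target = f$target_entity,
          columns = c(tolower(nm), f$name),
          references = c(tolower(nm), tolower(f$target_entity)))
        next
      }
      cols <- c(cols, f$name)
      types <- c(types, sql_type(f$valuetype))
      if (f$valuetype == "xref")
        fks[[length(fks) + 1]] <- list(column = f$name,
                                       references = tolower(f$target_entity))
    }
    tables[[tolower(nm)]] <- list(
      entity = nm, columns = cols, types = types,
      primary_key = "molgenisid",
      parent = if (is.null(e$extends)) NULL else tolower(e$extends),
      foreign_keys = fks)
  }
  structure(list(tables = tables, link_tables = links),
            class = "xg_relational_schema")
}

#' Render a relational schema as SQL DDL (SQLite dialect)
#'
#' @param rschema A [derive_relational_schema()] result.
#' @return Character scalar of `CREATE TABLE` statements in dependency
#'   order (parents and referenced tables first wherever possible).
#' @export
schema_ddl <- function(rschema) {
  stmts <- character()
  for (tn in names(rschema$tables)) {
    t <- rschema$tables[[tn]]
    defs <- sprintf("  %s %s%s", t$columns, t$types,
                    ifelse(t$columns == t$primary_key, " PRIMARY KEY", ""))
    for (fk in t$foreign_keys)
      defs <- c(defs, sprintf("  FOREIGN KEY (%s) REFERENCES %s(molgenisid)",
                              fk$column, fk$references))
    stmts <- c(stmts, sprintf("CREATE TABLE %s (\n%s\n);", tn,
                              paste(defs, collapse = ",\n")))
  }
  for (ln in names(rschema$link_tables)) {
    l <- rschema$link_tables[[ln]]
    defs <- c(sprintf("  %s INTEGER NOT NULL", l$columns),
              sprintf("  FOREIGN KEY (%s) REFERENCES %s(molgenisid)",
                      l$columns, l$references))
    stmts <- c(stmts, sprintf("CREATE TABLE %s (\n%s\n);", ln,
                              paste(defs, collapse = ",\n")))
  }
  paste(stmts, collapse = "\n\n")
}

# strongly connected components (Tarjan), nodes = character vector,
# edges = data.frame(from, to); returns integer component id per node
scc_components <- function(nodes, edges) {
  n <- length(nodes)
  idx <- setNames(seq_len(n), nodes)
  adj <- lapply(nodes, function(x) idx[edges$to[edges$from == x]])
  index <- rep(NA_integer_, n); low <- rep(NA_integer_, n)
  onstack <- rep(FALSE, n); stack <- integer(); comp <- rep(NA_integer_, n)
  counter <- 0L; ncomp <- 0L
  strongconnect <- function(v) {
    counter <<- counter + 1L
    index[v] <<- counter; low[v] <<- counter
    stack <<- c(stack, v); onstack[v] <<- TRUE
    for (w in adj[[v]]) {
      if (is.na(index[w])) {
        strongconnect(w)
        low[v] <<- min(low[v], low[w])
      } else if (onstack[w]) {
        low[v] <<- min(low[v], index[w])
      }
    }
    if (low[v] == index[v]) {
      ncomp <<- ncomp + 1L
      repeat {
        w <- stack[length(stack)]; stack <<- stack[-length(stack)]
        onstack[w] <<- FALSE; comp[w] <<- ncomp
        if (w == v) break
      }
    }
  }
  for (v in seq_len(n)) if (is.na(index[v])) strongconnect(v)
  setNames(comp, nodes)
}

#' Compute a safe import order over a model's reference graph
#'
#' Records must be imported so that every one-to-many reference points at
#' an already-loaded record: referenced entities come before referencing
#' entities and superclasses before subclasses. Reference edges that cannot
#' be ordered — self-references such as a pedigree's mother/father links,
#' or reference cycles — are returned as *deferred*: such fields are loaded
#' as missing in the first pass and patched in a second pass.
#'
#' @inheritParams entity_ancestors
#' @return A list with `order` (character vector of concrete entity names)
#'   and `deferred` (data.frame with columns `entity`, `field`, `target`;
#'   exactly the xref edges lying on cycles, plus all mref fields, which
#'   are always linked in the second pass).
#' @export
load_order <- function(model) {
  nodes <- concrete_entities(model)
  # edges from prerequisite to dependent
  ef <- character(); et <- character()
  xe <- list()  # xref bookkeeping: entity, field, target
  for (nm in nodes) {
    e <- model$entities[[nm]]
    if (!is.null(e$extends)) { ef <- c(ef, e$extends); et <- c(et, nm) }
    own <- e$fields
    for (i in e$implements) own <- c(own, flatten_fields(model, i))
    for (f in own) {
      if (identical(f$valuetype, "xref")) {
        ef <- c(ef, f$target_entity); et <- c(et, nm)
        xe[[length(xe) + 1]] <- c(nm, f$name, f$target_entity)
      }
    }
  }
  edges <- data.frame(from = ef, to = et, stringsAsFactors = FALSE)
  comp <- scc_components(nodes, edges)
  deferred <- data.frame(entity = character(), field = character(),
                         target = character(), stringsAsFactors = FALSE)
  for (x in xe) {
    if (comp[[x[1]]] == comp[[x[3]]])
      deferred[nrow(deferred) + 1, ] <- x
  }
  # mref links always resolve in pass two
  for (nm in nodes) {
    e <- model$entities[[nm]]
    own <- e$fields
    for (i in e$implements) own <- c(own, flatten_fields(model, i))
    for (f in own)
      if (identical(f$valuetype, "mref"))
        deferred[nrow(deferred) + 1, ] <- c(nm, f$name, f$target_entity)
  }
  # drop deferred xref edges, then Kahn in declaration order
  keep <- rep(TRUE, nrow(edges))
  for (i in seq_len(nrow(edges)))
    keep[i] <- comp[[edges$from[i]]] != comp[[edges$to[i]]] ||
      # inheritance edges are never deferred (extends graph is acyclic)
      edges$to[i] %in% nodes[vapply(nodes, function(nmm)
        identical(model$entities[[nmm]]$extends, edges$from[i]), logical(1))]
  edges <- edges[keep, , drop = FALSE]
  placed <- character(); remaining <- nodes
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(nmm)
      !any(edges$to == nmm & !edges$from %in% placed), logical(1))]
    if (!length(ready))
      stop("internal error: load order is stuck (unbroken cycle)")
    placed <- c(placed, ready[1])
    remaining <- setdiff(remaining, ready[1])
  }
  list(order = placed, deferred = deferred)
}
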