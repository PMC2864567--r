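# Embedded relational store.
#
# The store realizes derive_relational_schema(model) in a single SQLite
# file: one table per concrete entity sharing the primary key
# "molgenisid" along inheritance chains, xrefs as integer foreign keys,
# mrefs as link tables. Two auxiliary relations carry what the entity
# tables cannot: matrix cells live in a single `dataelement` relation
# (data id, row/col index, row/col DimensionElement, value) — one row per
# cell — and bundle constants in `bundle_constant`. Foreign keys are
# enforced by the engine (PRAGMA foreign_keys = ON).

#' Open (or create) an embedded store
#'
#' @param path SQLite file path; `":memory:"` for a throwaway store.
#' @param model The governing [xg_model()]; its relational schema is
#'   created on first open.
#' @return An object of class `xg_store`.
#' @export
open_store <- function(path = ":memory:", model = builtin_model()) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  DBI::dbExecute(con, "PRAGMA foreign_keys = ON")
  store <- structure(
    list2env(list(con = con, path = path, model = model,
                  rschema = derive_relational_schema(model),
                  lo = load_order(model), txn = FALSE),
             parent = emptyenv()),
    class = "xg_store")
  existing <- DBI::dbListTables(con)
  if (!length(intersect(names(store$rschema$tables), existing))) {
    for (stmt in strsplit(schema_ddl(store$rschema), ";\n*")[[1]])
      if (nzchar(trimws(stmt))) DBI::dbExecute(con, stmt)
    aux <- aux_ddl(model)
    for (stmt in aux) DBI::dbExecute(con, stmt)
  }
  store
}

aux_ddl <- function(model) {
  out <- character()
  ce <- concrete_entities(model)
  if (all(c("Data", "DimensionElement") %in% ce))
    out <- c(out, paste(
      "CREATE TABLE dataelement (",
      "  data INTEGER NOT NULL REFERENCES data(molgenisid),",
      "  row_index INTEGER NOT NULL,",
      "  col_index INTEGER NOT NULL,",
      "  row_element INTEGER REFERENCES dimensionelement(molgenisid),",
      "  col_element INTEGER REFERENCES dimensionelement(molgenisid),",
      "  value TEXT)", sep = "\n"))
  if ("Investigation" %in% ce)
    out <- c(out, paste(
      "CREATE TABLE bundle_constant (",
      "  investigation INTEGER REFERENCES investigation(molgenisid),",
      "  key TEXT NOT NULL,",
      "  value TEXT NOT NULL)", sep = "\n"))
  out
}

#' Close a store
#' @param store An [open_store()] handle.
#' @export
close_store <- function(store) {
  DBI::dbDisconnect(store$con)
  invisible(NULL)
}

#' @export
print.xg_store <- function(x, ...) {
  cat("<xg_store> ", x$path, if (x$txn) " [transaction open]", "\n",
      sep = "")
  invisible(x)
}

# ---- schema helpers -------------------------------------------------------

entity_chain <- function(model, entity)
  c(entity_ancestors(model, entity), entity)

# fields stored in entity's own table (declared + interface, minus mref)
table_fields <- function(model, entity) {
  e <- model$entities[[entity]]
  own <- e$fields
  for (i in e$implements) own <- c(own, flatten_fields(model, i))
  own <- own[!duplicated(names(own))]
  inh <- unlist(lapply(entity_ancestors(model, entity), function(a)
    names(model$entities[[a]]$fields)))
  own <- own[!names(own) %in% inh]
  own[vapply(own, function(f) f$valuetype != "mref", logical(1))]
}

mref_fields <- function(model, entity) {
  e <- model$entities[[entity]]
  own <- e$fields
  for (i in e$implements) own <- c(own, flatten_fields(model, i))
  own <- own[!duplicated(names(own))]
  own[vapply(own, function(f) f$valuetype == "mref", logical(1))]
}

# table (lowercased entity name) holding a given flattened field
field_table <- function(model, entity, field) {
  for (nm in rev(entity_chain(model, entity)))
    if (field %in% names(table_fields(model, nm)) ||
        field %in% names(mref_fields(model, nm)))
      return(nm)
  stop("entity '", entity, "' has no field '", field, "'")
}

root_of <- function(model, entity) entity_chain(model, entity)[1]

to_sql_value <- function(v, valuetype) {
  switch(valuetype,
         int = suppressWarnings(as.integer(v)),
         decimal = suppressWarnings(as.numeric(v)),
         as.character(v))
}

from_sql_value <- function(v, valuetype) {
  switch(valuetype,
         int = ifelse(is.na(v), NA_character_,
                      as.character(as.integer(v))),
         decimal = fmt_decimal(as.numeric(v)),
         as.character(v))
}

# ---- transactions ---------------------------------------------------------

#' Explicit store transactions
#'
#' `store_begin()` opens a transaction, `store_commit()` makes it durable,
#' `store_rollback()` restores the exact pre-begin state. Transactions do
#' not nest. [import_bundle()] and [store_add()] use savepoints
#' internally, so they are all-or-nothing whether or not an explicit
#' transaction is open.
#'
#' @param store An [open_store()] handle.
#' @return The store, invisibly.
#' @export
store_begin <- function(store) {
  if (store$txn) stop("transaction already active (no nesting)")
  DBI::dbExecute(store$con, "BEGIN")
  store$txn <- TRUE
  invisible(store)
}

#' @rdname store_begin
#' @export
store_commit <- function(store) {
  if (!store$txn) stop("no active transaction")
  DBI::dbExecute(store$con, "COMMIT")
  store$txn <- FALSE
  invisible(store)
}

#' @rdname store_begin
#' @export
store_rollback <- function(store) {
  if (!store$txn) stop("no active transaction")
  DBI::dbExecute(store$con, "ROLLBACK")
  store$txn <- FALSE
  invisible(store)
}

with_savepoint <- function(store, name, code) {
  DBI::dbExecute(store$con, paste("SAVEPOINT", name))
  ok <- FALSE
  on.exit({
    if (!ok) {
      DBI::dbExecute(store$con, paste("ROLLBACK TO", name))
      DBI::dbExecute(store$con, paste("RELEASE", name))
    }
  })
  res <- force(code)
  DBI::dbExecute(store$con, paste("RELEASE", name))
  ok <- TRUE
  res
}

# ---- snapshots ------------------------------------------------------------

#' Logical snapshot of a store
#'
#' Every table's full contents in rowid order; two snapshots compare with
#' `identical()`. Used to verify that failed imports leave no trace.
#'
#' @param store An [open_store()] handle.
#' @return Named list of data.frames.
#' @export
store_snapshot <- function(store) {
  out <- list()
  for (tn in sort(DBI::dbListTables(store$con))) {
    if (tn == "sqlite_sequence") next
    df <- DBI::dbGetQuery(store$con,
                          paste0("SELECT * FROM ", tn, " ORDER BY rowid"))
    rownames(df) <- NULL
    out[[tn]] <- df
  }
  out
}

# ---- lookups --------------------------------------------------------------

# SELECT of one concrete entity's rows with its table-resident columns
entity_rows <- function(store, entity, with_class = TRUE) {
  model <- store$model
  chain <- entity_chain(model, entity)
  root <- tolower(chain[1])
  sel <- c(paste0("t1.molgenisid AS molgenisid"),
           if (with_class) "t1.entity_class AS entity_class")
  from <- paste0(root, " t1")
  for (k in seq_along(chain)) {
    tf <- names(table_fields(model, chain[k]))
    if (length(tf))
      sel <- c(sel, paste0("t", k, ".", tf, " AS ", tf))
    if (k > 1)
      from <- paste0(from, " JOIN ", tolower(chain[k]), " t", k,
                     " ON t", k, ".molgenisid = t1.molgenisid")
  }
  sql <- paste0("SELECT ", paste(sel, collapse = ", "), " FROM ", from,
                " WHERE t1.entity_class = '", entity, "'",
                " ORDER BY t1.molgenisid")
  DBI::dbGetQuery(store$con, sql)
}

# names of records whose concrete class is exactly `entity`
store_names <- function(store, entity) {
  if (!entity %in% concrete_entities(store$model)) return(character())
  ff <- flatten_fields(store$model, entity)
  if (!"name" %in% names(ff)) return(character())
  df <- entity_rows(store, entity)
  df$name[!is.na(df$name)]
}

# name -> molgenisid over an entity and its concrete descendants
store_id_map <- function(store, entity) {
  out <- integer()
  for (e in concrete_descendants(store$model, entity)) {
    ff <- flatten_fields(store$model, e)
    if (!"name" %in% names(ff)) next
    df <- entity_rows(store, e)
    keep <- !is.na(df$name)
    out <- c(out, setNames(df$molgenisid[keep], df$name[keep]))
  }
  out
}

# ---- insertion ------------------------------------------------------------

# Insert canonical character records of one concrete entity. `resolver`
# maps (target entity, name) -> molgenisid. Deferred xref fields are
# inserted NULL and listed in the returned patch data.frame.
insert_records <- function(store, entity, df, resolver, deferred_fields) {
  model <- store$model
  n <- nrow(df)
  if (!n) return(list(ids = integer(), patches = NULL, links = NULL))
  chain <- entity_chain(model, entity)
  root <- tolower(chain[1])
  base <- DBI::dbGetQuery(store$con, paste0(
    "SELECT COALESCE(MAX(molgenisid), 0) AS m FROM ", root))$m
  ids <- base + seq_len(n)
  patches <- list()
  getcol <- function(fn) {
    v <- if (fn %in% names(df)) as.character(df[[fn]])
      else rep(NA_character_, n)
    v[!is.na(v) & !nzchar(v)] <- NA_character_
    v
  }
  for (k in seq_along(chain)) {
    tf <- table_fields(model, chain[k])
    cols <- list(molgenisid = ids)
    if (k == 1) cols$entity_class <- rep(entity, n)
    for (f in tf) {
      v <- getcol(f$name)
      if (f$valuetype == "xref") {
        if (f$name %in% deferred_fields) {
          idx <- which(!is.na(v))
          if (length(idx))
            patches[[length(patches) + 1]] <- data.frame(
              entity = entity, table = tolower(chain[k]), field = f$name,
              target = f$target_entity, molgenisid = ids[idx],
              value = v[idx], stringsAsFactors = FALSE)
          cols[[f$name]] <- rep(NA_integer_, n)
        } else {
          rid <- resolver(f$target_entity, v)
          if (any(!is.na(v) & is.na(rid)))
            stop("unresolved reference in ", entity, ".", f$name, ": '",
                 v[!is.na(v) & is.na(rid)][1], "'")
          cols[[f$name]] <- rid
        }
      } else {
        cols[[f$name]] <- to_sql_value(v, f$valuetype)
      }
    }
    sql <- paste0("INSERT INTO ", tolower(chain[k]), " (",
                  paste(names(cols), collapse = ", "), ") VALUES (",
                  paste(rep("?", length(cols)), collapse = ", "), ")")
    DBI::dbExecute(store$con, sql, params = unname(cols))
  }
  links <- list()
  for (f in mref_fields_all(model, entity)) {
    v <- getcol(f$field)
    idx <- which(!is.na(v))
    if (length(idx))
      links[[length(links) + 1]] <- data.frame(
        entity = entity, owner_entity = f$owner, field = f$field,
        target = f$target, molgenisid = ids[idx], value = v[idx],
        stringsAsFactors = FALSE)
  }
  list(ids = setNames(ids, getcol("name")),
       patches = if (length(patches)) do.call(rbind, patches) else NULL,
       links = if (length(links)) do.call(rbind, links) else NULL)
}

# mref fields anywhere along the chain, with their declaring entity
mref_fields_all <- function(model, entity) {
  out <- list()
  for (nm in entity_chain(model, entity))
    for (f in mref_fields(model, nm))
      out[[length(out) + 1]] <- list(owner = nm, field = f$name,
                                     target = f$target_entity)
  out
}

apply_patches <- function(store, patches, resolver) {
  if (is.null(patches)) return(invisible())
  for (i in seq_len(nrow(patches))) {
    rid <- resolver(patches$target[i], patches$value[i])
    if (is.na(rid))
      stop("unresolved deferred reference in ", patches$entity[i], ".",
           patches$field[i], ": '", patches$value[i], "'")
    DBI::dbExecute(store$con, paste0(
      "UPDATE ", patches$table[i], " SET ", patches$field[i],
      " = ? WHERE molgenisid = ?"), params = list(rid,
                                                  patches$molgenisid[i]))
  }
  invisible()
}

apply_links <- function(store, links, resolver) {
  if (is.null(links)) return(invisible())
  for (i in seq_len(nrow(links))) {
    owner <- links$owner_entity[i]
    tbl <- tolower(paste0("mref_", owner, "_", links$field[i]))
    members <- trimws(strsplit(links$value[i], ",", fixed = TRUE)[[1]])
    members <- members[nzchar(members)]
    for (mname in members) {
      rid <- resolver(links$target[i], mname)
      if (is.na(rid))
        stop("unresolved reference in ", links$entity[i], ".",
             links$field[i], ": '", mname, "'")
      DBI::dbExecute(store$con, paste0(
        "INSERT INTO ", tbl, " (", tolower(owner), ", ", links$field[i],
        ") VALUES (?, ?)"), params = list(links$molgenisid[i], rid))
    }
  }
  invisible()
}

# resolver factory: in-flight idmap (entity -> named id vector) backed by
# the store
make_resolver <- function(store, idmap_env) {
  model <- store$model
  function(target, names) {
    out <- rep(NA_integer_, length(names))
    cand <- concrete_descendants(model, target)
    for (e in cand) {
      mp <- idmap_env$map[[e]]
      if (!is.null(mp)) {
        hit <- !is.na(names) & is.na(out) & names %in% names(mp)
        out[hit] <- mp[names[hit]]
      }
    }
    if (any(!is.na(names) & is.na(out))) {
      smap <- store_id_map(store, target)
      hit <- !is.na(names) & is.na(out) & names %in% names(smap)
      out[hit] <- smap[names[hit]]
    }
    out
  }
}

#' Import a bundle into the store
#'
#' Validates the bundle first ([validate_bundle()]; any error-severity
#' finding aborts the import with the report attached to the condition).
#' Records are then inserted in dependency order with deferred
#' (self/cyclic) references patched in a second pass, mref link rows
#' added, each matrix persisted as one `Data` row plus one `dataelement`
#' row per cell, and constants stored. The whole import is one atomic
#' unit: on any failure the store is exactly as before the call.
#'
#' @param store An [open_store()] handle.
#' @param bundle An [xg_bundle()].
#' @return Import summary: named list with `records` (named count per
#'   entity), `matrices` (count), and `cells` (dataelement rows written).
#' @export
import_bundle <- function(store, bundle) {
  model <- store$model
  report <- validate_bundle(bundle, model, store = store)
  if (!is_valid(report)) {
    cond <- structure(
      class = c("xg_validation_error", "error", "condition"),
      list(message = paste0("bundle failed validation (",
                            sum(report$severity == "error"),
                            " error(s)); first: ",
                            report$message[report$severity == "error"][1],
                            " at ",
                            report$location[report$severity == "error"][1]),
           call = sys.call(), report = report))
    stop(cond)
  }
  with_savepoint(store, "xg_import", {
    idmap_env <- new.env(parent = emptyenv())
    idmap_env$map <- list()
    resolver <- make_resolver(store, idmap_env)
    counts <- integer()
    all_patches <- list(); all_links <- list()
    for (entity in store$lo$order) {
      df <- bundle$records[[entity]]
      if (is.null(df) || !nrow(df)) next
      defer <- store$lo$deferred
      dfields <- defer$field[defer$entity == entity]
      res <- insert_records(store, entity, df, resolver, dfields)
      idmap_env$map[[entity]] <- res$ids[!is.na(names(res$ids)) &
                                           nzchar(names(res$ids))]
      counts[entity] <- nrow(df)
      if (!is.null(res$patches))
        all_patches[[length(all_patches) + 1]] <- res$patches
      if (!is.null(res$links))
        all_links[[length(all_links) + 1]] <- res$links
    }
    # second pass: deferred xrefs, then mref links
    if (length(all_patches))
      apply_patches(store, do.call(rbind, all_patches), resolver)
    if (length(all_links))
      apply_links(store, do.call(rbind, all_links), resolver)
    # matrices
    cells <- 0L
    ddf <- bundle$records[["Data"]]
    for (mn in names(bundle$matrices)) {
      m <- bundle$matrices[[mn]]
      data_id <- idmap_env$map[["Data"]][[mn]]
      decl <- ddf[match(mn, ddf$name), ]
      rid <- resolver(decl$rowtype, rownames(m$values))
      cid <- resolver(decl$coltype, colnames(m$values))
      nr <- nrow(m$values); nc <- ncol(m$values)
      if (nr && nc) {
        vals <- if (m$valuetype == "decimal") fmt_decimal(m$values)
          else as.character(m$values)
        dim(vals) <- dim(m$values)
        params <- list(
          data = rep(data_id, nr * nc),
          row_index = rep(seq_len(nr), times = nc),
          col_index = rep(seq_len(nc), each = nr),
          row_element = rep(unname(rid), times = nc),
          col_element = rep(unname(cid), each = nr),
          value = as.vector(vals))
        DBI::dbExecute(store$con, paste(
          "INSERT INTO dataelement",
          "(data, row_index, col_index, row_element, col_element, value)",
          "VALUES (?, ?, ?, ?, ?, ?)"), params = unname(params))
        cells <- cells + nr * nc
      }
    }
    # constants, tied to the bundle's investigation
    if (length(bundle$constants)) {
      inv_id <- NA_integer_
      if (!is.null(idmap_env$map[["Investigation"]]) &&
          length(idmap_env$map[["Investigation"]]))
        inv_id <- idmap_env$map[["Investigation"]][[1]]
      DBI::dbExecute(store$con, paste(
        "INSERT INTO bundle_constant (investigation, key, value)",
        "VALUES (?, ?, ?)"),
        params = list(rep(inv_id, length(bundle$constants)),
                      names(bundle$constants),
                      unname(bundle$constants)))
    }
    list(records = counts, matrices = length(bundle$matrices),
         cells = cells)
  })
}

# ---- retrieval ------------------------------------------------------------

canonical_rows <- function(store, entity) {
  model <- store$model
  ff <- flatten_fields(model, entity)
  raw <- entity_rows(store, entity)
  n <- nrow(raw)
  out <- list()
  xref_cache <- new.env(parent = emptyenv())
  id_to_name <- function(target, ids) {
    key <- target
    if (is.null(xref_cache[[key]])) {
      mp <- store_id_map(store, target)
      xref_cache[[key]] <- if (length(mp)) setNames(names(mp), mp)
        else setNames(character(), character())
    }
    lk <- xref_cache[[key]]
    if (!length(ids)) return(character())
    unname(lk[as.character(ids)])
  }
  for (f in ff) {
    if (f$valuetype == "mref") {
      tbl <- tolower(paste0("mref_", field_table(model, entity, f$name),
                            "_", f$name))
      owner <- tolower(field_table(model, entity, f$name))
      v <- rep(NA_character_, n)
      if (n) {
        lk <- DBI::dbGetQuery(store$con, paste0(
          "SELECT ", owner, " AS owner, ", f$name,
          " AS target FROM ", tbl, " ORDER BY rowid"))
        if (nrow(lk)) {
          tn <- id_to_name(f$target_entity, lk$target)
          agg <- tapply(tn, lk$owner, paste, collapse = ",")
          hit <- match(raw$molgenisid, as.integer(names(agg)))
          v[!is.na(hit)] <- unname(agg[hit[!is.na(hit)]])
        }
      }
      out[[f$name]] <- v
    } else if (f$valuetype == "xref") {
      out[[f$name]] <- if (n) id_to_name(f$target_entity, raw[[f$name]])
        else character()
    } else {
      out[[f$name]] <- from_sql_value(raw[[f$name]], f$valuetype)
    }
  }
  df <- as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
  df$entity_class <- raw$entity_class
  df$molgenisid <- raw$molgenisid
  df
}

#' Find records in the store
#'
#' Returns records of `entity` *and all its subtypes* (a `Gene` is
#' returned by `store_find(store, "Trait")`), projected onto the queried
#' entity's flattened fields, with xref/mref values resolved back to
#' names. Filters are a conjunction of field = value tests on those
#' fields.
#'
#' @param store An [open_store()] handle.
#' @param entity Concrete entity name.
#' @param filters Named list/vector of field = value (canonical character
#'   form; xref filters take the target record's name).
#' @return data.frame with the flattened fields plus `entity_class` and
#'   `molgenisid`.
#' @export
store_find <- function(store, entity, filters = list()) {
  model <- store$model
  ff <- flatten_fields(model, get_entity(model, entity)$name)
  bad <- setdiff(names(filters), names(ff))
  if (length(bad))
    stop("unknown filter field(s) for ", entity, ": ",
         paste(bad, collapse = ", "))
  parts <- lapply(concrete_descendants(model, entity), function(e) {
    df <- canonical_rows(store, e)
    df[, c(names(ff), "entity_class", "molgenisid"), drop = FALSE]
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) return(out)
  rownames(out) <- NULL
  for (fn in names(filters)) {
    keep <- !is.na(out[[fn]]) & out[[fn]] == as.character(filters[[fn]])
    out <- out[keep, , drop = FALSE]
  }
  out <- out[order(out$molgenisid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Add, update or remove records
#'
#' All three are all-or-nothing per call: a constraint violation or
#' unresolved reference anywhere in the batch leaves the store untouched.
#' Batches of tens of thousands of records are inserted with batched
#' parameter binding. `store_update()` matches records by `name` (and
#' `investigation_name` when present); `store_remove()` refuses to delete
#' records that are still referenced (nothing cascades).
#'
#' @param store An [open_store()] handle.
#' @param entity Concrete entity name.
#' @param records data.frame of records in canonical character form.
#' @return Number of records affected, invisibly.
#' @export
store_add <- function(store, entity, records) {
  model <- store$model
  get_entity(model, entity)
  if (model$entities[[entity]]$is_interface)
    stop("cannot instantiate interface '", entity, "'")
  invisible(with_savepoint(store, "xg_add", {
    idmap_env <- new.env(parent = emptyenv())
    idmap_env$map <- list()
    resolver <- make_resolver(store, idmap_env)
    defer <- store$lo$deferred
    dfields <- defer$field[defer$entity == entity]
    res <- insert_records(store, entity, records, resolver, dfields)
    idmap_env$map[[entity]] <- res$ids
    apply_patches(store, res$patches, resolver)
    apply_links(store, res$links, resolver)
    nrow(records)
  }))
}

#' @rdname store_add
#' @export
store_update <- function(store, entity, records) {
  model <- store$model
  ff <- flatten_fields(model, get_entity(model, entity)$name)
  invisible(with_savepoint(store, "xg_update", {
    existing <- canonical_rows(store, entity)
    resolver <- make_resolver(store,
                              local({
                                e <- new.env(parent = emptyenv())
                                e$map <- list(); e
                              }))
    n <- 0L
    for (i in seq_len(nrow(records))) {
      key <- existing$name == records$name[i]
      if ("investigation_name" %in% names(records) &&
          "investigation_name" %in% names(existing) &&
          !is.na(records$investigation_name[i]))
        key <- key & !is.na(existing$investigation_name) &
          existing$investigation_name == records$investigation_name[i]
      idx <- which(!is.na(key) & key)
      if (!length(idx))
        stop("no existing ", entity, " named '", records$name[i], "'")
      id <- existing$molgenisid[idx[1]]
      for (fn in setdiff(intersect(names(records), names(ff)), "name")) {
        f <- ff[[fn]]
        v <- records[[fn]][i]
        if (is.na(v)) next
        if (f$valuetype == "mref") next  # link edits not supported here
        sqlv <- if (f$valuetype == "xref") {
          rid <- resolver(f$target_entity, v)
          if (is.na(rid)) stop("unresolved reference '", v, "'")
          rid
        } else to_sql_value(v, f$valuetype)
        DBI::dbExecute(store$con, paste0(
          "UPDATE ", tolower(field_table(model, entity, fn)), " SET ", fn,
          " = ? WHERE molgenisid = ?"), params = list(sqlv, id))
      }
      n <- n + 1L
    }
    n
  }))
}

#' @rdname store_add
#' @param names Character vector of record names to remove.
#' @export
store_remove <- function(store, entity, names) {
  model <- store$model
  invisible(with_savepoint(store, "xg_remove", {
    existing <- canonical_rows(store, entity)
    idx <- match(names, existing$name)
    if (anyNA(idx))
      stop("no existing ", entity, " named '", names[is.na(idx)][1], "'")
    ids <- existing$molgenisid[idx]
    for (tn in rev(entity_chain(model, entity))) {
      for (l in names(store$rschema$link_tables)) {
        lt <- store$rschema$link_tables[[l]]
        if (lt$entity == tn)
          DBI::dbExecute(store$con, paste0(
            "DELETE FROM ", l, " WHERE ", tolower(tn), " IN (",
            paste(ids, collapse = ","), ")"))
      }
      DBI::dbExecute(store$con, paste0(
        "DELETE FROM ", tolower(tn), " WHERE molgenisid IN (",
        paste(ids, collapse = ","), ")"))
    }
    length(ids)
  }))
}

# ---- export ---------------------------------------------------------------

#' Export an investigation as a bundle
#'
#' Collects every record, matrix and constant belonging to the named
#' investigation into a bundle; importing a bundle and exporting its
#' investigation returns the canonical form of the input.
#'
#' @param store An [open_store()] handle.
#' @param investigation Investigation name.
#' @return An [xg_bundle()].
#' @export
export_investigation <- function(store, investigation) {
  model <- store$model
  invs <- canonical_rows(store, "Investigation")
  idx <- match(investigation, invs$name)
  if (is.na(idx)) stop("unknown investigation: '", investigation, "'")
  inv_id <- invs$molgenisid[idx]
  records <- list()
  for (entity in store$lo$order) {
    df <- canonical_rows(store, entity)
    if (!nrow(df)) next
    keep <- if (entity == "Investigation") df$name == investigation
      else if ("investigation_name" %in% names(df))
        !is.na(df$investigation_name) &
          df$investigation_name == investigation
      else rep(FALSE, nrow(df))
    df <- df[keep, setdiff(names(df), c("entity_class", "molgenisid")),
             drop = FALSE]
    rownames(df) <- NULL
    if (nrow(df)) records[[entity]] <- df
  }
  matrices <- list()
  ddf <- records[["Data"]]
  if (!is.null(ddf)) {
    all_data <- canonical_rows(store, "Data")
    all_data <- all_data[!is.na(all_data$investigation_name) &
                           all_data$investigation_name == investigation, ,
                         drop = FALSE]
    for (i in seq_len(nrow(ddf))) {
      mn <- ddf$name[i]
      data_id <- all_data$molgenisid[match(mn, all_data$name)]
      cells <- DBI::dbGetQuery(store$con, paste0(
        "SELECT row_index, col_index, row_element, col_element, value ",
        "FROM dataelement WHERE data = ", data_id,
        " ORDER BY col_index, row_index"))
      if (!nrow(cells)) next
      nr <- max(cells$row_index); nc <- max(cells$col_index)
      elem_name <- function(ids) {
        uq <- unique(ids)
        lk <- DBI::dbGetQuery(store$con, paste0(
          "SELECT molgenisid, name FROM dimensionelement ",
          "WHERE molgenisid IN (", paste(uq, collapse = ","), ")"))
        setNames(lk$name, lk$molgenisid)[as.character(ids)]
      }
      rn <- elem_name(cells$row_element[cells$col_index == 1][
        order(cells$row_index[cells$col_index == 1])])
      cn <- elem_name(cells$col_element[cells$row_index == 1][
        order(cells$col_index[cells$row_index == 1])])
      vt <- ddf$valuetype[i]
      vals <- matrix(if (vt == "decimal") NA_real_ else NA_character_,
                     nr, nc, dimnames = list(unname(rn), unname(cn)))
      vals[cbind(cells$row_index, cells$col_index)] <-
        if (vt == "decimal") as.numeric(cells$value) else cells$value
      matrices[[mn]] <- data_matrix(mn, vals, vt)
    }
  }
  const <- DBI::dbGetQuery(store$con, paste0(
    "SELECT key, value FROM bundle_constant WHERE investigation = ",
    inv_id, " ORDER BY key"))
  xg_bundle(records, matrices,
            setNames(const$value, const$key), list())
}
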