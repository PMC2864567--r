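#' @importFrom stats setNames rnorm rbinom
#' @importFrom utils unzip read.table
NULL

XG_VALUETYPES <- c("string", "text", "int", "decimal", "bool", "date",
                   "xref", "mref", "file")

#' Create a field definition
#'
#' A field is the atomic unit of the entity meta-model: a named, typed slot
#' of an entity. Reference types (`xref` for one-to-many, `mref` for
#' many-to-many) must name a target entity; all other types must not.
#'
#' @param name Field name (identifier: letters, digits, underscore).
#' @param valuetype One of `string`, `text`, `int`, `decimal`, `bool`,
#'   `date`, `xref`, `mref`, `file`.
#' @param target_entity Target entity name; required iff `valuetype` is
#'   `xref` or `mref`.
#' @param required Logical; must a value always be present?
#' @param description Optional free-text description.
#' @return An object of class `xg_field`.
#' @export
xg_field <- function(name, valuetype, target_entity = NULL, required = FALSE,
                     description = "") {
  if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", name))
    stop("invalid field name: '", name, "'")
  valuetype <- match.arg(valuetype, XG_VALUETYPES)
  is_ref <- valuetype %in% c("xref", "mref")
  if (is_ref && (is.null(target_entity) || !nzchar(target_entity)))
    stop("field '", name, "': valuetype ", valuetype,
         " requires a target entity")
  if (!is_ref && !is.null(target_entity))
    stop("field '", name, "': target entity only allowed for xref/mref")
  structure(list(name = name, valuetype = valuetype,
                 target_entity = if (is_ref) target_entity else NULL,
                 required = isTRUE(required),
                 description = as.character(description)),
            class = "xg_field")
}

#' Create an entity definition
#'
#' @param name Entity name (identifier; case-sensitive).
#' @param fields List of [xg_field()] objects declared on this entity
#'   (not including inherited or interface fields).
#' @param extends Name of the single parent entity, or `NULL`.
#' @param implements Character vector of interface names.
#' @param is_interface Logical; interfaces contribute fields to implementing
#'   entities but are never instantiated and get no file or table.
#' @return An object of class `xg_entity`.
#' @export
xg_entity <- function(name, fields = list(), extends = NULL,
                      implements = character(), is_interface = FALSE) {
  if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", name))
    stop("invalid entity name: '", name, "'")
  stopifnot(all(vapply(fields, inherits, logical(1), "xg_field")))
  fn <- vapply(fields, `[[`, character(1), "name")
  if (anyDuplicated(fn))
    stop("entity '", name, "': duplicate field name '",
         fn[duplicated(fn)][1], "'")
  structure(list(name = name, extends = extends,
                 implements = as.character(implements),
                 is_interface = isTRUE(is_interface),
                 fields = setNames(fields, fn)),
            class = "xg_entity")
}

#' Assemble a model schema from entity definitions
#'
#' Validates the meta-model invariants: unique entity names, resolvable
#' `extends`/`implements`/reference targets, an acyclic inheritance graph,
#' interface-only implements targets, and non-interface reference targets.
#'
#' @param entities List of [xg_entity()] objects, in declaration order.
#' @return An object of class `xg_model`.
#' @export
xg_model <- function(entities = list()) {
  stopifnot(all(vapply(entities, inherits, logical(1), "xg_entity")))
  nm <- vapply(entities, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicate entity name: '", nm[duplicated(nm)][1], "'")
  model <- structure(list(entities = setNames(entities, nm)),
                     class = "xg_model")
  validate_model(model)
  model
}

validate_model <- function(model) {
  ents <- model$entities
  nm <- names(ents)
  for (e in ents) {
    if (!is.null(e$extends)) {
      if (!e$extends %in% nm)
        stop("entity '", e$name, "' extends unknown entity '", e$extends, "'")
      if (ents[[e$extends]]$is_interface)
        stop("entity '", e$name, "' cannot extend interface '",
             e$extends, "'")
    }
    for (i in e$implements) {
      if (!i %in% nm)
        stop("entity '", e$name, "' implements unknown interface '", i, "'")
      if (!ents[[i]]$is_interface)
        stop("entity '", e$name, "' implements non-interface '", i, "'")
    }
    for (f in e$fields) {
      if (!is.null(f$target_entity)) {
        if (!f$target_entity %in% nm)
          stop("entity '", e$name, "', field '", f$name,
               "': unknown target entity '", f$target_entity, "'")
        if (ents[[f$target_entity]]$is_interface)
          stop("entity '", e$name, "', field '", f$name,
               "': reference target may not be an interface")
      }
    }
  }
  # inheritance graph (extends + implements) must be acyclic
  for (start in nm) {
    seen <- character()
    stack <- start
    while (length(stack)) {
      cur <- stack[1]; stack <- stack[-1]
      if (cur %in% seen) next
      seen <- c(seen, cur)
      e <- ents[[cur]]
      up <- c(e$extends, e$implements)
      if (start %in% up)
        stop("inheritance cycle involving entity '", start, "'")
      stack <- c(stack, up)
    }
  }
  # duplicate names in the flattened view are caught here
  for (e in ents) flatten_fields(model, e$name)
  invisible(model)
}

#' List the ancestors of an entity (root first)
#'
#' @param model An [xg_model()].
#' @param entity Entity name.
#' @return Character vector of ancestor names, root ancestor first, not
#'   including `entity` itself.
#' @export
entity_ancestors <- function(model, entity) {
  e <- get_entity(model, entity)
  out <- character()
  while (!is.null(e$extends)) {
    out <- c(e$extends, out)
    e <- model$entities[[e$extends]]
  }
  out
}

get_entity <- function(model, entity) {
  e <- model$entities[[entity]]
  if (is.null(e)) stop("unknown entity: '", entity, "'")
  e
}

#' Flatten the field list of an entity
#'
#' Returns the full field list an instance of `entity` carries: fields of
#' all ancestors (root ancestor first, in declaration order), then fields
#' contributed by implemented interfaces (in ancestry-then-declaration
#' order) that are not already present, then the entity's own fields.
#' Duplicate names keep their first occurrence.
#'
#' @inheritParams entity_ancestors
#' @return Named list of [xg_field()] objects in canonical order.
#' @export
flatten_fields <- function(model, entity) {
  chain <- c(entity_ancestors(model, entity), entity)
  own <- list()
  for (nm in chain) own <- c(own, model$entities[[nm]]$fields)
  ifaces <- character()
  for (nm in chain) ifaces <- c(ifaces, model$entities[[nm]]$implements)
  iface_fields <- list()
  for (i in unique(ifaces))
    iface_fields <- c(iface_fields, flatten_fields(model, i))
  # interface fields slot in between inherited fields and the entity's own
  self_own <- model$entities[[entity]]$fields
  inherited <- own[seq_len(length(own) - length(self_own))]
  merged <- c(inherited, iface_fields, self_own)
  merged[!duplicated(names(merged))]
}

#' Names of concrete (non-interface) entities
#' @inheritParams entity_ancestors
#' @return Character vector in declaration order.
#' @export
concrete_entities <- function(model) {
  keep <- !vapply(model$entities, `[[`, logical(1), "is_interface")
  names(model$entities)[keep]
}

#' Test whether one entity is (a descendant of) another
#' @inheritParams entity_ancestors
#' @param ancestor Candidate ancestor (or interface) name.
#' @return Logical.
#' @export
entity_is_a <- function(model, entity, ancestor) {
  if (identical(entity, ancestor)) return(TRUE)
  e <- get_entity(model, entity)
  chain <- c(entity_ancestors(model, entity), entity)
  ancestor %in% chain ||
    ancestor %in% unlist(lapply(chain,
      function(nm) model$entities[[nm]]$implements))
}

#' Concrete descendants of an entity (including itself if concrete)
#' @inheritParams entity_is_a
#' @param entity Entity or interface name.
#' @return Character vector of concrete entity names.
#' @export
concrete_descendants <- function(model, entity) {
  cand <- concrete_entities(model)
  cand[vapply(cand, function(x) entity_is_a(model, x, entity), logical(1))]
}

# ---------------------------------------------------------------------------
# Model DSL
#
# One declaration per block:
#   entity Name [extends Parent] [implements A, B]
#     field: valuetype [-> Target] [, required]   # description
#   interface Name
#     ...
# '#' starts a comment; blank lines separate nothing in particular.
# ---------------------------------------------------------------------------

#' Parse a model definition written in the model DSL
#'
#' The syntax is line-oriented: an `entity Name` or `interface Name` header
#' (optionally `extends Parent` and/or `implements A, B`), followed by
#' indented field lines of the form `name: valuetype [-> Target]
#' [, required]`. A trailing `# text` on a field line becomes the field
#' description; `#` at line start is a comment.
#'
#' @param text Character scalar (the whole document) or character vector of
#'   lines. Use [parse_model_file()] to read from disk.
#' @return An [xg_model()]; entity declaration order is preserved.
#' @export
parse_model <- function(text) {
  lines <- if (length(text) == 1 && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1]] else as.character(text)
  entities <- list()
  cur <- NULL  # list(name, extends, implements, is_interface, fields)
  flush <- function() {
    if (is.null(cur)) return()
    entities[[length(entities) + 1]] <<-
      xg_entity(cur$name, cur$fields, cur$extends, cur$implements,
                cur$is_interface)
  }
  head_re <- paste0("^(entity|interface)\\s+([A-Za-z_][A-Za-z0-9_]*)",
                    "(\\s+extends\\s+([A-Za-z_][A-Za-z0-9_]*))?",
                    "(\\s+implements\\s+([A-Za-z0-9_,\\s]+?))?\\s*$")
  field_re <- paste0("^\\s+([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*([a-z]+)",
                     "(\\s*->\\s*([A-Za-z_][A-Za-z0-9_]*))?",
                     "(\\s*,\\s*required)?",
                     "(\\s*#\\s*(.*))?\\s*$")
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^\\s*(#|$)", ln)) next
    if (grepl("^\\S", ln)) {
      m <- regmatches(ln, regexec(head_re, ln))[[1]]
      if (!length(m))
        stop("model DSL syntax error at line ", i, ": '", trimws(ln), "'")
      flush()
      impl <- if (nzchar(m[7]))
        trimws(strsplit(m[7], ",")[[1]]) else character()
      cur <- list(name = m[3],
                  extends = if (nzchar(m[5])) m[5] else NULL,
                  implements = impl[nzchar(impl)],
                  is_interface = m[2] == "interface",
                  fields = list())
    } else {
      if (is.null(cur))
        stop("model DSL syntax error at line ", i,
             ": field outside an entity block")
      m <- regmatches(ln, regexec(field_re, ln))[[1]]
      if (!length(m))
        stop("model DSL syntax error at line ", i, ": '", trimws(ln), "'")
      if (!m[3] %in% XG_VALUETYPES)
        stop("model DSL error at line ", i, ": unknown valuetype '",
             m[3], "'")
      f <- xg_field(m[2], m[3],
                    target_entity = if (nzchar(m[5])) m[5] else NULL,
                    required = nzchar(m[6]),
                    description = if (length(m) >= 8) m[8] else "")
      cur$fields[[length(cur$fields) + 1]] <- f
    }
  }
  flush()
  xg_model(entities)
}

#' @rdname parse_model
#' @param path Path to a model-DSL file (UTF-8).
#' @export
parse_model_file <- function(path) {
  parse_model(readLines(path, encoding = "UTF-8", warn = FALSE))
}

#' Serialize a model to its DSL text
#'
#' `parse_model(write_model(m))` reproduces `m` exactly.
#'
#' @inheritParams entity_ancestors
#' @param path Optional file path; when given, the text is also written
#'   there.
#' @return The DSL document as a single character scalar (invisibly when
#'   `path` is given).
#' @export
write_model <- function(model, path = NULL) {
  out <- character()
  for (e in model$entities) {
    hd <- paste0(if (e$is_interface) "interface " else "entity ", e$name)
    if (!is.null(e$extends)) hd <- paste0(hd, " extends ", e$extends)
    if (length(e$implements))
      hd <- paste0(hd, " implements ", paste(e$implements, collapse = ", "))
    out <- c(out, hd)
    for (f in e$fields) {
      fl <- paste0("  ", f$name, ": ", f$valuetype)
      if (!is.null(f$target_entity))
        fl <- paste0(fl, " -> ", f$target_entity)
      if (f$required) fl <- paste0(fl, ", required")
      if (nzchar(f$description)) fl <- paste0(fl, "  # ", f$description)
      out <- c(out, fl)
    }
    out <- c(out, "")
  }
  txt <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

#' @export
print.xg_model <- function(x, ...) {
  cat("<xg_model> ", length(x$entities), " entities\n", sep = "")
  for (e in x$entities) {
    tag <- if (e$is_interface) "interface" else "entity"
    cat(sprintf("  %s %s%s%s (%d fields)\n", tag, e$name,
                if (!is.null(e$extends)) paste0(" extends ", e$extends)
                else "",
                if (length(e$implements))
                  paste0(" implements ", paste(e$implements, collapse = ","))
                else "",
                length(e$fields)))
  }
  invisible(x)
}

#' @export
print.xg_field <- function(x, ...) {
  cat("<xg_field> ", x$name, ": ", x$valuetype,
      if (!is.null(x$target_entity)) paste0(" -> ", x$target_entity) else "",
      if (x$required) ", required" else "", "\n", sep = "")
  invisible(x)
}
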