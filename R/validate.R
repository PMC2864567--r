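# Referential and structural validation of bundles.
#
# The validator is what keeps "orphaned" data out of the store: every
# cross-reference must resolve, matrix dimension names must match
# annotation records of the declared row/column type, required fields
# must be present, names must be unique, and declared value types must
# hold. Findings are data, not conditions: import decides what to do.
#
# Location grammar (stable, used verbatim by the defect injector):
#   <entity>[<row>].<field>      a cell of an annotation table (1-based row)
#   <entity>:name=<name>         a duplicated record name
#   <matrix>[<row>,<col>]        a matrix cell (by names)
#   <matrix>[row:<name>]         a matrix row name; likewise [col:<name>]
#   <matrix>                     a whole matrix

XG_FINDING_KINDS <- c("unresolved_reference", "duplicate_name",
                      "missing_required", "type_mismatch",
                      "matrix_name_mismatch", "undeclared_matrix",
                      "missing_matrix", "ragged", "unknown_column")

new_report <- function() {
  data.frame(severity = character(), kind = character(),
             location = character(), message = character(),
             stringsAsFactors = FALSE)
}

add_finding <- function(report, severity, kind, location, message) {
  stopifnot(kind %in% XG_FINDING_KINDS)
  report[nrow(report) + 1, ] <- c(severity, kind, location, message)
  report
}

#' Is a validation report free of errors?
#'
#' @param report A report from [validate_bundle()].
#' @return Logical; `TRUE` iff the report has no error-severity findings
#'   (warnings never block).
#' @export
is_valid <- function(report) {
  !any(report$severity == "error")
}

#' @export
print.xg_validation_report <- function(x, ...) {
  cat("<validation report> ", sum(x$severity == "error"), " error(s), ",
      sum(x$severity == "warning"), " warning(s)\n", sep = "")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  [%s] %s at %s: %s\n", x$severity[i], x$kind[i],
                x$location[i], x$message[i]))
  invisible(x)
}

parses_as <- function(v, valuetype) {
  switch(valuetype,
    int = grepl("^[+-]?[0-9]+$", v),
    decimal = !is.na(suppressWarnings(as.numeric(v))),
    bool = v %in% c("true", "false", "TRUE", "FALSE", "0", "1"),
    date = !is.na(suppressWarnings(as.Date(v, format = "%Y-%m-%d"))),
    rep(TRUE, length(v)))
}

ANNOTATABLE_ROOTS <- c("DimensionElement", "Investigation", "Protocol",
                       "ProtocolApplication", "Data")

#' Validate a bundle against a model
#'
#' Performs the complete pre-import consistency check: required fields,
#' value types, name uniqueness per concrete entity and investigation,
#' xref/mref resolution (against the bundle, and the store when one is
#' given), annotation-target resolution, matrix declarations, matrix
#' dimension names against the declared rowtype/coltype records, and
#' matrix value types. Deterministic: the same bundle always yields the
#' same findings in the same order.
#'
#' @param bundle An [xg_bundle()].
#' @param model The governing [xg_model()].
#' @param store Optional open store; its records are included as
#'   resolution targets so bundles can extend stored investigations.
#' @return A data.frame of findings (classes `xg_validation_report`,
#'   `data.frame`) with columns severity, kind, location, message.
#' @export
validate_bundle <- function(bundle, model = builtin_model(), store = NULL) {
  rep <- new_report()
  lo <- load_order(model)$order
  # name lookup per concrete entity: bundle names plus store names
  name_cache <- new.env(parent = emptyenv())
  names_of <- function(entity) {
    hit <- name_cache[[entity]]
    if (!is.null(hit)) return(hit)
    out <- character()
    df <- bundle$records[[entity]]
    if (!is.null(df) && "name" %in% names(df))
      out <- df$name[!is.na(df$name) & nzchar(df$name)]
    if (!is.null(store))
      out <- c(out, store_names(store, entity))
    name_cache[[entity]] <- out
    out
  }
  desc_cache <- new.env(parent = emptyenv())
  resolve_pool <- function(target) {
    hit <- desc_cache[[target]]
    if (!is.null(hit)) return(hit)
    out <- unique(unlist(lapply(concrete_descendants(model, target),
                                names_of)))
    if (is.null(out)) out <- character()
    desc_cache[[target]] <- out
    out
  }
  resolves <- function(target, value) value %in% resolve_pool(target)
  for (entity in lo) {
    df <- bundle$records[[entity]]
    if (is.null(df) || !nrow(df)) next
    ff <- flatten_fields(model, entity)
    has_target <- all(c("target_entity", "target_name") %in% names(ff))
    for (i in seq_len(nrow(df))) {
      for (f in ff) {
        v <- if (f$name %in% names(df)) df[[f$name]][i] else NA_character_
        loc <- sprintf("%s[%d].%s", entity, i, f$name)
        if (is.na(v) || !nzchar(v)) {
          if (f$required)
            rep <- add_finding(rep, "error", "missing_required", loc,
                               paste0("required field '", f$name,
                                      "' is missing"))
          next
        }
        if (f$valuetype %in% c("int", "decimal", "bool", "date") &&
            !parses_as(v, f$valuetype)) {
          rep <- add_finding(rep, "error", "type_mismatch", loc,
                             sprintf("value '%s' is not a valid %s", v,
                                     f$valuetype))
          next
        }
        if (f$valuetype == "xref" && !resolves(f$target_entity, v))
          rep <- add_finding(rep, "error", "unresolved_reference", loc,
                             sprintf("no %s named '%s'", f$target_entity, v))
        if (f$valuetype == "mref") {
          for (member in trimws(strsplit(v, ",", fixed = TRUE)[[1]]))
            if (nzchar(member) && !resolves(f$target_entity, member))
              rep <- add_finding(rep, "error", "unresolved_reference",
                                 paste0(loc, ":", member),
                                 sprintf("no %s named '%s'",
                                         f$target_entity, member))
        }
      }
      if (has_target) {
        te <- df$target_entity[i]; tn <- df$target_name[i]
        if (!is.na(te) && nzchar(te)) {
          ok_type <- te %in% concrete_entities(model) &&
            any(vapply(ANNOTATABLE_ROOTS, function(r)
              entity_is_a(model, te, r), logical(1)))
          if (!ok_type) {
            rep <- add_finding(rep, "error", "unresolved_reference",
                               sprintf("%s[%d].target_entity", entity, i),
                               sprintf("'%s' is not an annotatable entity",
                                       te))
          } else if (!is.na(tn) && nzchar(tn) && !resolves(te, tn)) {
            rep <- add_finding(rep, "error", "unresolved_reference",
                               sprintf("%s[%d].target_name", entity, i),
                               sprintf("no %s named '%s'", te, tn))
          }
        }
      }
      # genome coordinates must be ordered when both ends are present
      if (all(c("bp_start", "bp_end") %in% names(df))) {
        bs <- df$bp_start[i]; be <- df$bp_end[i]
        if (!is.na(bs) && !is.na(be) && parses_as(bs, "int") &&
            parses_as(be, "int") &&
            as.numeric(bs) > as.numeric(be))
          rep <- add_finding(rep, "warning", "type_mismatch",
                             sprintf("%s[%d].bp_start", entity, i),
                             "bp_start exceeds bp_end")
      }
    }
    # duplicate names, scoped per concrete entity and investigation
    if ("name" %in% names(df)) {
      scope <- if ("investigation_name" %in% names(df))
        ifelse(is.na(df$investigation_name), "", df$investigation_name)
      else ""
      key <- paste0(scope, "\r", df$name)
      key[is.na(df$name)] <- NA
      dup <- unique(df$name[!is.na(key) & duplicated(key)])
      for (nm in dup)
        rep <- add_finding(rep, "error", "duplicate_name",
                           sprintf("%s:name=%s", entity, nm),
                           sprintf("name '%s' occurs more than once", nm))
    }
  }
  # Data declarations and matrices
  ddf <- bundle$records[["Data"]]
  dim_entities <- concrete_descendants(model, "DimensionElement")
  if (!is.null(ddf) && nrow(ddf)) {
    for (i in seq_len(nrow(ddf))) {
      for (col in c("rowtype", "coltype")) {
        v <- ddf[[col]][i]
        if (!is.na(v) && nzchar(v) && !v %in% dim_entities)
          rep <- add_finding(rep, "error", "type_mismatch",
                             sprintf("Data[%d].%s", i, col),
                             sprintf(
                               "'%s' is not a DimensionElement variant", v))
      }
      vt <- ddf$valuetype[i]
      if (!is.na(vt) && nzchar(vt) && !vt %in% c("decimal", "text"))
        rep <- add_finding(rep, "error", "type_mismatch",
                           sprintf("Data[%d].valuetype", i),
                           sprintf("'%s' is not 'decimal' or 'text'", vt))
    }
    declared <- ddf$name[!is.na(ddf$name)]
    for (i in which(!is.na(ddf$name))) {
      if (!ddf$name[i] %in% names(bundle$matrices))
        rep <- add_finding(rep, "error", "missing_matrix", ddf$name[i],
                           sprintf("Data '%s' has no matrix", ddf$name[i]))
    }
  } else declared <- character()
  for (mn in setdiff(names(bundle$matrices), declared))
    rep <- add_finding(rep, "error", "undeclared_matrix", mn,
                       sprintf("matrix '%s' has no Data record", mn))
  for (mn in intersect(declared, names(bundle$matrices))) {
    m <- bundle$matrices[[mn]]
    i <- match(mn, ddf$name)
    for (axis in c("row", "col")) {
      tp <- ddf[[paste0(axis, "type")]][i]
      if (is.na(tp) || !tp %in% dim_entities) next  # unreported/reported above
      nms <- if (axis == "row") rownames(m$values) else colnames(m$values)
      known <- resolve_pool(tp)
      for (nm in setdiff(nms, known))
        rep <- add_finding(rep, "error", "matrix_name_mismatch",
                           sprintf("%s[%s:%s]", mn, axis, nm),
                           sprintf("%s name '%s' matches no %s record",
                                   axis, nm, tp))
    }
    vt <- ddf$valuetype[i]
    if (!is.na(vt) && vt == "decimal" && m$valuetype == "text") {
      v <- m$values
      bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))),
                   arr.ind = TRUE)
      for (k in seq_len(nrow(bad)))
        rep <- add_finding(rep, "error", "type_mismatch",
                           sprintf("%s[%s,%s]", mn,
                                   rownames(v)[bad[k, 1]],
                                   colnames(v)[bad[k, 2]]),
                           sprintf("non-numeric value '%s' in decimal matrix",
                                   v[bad[k, 1], bad[k, 2]]))
    }
  }
  class(rep) <- c("xg_validation_report", "data.frame")
  rep
}
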