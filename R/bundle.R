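# In-memory containers: DataMatrix and Bundle.

#' Create a data matrix
#'
#' A named matrix of observations whose row and column names refer to
#' records of the two `DimensionElement` variants declared by the matching
#' `Data` record (e.g. Probe rows by Individual columns for expression
#' data). A cell is one observation (a DataElement); missing cells are
#' `NA`.
#'
#' @param name Matrix name; must match a `Data` record name in a bundle.
#' @param values A matrix with unique, non-empty `dimnames`: numeric when
#'   `valuetype` is `"decimal"`, character when `"text"`.
#' @param valuetype `"decimal"` or `"text"`.
#' @return An object of class `xg_matrix`.
#' @export
data_matrix <- function(name, values, valuetype = c("decimal", "text")) {
  valuetype <- match.arg(valuetype)
  stopifnot(is.matrix(values))
  dn <- dimnames(values)
  if ((nrow(values) > 0 && is.null(dn[[1]])) ||
      (ncol(values) > 0 && is.null(dn[[2]])))
    stop("matrix '", name, "': row and column names are required")
  if (anyDuplicated(dn[[1]]))
    stop("matrix '", name, "': duplicate row name '",
         dn[[1]][duplicated(dn[[1]])][1], "'")
  if (anyDuplicated(dn[[2]]))
    stop("matrix '", name, "': duplicate column name '",
         dn[[2]][duplicated(dn[[2]])][1], "'")
  if (valuetype == "decimal") storage.mode(values) <- "double"
  else storage.mode(values) <- "character"
  structure(list(name = name, values = values, valuetype = valuetype),
            class = "xg_matrix")
}

#' @export
print.xg_matrix <- function(x, ...) {
  cat(sprintf("<xg_matrix> '%s' %d x %d (%s)\n", x$name,
              nrow(x$values), ncol(x$values), x$valuetype))
  invisible(x)
}

#' Create an investigation bundle
#'
#' A bundle is the in-memory form of one XGAP-TAB directory: record tables
#' per concrete entity, data matrices, constants, and the unparsed
#' `original/` files.
#'
#' @param records Named list: concrete entity name -> data.frame of
#'   records (all columns character; `NA` = missing).
#' @param matrices Named list of [data_matrix()] objects, keyed by name.
#' @param constants Named character vector (the `constant.properties`
#'   key=value pairs).
#' @param original_files Named list of raw vectors keyed by path relative
#'   to `original/`; carried verbatim, never parsed.
#' @return An object of class `xg_bundle`.
#' @export
xg_bundle <- function(records = list(), matrices = list(),
                      constants = character(), original_files = list()) {
  if (length(matrices)) {
    nm <- vapply(matrices, `[[`, character(1), "name")
    names(matrices) <- nm
    if (anyDuplicated(nm)) stop("duplicate matrix name")
  }
  if (anyDuplicated(names(constants))) stop("duplicate constant key")
  structure(list(records = records, matrices = matrices,
                 constants = constants, original_files = original_files),
            class = "xg_bundle")
}

#' @export
print.xg_bundle <- function(x, ...) {
  n <- vapply(x$records, nrow, integer(1))
  n <- n[n > 0]
  cat("<xg_bundle>\n  records: ",
      if (length(n)) paste0(names(n), "(", n, ")", collapse = " ")
      else "none", "\n", sep = "")
  for (m in x$matrices)
    cat(sprintf("  matrix '%s': %d x %d (%s)\n", m$name, nrow(m$values),
                ncol(m$values), m$valuetype))
  if (length(x$constants))
    cat("  constants: ", paste(names(x$constants), collapse = ", "), "\n",
        sep = "")
  if (length(x$original_files))
    cat("  original/: ", length(x$original_files), " file(s)\n", sep = "")
  invisible(x)
}

empty_records <- function(columns) {
  as.data.frame(setNames(rep(list(character()), length(columns)), columns),
                stringsAsFactors = FALSE, check.names = FALSE)
}

#' Records of one entity in a bundle
#'
#' @param bundle An [xg_bundle()].
#' @param entity Concrete entity name.
#' @return The records data.frame (zero rows if the bundle has none).
#' @export
bundle_records <- function(bundle, entity) {
  r <- bundle$records[[entity]]
  if (is.null(r)) empty_records("name") else r
}

#' Canonicalize a bundle against a model
#'
#' Puts a bundle into the unique form the writer emits: entity tables in
#' load order with the full canonical column set (in flattened-field
#' order), zero-row tables dropped, row names stripped, matrices keyed and
#' ordered by `Data` record order with rows/columns reordered to the
#' annotation-file record order of their rowtype/coltype.
#'
#' @param bundle An [xg_bundle()].
#' @param model The governing [xg_model()].
#' @return A canonical [xg_bundle()].
#' @export
canonicalize_bundle <- function(bundle, model) {
  spec <- derive_format_spec(model)
  lo <- load_order(model)$order
  records <- list()
  for (entity in lo) {
    df <- bundle$records[[entity]]
    if (is.null(df) || nrow(df) == 0) next
    cols <- spec$files[[entity]]$columns
    vals <- lapply(cols, function(cn) {
      v <- if (cn %in% names(df)) as.character(df[[cn]])
        else rep(NA_character_, nrow(df))
      v[!is.na(v) & !nzchar(v)] <- NA_character_  # empty string == missing
      v
    })
    out <- as.data.frame(setNames(vals, cols), stringsAsFactors = FALSE,
                         check.names = FALSE)
    rownames(out) <- NULL
    records[[entity]] <- out
  }
  dimorder <- function(entity) {
    df <- records[[entity]]
    if (is.null(df)) character() else df$name[!is.na(df$name)]
  }
  matrices <- list()
  ddf <- records[["Data"]]
  mat_names <- c(intersect(if (is.null(ddf)) character() else ddf$name,
                           names(bundle$matrices)),
                 setdiff(names(bundle$matrices),
                         if (is.null(ddf)) character() else ddf$name))
  for (mn in mat_names) {
    m <- bundle$matrices[[mn]]
    decl <- if (!is.null(ddf) && mn %in% ddf$name)
      ddf[match(mn, ddf$name), ] else NULL
    v <- m$values
    if (!is.null(decl)) {
      ro <- intersect(dimorder(decl$rowtype), rownames(v))
      co <- intersect(dimorder(decl$coltype), colnames(v))
      v <- v[c(ro, setdiff(rownames(v), ro)),
             c(co, setdiff(colnames(v), co)), drop = FALSE]
    }
    matrices[[mn]] <- data_matrix(mn, v, m$valuetype)
  }
  const <- if (length(bundle$constants))
    bundle$constants[order(names(bundle$constants))] else character()
  orig <- if (length(bundle$original_files))
    bundle$original_files[order(names(bundle$original_files))] else list()
  xg_bundle(records, matrices, const, orig)
}

#' Compare two bundles for equality of content
#'
#' Both bundles are canonicalized against `model` first, so record order
#' inside a table, matrix row/column order and column sets are compared in
#' canonical form.
#'
#' @param a,b Bundles.
#' @param model The governing [xg_model()].
#' @param ignore_original Skip the `original/` file payloads?
#' @return Logical.
#' @export
bundle_equal <- function(a, b, model, ignore_original = FALSE) {
  ca <- canonicalize_bundle(a, model)
  cb <- canonicalize_bundle(b, model)
  if (ignore_original) ca$original_files <- cb$original_files <- list()
  isTRUE(all.equal(unclass(ca), unclass(cb), tolerance = 0,
                   check.attributes = TRUE))
}
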