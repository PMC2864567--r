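# XGAP-TAB file dialect.
#
# UTF-8, tab-delimited, LF line ends, header row, no quoting. In-cell
# tab, newline and backslash are escaped as \t, \n, \\. An empty cell is a
# missing value; "NA" is additionally accepted on read in lax mode. A
# bundle directory holds one annotation file per concrete entity (lowered
# entity name + ".txt"; the Data declarations land in data.txt), matrix
# files under data/<name>.txt, key=value pairs in constant.properties and
# unparsed raw inputs under original/.

escape_cell <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

unescape_cell <- function(x) {
  # single left-to-right pass so "\\t" stays a literal backslash + t
  vapply(x, function(s) {
    if (!grepl("\\", s, fixed = TRUE)) return(s)
    parts <- strsplit(s, "", fixed = TRUE)[[1]]
    out <- character(0); i <- 1L; n <- length(parts)
    while (i <= n) {
      ch <- parts[i]
      if (ch == "\\" && i < n) {
        nxt <- parts[i + 1L]
        out <- c(out, switch(nxt, t = "\t", n = "\n", "\\" = "\\",
                             paste0("\\", nxt)))
        i <- i + 2L
      } else {
        out <- c(out, ch); i <- i + 1L
      }
    }
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

read_tab_lines <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  # sentinel keeps trailing empty cells, which strsplit would drop
  cells <- strsplit(paste0(lines, "\x01"), "\t", fixed = TRUE)
  lapply(cells, function(x) {
    x[length(x)] <- sub("\x01$", "", x[length(x)])
    x
  })
}

cells_to_values <- function(cells, lax = FALSE) {
  v <- unescape_cell(cells)
  v[!nzchar(v)] <- NA_character_
  if (lax) v[v %in% "NA"] <- NA_character_
  v
}

value_to_cell <- function(v) {
  v[is.na(v)] <- ""
  escape_cell(v)
}

# shortest representation of a double that survives as.numeric() exactly
fmt_decimal <- function(x) {
  out <- as.character(x)
  out[is.na(x)] <- NA_character_
  bad <- !is.na(x) & (is.na(suppressWarnings(as.numeric(out))) |
                        suppressWarnings(as.numeric(out)) != x)
  out[bad] <- sprintf("%.17g", x[bad])
  out
}

#' Read a tab-delimited entity annotation file
#'
#' @param path File path.
#' @param columns Expected column names (the entity's flattened fields).
#' @param required Names of columns that must be present in the header.
#' @param lax Tolerate unknown header columns (dropped with a warning) and
#'   accept the token `NA` as a missing value.
#' @return data.frame with exactly `columns` as character columns, one row
#'   per data line; empty cells are `NA`.
#' @export
read_entity_file <- function(path, columns, required = character(),
                             lax = FALSE) {
  rows <- read_tab_lines(path)
  if (!length(rows))
    return(empty_records(columns))
  header <- unescape_cell(rows[[1]])
  unknown <- setdiff(header, columns)
  if (length(unknown)) {
    if (!lax)
      stop(basename(path), ": unknown column(s): ",
           paste(unknown, collapse = ", "))
    warning(basename(path), ": ignoring unknown column(s): ",
            paste(unknown, collapse = ", "))
  }
  miss <- setdiff(required, header)
  if (length(miss))
    stop(basename(path), ": missing required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(header))
    stop(basename(path), ": duplicate header column '",
         header[duplicated(header)][1], "'")
  body <- rows[-1]
  nc <- length(header)
  for (i in seq_along(body)) {
    if (length(body[[i]]) != nc)
      stop(basename(path), ": ragged row at line ", i + 1, " (",
           length(body[[i]]), " cells, expected ", nc, ")")
  }
  grid <- if (length(body))
    matrix(cells_to_values(unlist(body), lax = lax), ncol = nc,
           byrow = TRUE)
  else matrix(character(), ncol = nc)
  n <- nrow(grid)
  vals <- lapply(columns, function(cn) {
    j <- match(cn, header)
    if (is.na(j)) rep(NA_character_, n) else grid[, j]
  })
  as.data.frame(setNames(vals, columns), stringsAsFactors = FALSE,
                check.names = FALSE)
}

#' Write a tab-delimited entity annotation file
#'
#' Inverse of [read_entity_file()]: `read_entity_file(write_entity_file(r))`
#' recovers `r` exactly, including cells containing tabs or newlines.
#'
#' @param records data.frame of records (character cells; `NA` = missing).
#' @param columns Column names to emit, in order.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_entity_file <- function(records, columns, path) {
  lines <- paste(escape_cell(columns), collapse = "\t")
  if (nrow(records)) {
    cells <- vapply(columns, function(cn) {
      v <- if (cn %in% names(records)) as.character(records[[cn]])
        else rep(NA_character_, nrow(records))
      value_to_cell(v)
    }, character(nrow(records)))
    cells <- matrix(cells, nrow = nrow(records))
    lines <- c(lines, apply(cells, 1, paste, collapse = "\t"))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a matrix file
#'
#' First row: column names (the corner cell is ignored); first column: row
#' names; remaining cells: values.
#'
#' @param path File path.
#' @param name Matrix name (defaults to the file name without `.txt`).
#' @param valuetype `"decimal"` (cells parsed as numbers) or `"text"`.
#' @param lax Accept `NA` tokens as missing.
#' @return An [data_matrix()] object.
#' @export
read_matrix <- function(path, name = sub("\\.txt$", "", basename(path)),
                        valuetype = c("decimal", "text"), lax = FALSE) {
  valuetype <- match.arg(valuetype)
  rows <- read_tab_lines(path)
  if (!length(rows)) stop(basename(path), ": empty matrix file")
  header <- cells_to_values(rows[[1]], lax = lax)
  col_names <- as.character(header[-1])
  body <- rows[-1]
  nc <- length(col_names)
  row_names <- character(length(body))
  vals <- matrix(NA_character_, nrow = length(body), ncol = nc)
  for (i in seq_along(body)) {
    cells <- cells_to_values(body[[i]], lax = lax)
    if (length(cells) != nc + 1)
      stop(basename(path), ": ragged row at line ", i + 1)
    if (is.na(cells[1]))
      stop(basename(path), ": missing row name at line ", i + 1)
    row_names[i] <- cells[1]
    if (nc) vals[i, ] <- cells[-1]
  }
  if (anyDuplicated(row_names))
    stop(basename(path), ": duplicate row name '",
         row_names[duplicated(row_names)][1], "'")
  if (anyDuplicated(col_names))
    stop(basename(path), ": duplicate column name '",
         col_names[duplicated(col_names)][1], "'")
  if (valuetype == "decimal") {
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(is.na(num) & !is.na(vals))
    if (length(bad)) {
      i <- ((bad[1] - 1) %% nrow(vals)) + 1
      j <- ((bad[1] - 1) %/% nrow(vals)) + 1
      stop(basename(path), ": non-numeric cell '", vals[i, j],
           "' at row '", row_names[i], "', column '", col_names[j], "'")
    }
    vals <- matrix(num, nrow = length(body))
  }
  dimnames(vals) <- list(row_names, col_names)
  data_matrix(name, vals, valuetype)
}

#' Write a matrix file
#'
#' Inverse of [read_matrix()]; decimals are serialized with the shortest
#' representation that parses back to the same double, missing cells as
#' empty cells, and the corner cell empty.
#'
#' @param matrix An [data_matrix()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  v <- matrix$values
  cells <- if (matrix$valuetype == "decimal") fmt_decimal(v)
    else as.character(v)
  cells <- value_to_cell(cells)
  dim(cells) <- dim(v)
  lines <- paste(c("", escape_cell(colnames(v))), collapse = "\t")
  if (nrow(v))
    lines <- c(lines, vapply(seq_len(nrow(v)), function(i)
      paste(c(escape_cell(rownames(v)[i]), cells[i, ]), collapse = "\t"),
      character(1)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

read_constants <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|!|$)", lines)]
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 0)) stop(basename(path), ": line without '=' separator")
  keys <- trimws(substr(lines, 1, eq - 1))
  vals <- trimws(substring(lines, eq + 1))
  setNames(vals, keys)
}

write_constants <- function(constants, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste0(names(constants), "=", constants), con, sep = "\n",
             useBytes = TRUE)
  invisible(path)
}

#' Read an XGAP-TAB bundle from a directory or zip file
#'
#' Loads every annotation file present (per the model's derived format
#' spec; absent files mean zero records), the matrix declarations from
#' `data.txt`, each declared matrix from `data/<name>.txt`,
#' `constant.properties`, and the files under `original/` verbatim.
#'
#' @param path Bundle directory or `.zip` file.
#' @param model The governing [xg_model()].
#' @param lax Tolerate unknown columns, `NA` tokens, and
#'   declared-but-missing / present-but-undeclared matrix files (the
#'   latter are loaded as text matrices so validation can report them).
#' @return An [xg_bundle()].
#' @export
read_bundle <- function(path, model = builtin_model(), lax = FALSE) {
  if (file.exists(path) && !dir.exists(path)) {
    exdir <- tempfile("xgbundle")
    utils::unzip(path, exdir = exdir)
    # tolerate a single wrapping directory inside the zip
    entries <- list.files(exdir)
    if (length(entries) == 1 && dir.exists(file.path(exdir, entries)))
      exdir <- file.path(exdir, entries)
    on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
    return(read_bundle(exdir, model, lax = lax))
  }
  if (!dir.exists(path)) stop("no such bundle: '", path, "'")
  spec <- derive_format_spec(model)
  records <- list()
  for (entity in names(spec$files)) {
    f <- file.path(path, spec$files[[entity]]$file)
    if (!file.exists(f)) next
    ff <- flatten_fields(model, entity)
    req <- names(ff)[vapply(ff, `[[`, logical(1), "required")]
    records[[entity]] <- read_entity_file(f, spec$files[[entity]]$columns,
                                          required = req, lax = lax)
  }
  matrices <- list()
  ddf <- records[["Data"]]
  declared <- if (is.null(ddf)) character() else ddf$name[!is.na(ddf$name)]
  mdir <- file.path(path, spec$matrix_dir)
  present <- if (dir.exists(mdir))
    sub("\\.txt$", "", list.files(mdir, pattern = "\\.txt$")) else character()
  missing_m <- setdiff(declared, present)
  undeclared <- setdiff(present, declared)
  if (!lax && length(missing_m))
    stop("matrix declared in data.txt but file missing: ",
         paste0(spec$matrix_dir, "/", missing_m, ".txt", collapse = ", "))
  if (!lax && length(undeclared))
    stop("matrix file present but not declared in data.txt: ",
         paste0(spec$matrix_dir, "/", undeclared, ".txt", collapse = ", "))
  for (mn in present) {
    vt <- "text"
    if (mn %in% declared) {
      vtd <- ddf$valuetype[match(mn, ddf$name)]
      if (!is.na(vtd) && vtd %in% c("decimal", "text")) vt <- vtd
    }
    matrices[[mn]] <- read_matrix(file.path(mdir, paste0(mn, ".txt")),
                                  name = mn, valuetype = vt, lax = lax)
  }
  constants <- character()
  cp <- file.path(path, "constant.properties")
  if (file.exists(cp)) constants <- read_constants(cp)
  original <- list()
  odir <- file.path(path, "original")
  if (dir.exists(odir)) {
    for (f in list.files(odir, recursive = TRUE)) {
      fp <- file.path(odir, f)
      original[[f]] <- readBin(fp, "raw", n = file.size(fp))
    }
  }
  xg_bundle(records, matrices, constants, original)
}

#' Write an XGAP-TAB bundle to a directory or zip file
#'
#' Writes the canonical form (see [canonicalize_bundle()]): entity files
#' in load order (only non-empty ones), matrices under `data/`, constants
#' in `constant.properties`, and `original/` copied verbatim. Writing the
#' result of a read back out reproduces the canonical bytes exactly.
#'
#' @param bundle An [xg_bundle()].
#' @param path Output directory, or `.zip` path when `zip = TRUE`.
#' @param model The governing [xg_model()].
#' @param zip Write a zip archive instead of a directory.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path, model = builtin_model(),
                         zip = grepl("\\.zip$", path)) {
  b <- canonicalize_bundle(bundle, model)
  dir <- if (zip) tempfile("xgout") else path
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- derive_format_spec(model)
  for (entity in names(b$records)) {
    cols <- spec$files[[entity]]$columns
    write_entity_file(b$records[[entity]], cols,
                      file.path(dir, spec$files[[entity]]$file))
  }
  if (length(b$matrices)) {
    mdir <- file.path(dir, spec$matrix_dir)
    dir.create(mdir, showWarnings = FALSE)
    for (m in b$matrices)
      write_matrix(m, file.path(mdir, paste0(m$name, ".txt")))
  }
  if (length(b$constants))
    write_constants(b$constants, file.path(dir, "constant.properties"))
  for (f in names(b$original_files)) {
    fp <- file.path(dir, "original", f)
    dir.create(dirname(fp), recursive = TRUE, showWarnings = FALSE)
    writeBin(b$original_files[[f]], fp)
  }
  if (zip) {
    files <- list.files(dir, recursive = TRUE)
    write_zip(path, dir, files)
    unlink(dir, recursive = TRUE)
  }
  invisible(path)
}
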