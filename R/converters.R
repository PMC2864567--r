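# Converters: R/qtl-style cross CSV and PLINK-style PED/MAP.
#
# The cross CSV layout written here (and required back on read) is the
# single-file comma-separated form: individuals as rows; first column
# "id"; then phenotype columns; then one column per marker with two extra
# header rows under the marker names giving chromosome and cM position
# (blank under id/phenotypes). No quoting; cells must not contain commas.

#' Genotype code map
#'
#' Maps stored genotype codes to cross-format codes on export; the
#' derived inverse (preferring a code that maps to itself, otherwise the
#' first preimage in map order) is used on import, so recoding is
#' lossless for codes the map emits.
#'
#' @param forward Named character vector, stored code -> emitted code.
#' @param missing Code emitted for a missing genotype.
#' @return An object of class `xg_code_map`.
#' @export
genotype_code_map <- function(
    forward = c(AA = "A", AB = "H", BA = "H", BB = "B",
                A = "A", H = "H", B = "B"),
    missing = "-") {
  inverse <- character()
  for (code in unique(forward)) {
    pre <- names(forward)[forward == code]
    inverse[code] <- if (code %in% pre) code else pre[1]
  }
  structure(list(forward = forward, missing = missing, inverse = inverse),
            class = "xg_code_map")
}

recode_forward <- function(v, codes) {
  out <- rep(codes$missing, length(v))
  known <- !is.na(v)
  bad <- known & !v %in% names(codes$forward)
  if (any(bad))
    stop("unmappable genotype code(s): ",
         paste(unique(v[bad]), collapse = ", "))
  out[known] <- unname(codes$forward[v[known]])
  out
}

recode_inverse <- function(v, codes) {
  out <- rep(NA_character_, length(v))
  known <- !is.na(v) & nzchar(v) & v != codes$missing
  bad <- known & !v %in% names(codes$inverse)
  if (any(bad))
    stop("unmappable genotype code(s) on import: ",
         paste(unique(v[bad]), collapse = ", "))
  out[known] <- unname(codes$inverse[v[known]])
  out
}

#' Convert a bundle to an R/qtl-style cross CSV
#'
#' @param bundle An [xg_bundle()] holding a genotype matrix whose markers
#'   carry chromosome and cM map positions (Locus fields).
#' @param genotype_data Name of the genotype `Data` matrix (Marker by
#'   Individual/Strain in either orientation).
#' @param phenotype_data Character vector of phenotype `Data` names whose
#'   trait values become phenotype columns (may be empty).
#' @param codes A [genotype_code_map()].
#' @param model The governing [xg_model()].
#' @return Character vector of CSV lines.
#' @export
to_rqtl <- function(bundle, genotype_data, phenotype_data = character(),
                    codes = genotype_code_map(), model = builtin_model()) {
  ddf <- bundle$records[["Data"]]
  if (is.null(ddf) || !genotype_data %in% ddf$name)
    stop("no Data record named '", genotype_data, "'")
  decl <- ddf[match(genotype_data, ddf$name), ]
  m <- bundle$matrices[[genotype_data]]
  if (is.null(m)) stop("no matrix named '", genotype_data, "'")
  marker_axis <- if (entity_is_a(model, decl$rowtype, "Marker")) "row"
    else if (entity_is_a(model, decl$coltype, "Marker")) "col"
    else stop("matrix '", genotype_data, "' has no Marker axis")
  g <- if (marker_axis == "row") t(m$values) else m$values
  # g: individuals x markers
  markers <- colnames(g); individuals <- rownames(g)
  mrec <- bundle$records[[if (marker_axis == "row") decl$rowtype
                          else decl$coltype]]
  mi <- match(markers, mrec$name)
  if (anyNA(mi)) stop("marker(s) missing annotation record: ",
                      paste(markers[is.na(mi)], collapse = ", "))
  chr <- mrec$chromosome[mi]; cm <- mrec$cm[mi]
  if (any(is.na(chr)) || any(is.na(cm)))
    stop("marker(s) lacking chromosome or cM position: ",
         paste(markers[is.na(chr) | is.na(cm)], collapse = ", "))
  phen <- NULL
  for (pn in phenotype_data) {
    pd <- ddf[match(pn, ddf$name), ]
    pm <- bundle$matrices[[pn]]
    if (is.null(pm)) stop("no matrix named '", pn, "'")
    pv <- if (all(individuals %in% colnames(pm$values))) t(pm$values)
      else pm$values
    pv <- pv[individuals, , drop = FALSE]
    phen <- cbind(phen, pv)
  }
  pn_names <- colnames(phen)
  header <- c("id", pn_names, markers)
  l2 <- c("", rep("", length(pn_names)), chr)
  l3 <- c("", rep("", length(pn_names)),
          fmt_decimal(as.numeric(cm)))
  lines <- c(paste(header, collapse = ","), paste(l2, collapse = ","),
             paste(l3, collapse = ","))
  for (i in seq_along(individuals)) {
    ph <- if (is.null(phen)) character()
      else fmt_decimal(as.numeric(phen[i, ]))
    ph[is.na(ph)] <- ""
    gr <- recode_forward(g[i, ], codes)
    lines <- c(lines, paste(c(individuals[i], ph, gr), collapse = ","))
  }
  lines
}

#' Build a bundle from an R/qtl-style cross CSV
#'
#' Accepts the layout emitted by [to_rqtl()]: marker columns are those
#' with a non-empty chromosome in the second header row; an `id` column
#' names the individuals; remaining leading columns are phenotypes.
#'
#' @param csv Character vector of CSV lines, or a file path.
#' @param investigation_name Name for the created Investigation.
#' @param codes A [genotype_code_map()] (its inverse recodes genotypes).
#' @param model The governing [xg_model()].
#' @return An [xg_bundle()] with Marker and Individual records, a text
#'   genotype matrix `genotypes`, and (when phenotype columns exist) a
#'   decimal phenotype matrix `phenotypes` with one Trait per column.
#' @export
from_rqtl <- function(csv, investigation_name = "cross",
                      codes = genotype_code_map(),
                      model = builtin_model()) {
  lines <- if (length(csv) == 1 && file.exists(csv))
    readLines(csv, warn = FALSE) else csv
  if (length(lines) < 3) stop("cross CSV needs 2 map header rows")
  cells <- strsplit(paste0(lines, "\x01"), ",", fixed = TRUE)
  cells <- lapply(cells, function(x) {
    x[length(x)] <- sub("\x01$", "", x[length(x)]); trimws(x) })
  header <- cells[[1]]; chr_row <- cells[[2]]; cm_row <- cells[[3]]
  nc <- length(header)
  if (length(chr_row) != nc || length(cm_row) != nc)
    stop("malformed map header rows (cell counts differ from header)")
  is_marker <- nzchar(chr_row)
  if (!any(is_marker)) stop("no marker columns (empty chromosome row)")
  if (anyDuplicated(header[is_marker]))
    stop("duplicate marker name: ",
         header[is_marker][duplicated(header[is_marker])][1])
  id_col <- which(!is_marker & header == "id")[1]
  phen_cols <- setdiff(which(!is_marker),
                       if (is.na(id_col)) integer() else id_col)
  body <- cells[-(1:3)]
  body <- body[vapply(body, function(x) any(nzchar(x)), logical(1))]
  n <- length(body)
  for (i in seq_len(n))
    if (length(body[[i]]) != nc)
      stop("ragged CSV row at line ", i + 3)
  grid <- if (n) matrix(unlist(body), nrow = n, byrow = TRUE)
    else matrix(character(), ncol = nc)
  individuals <- if (!is.na(id_col)) grid[, id_col]
    else sprintf("ind%0*d", nchar(n), seq_len(n))
  markers <- header[is_marker]
  inv <- data.frame(name = investigation_name,
                    description = NA_character_, stringsAsFactors = FALSE)
  mrec <- data.frame(name = markers, type = NA_character_,
                     investigation_name = investigation_name,
                     chromosome = chr_row[is_marker],
                     bp_start = NA_character_, bp_end = NA_character_,
                     cm = fmt_decimal(as.numeric(cm_row[is_marker])),
                     stringsAsFactors = FALSE)
  irec <- data.frame(name = individuals, type = NA_character_,
                     investigation_name = investigation_name,
                     mother = NA_character_, father = NA_character_,
                     strain = NA_character_, stringsAsFactors = FALSE)
  g <- matrix(NA_character_, length(markers), n,
              dimnames = list(markers, individuals))
  mk_idx <- which(is_marker)
  for (j in seq_along(mk_idx))
    g[j, ] <- recode_inverse(grid[, mk_idx[j]], codes)
  records <- list(Investigation = inv, Marker = mrec, Individual = irec)
  matrices <- list(genotypes = data_matrix("genotypes", g, "text"))
  dat <- data.frame(name = "genotypes",
                    investigation_name = investigation_name,
                    rowtype = "Marker", coltype = "Individual",
                    valuetype = "text", stringsAsFactors = FALSE)
  if (length(phen_cols)) {
    trec <- data.frame(name = header[phen_cols], type = NA_character_,
                       investigation_name = investigation_name,
                       stringsAsFactors = FALSE)
    pv <- matrix(suppressWarnings(as.numeric(grid[, phen_cols])),
                 nrow = n,
                 dimnames = list(individuals, header[phen_cols]))
    records$Trait <- trec
    matrices$phenotypes <- data_matrix("phenotypes", t(pv), "decimal")
    dat <- rbind(dat, data.frame(
      name = "phenotypes", investigation_name = investigation_name,
      rowtype = "Trait", coltype = "Individual", valuetype = "decimal",
      stringsAsFactors = FALSE))
  }
  records$Data <- dat
  xg_bundle(records, matrices)
}

#' Build a bundle from PED/MAP genotype files
#'
#' MAP lines: chromosome, marker id, cM position, bp position. PED lines:
#' family, individual, father, mother, sex, phenotype, then two allele
#' columns per marker. Genotypes are stored unphased as `a1/a2` text
#' (`0/0` is missing); parent ids of `0` mean no reference, and a parent
#' id that names no individual in the file is dropped with a warning.
#' Family and sex are kept as a `Description` annotation per individual.
#'
#' @param ped,map Paths to the PED and MAP files (whitespace-delimited).
#' @param investigation_name Name for the created Investigation.
#' @param model The governing [xg_model()].
#' @return An [xg_bundle()] that passes [validate_bundle()] cleanly.
#' @export
from_pedmap <- function(ped, map, investigation_name = "pedmap",
                        model = builtin_model()) {
  mp <- read.table(map, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("chr", "id", "cm", "bp"),
                   colClasses = "character")
  if (anyDuplicated(mp$id))
    stop("duplicate marker id in MAP: ", mp$id[duplicated(mp$id)][1])
  pd <- read.table(ped, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  nmark <- nrow(mp)
  if (ncol(pd) != 6 + 2 * nmark)
    stop("PED has ", ncol(pd) - 6, " allele columns; expected ",
         2 * nmark, " (2 per marker)")
  fam <- pd[[1]]; ind <- pd[[2]]; father <- pd[[3]]; mother <- pd[[4]]
  sex <- pd[[5]]; phen <- pd[[6]]
  if (anyDuplicated(ind))
    stop("duplicate individual id in PED: ", ind[duplicated(ind)][1])
  fix_parent <- function(p, which) {
    out <- ifelse(p == "0", NA_character_, p)
    unknown <- !is.na(out) & !out %in% ind
    if (any(unknown)) {
      warning("unknown ", which, " id(s) in PED kept as missing: ",
              paste(unique(out[unknown]), collapse = ", "))
      out[unknown] <- NA_character_
    }
    out
  }
  mother <- fix_parent(mother, "mother")
  father <- fix_parent(father, "father")
  g <- matrix(NA_character_, nmark, nrow(pd),
              dimnames = list(mp$id, ind))
  for (j in seq_len(nmark)) {
    a1 <- pd[[5 + 2 * j]]; a2 <- pd[[6 + 2 * j]]
    cell <- paste0(a1, "/", a2)
    cell[a1 == "0" & a2 == "0"] <- NA_character_
    g[j, ] <- cell
  }
  inv <- data.frame(name = investigation_name,
                    description = NA_character_, stringsAsFactors = FALSE)
  mrec <- data.frame(name = mp$id, type = NA_character_,
                     investigation_name = investigation_name,
                     chromosome = mp$chr,
                     bp_start = mp$bp, bp_end = mp$bp,
                     cm = fmt_decimal(as.numeric(mp$cm)),
                     stringsAsFactors = FALSE)
  irec <- data.frame(name = ind, type = NA_character_,
                     investigation_name = investigation_name,
                     mother = mother, father = father,
                     strain = NA_character_, stringsAsFactors = FALSE)
  desc <- data.frame(name = paste0(ind, "_pedinfo"),
                     investigation_name = investigation_name,
                     target_entity = "Individual", target_name = ind,
                     description = paste0("family=", fam, " sex=", sex),
                     stringsAsFactors = FALSE)
  records <- list(Investigation = inv, Marker = mrec, Individual = irec,
                  Description = desc)
  matrices <- list(genotypes = data_matrix("genotypes", g, "text"))
  dat <- data.frame(name = "genotypes",
                    investigation_name = investigation_name,
                    rowtype = "Marker", coltype = "Individual",
                    valuetype = "text", stringsAsFactors = FALSE)
  phen_num <- suppressWarnings(as.numeric(phen))
  phen_num[phen %in% c("-9", "0")] <- NA  # PLINK missing-phenotype codes
  if (any(!is.na(phen_num))) {
    records$Trait <- data.frame(name = "phenotype", type = NA_character_,
                                investigation_name = investigation_name,
                                stringsAsFactors = FALSE)
    pv <- matrix(phen_num, nrow = 1,
                 dimnames = list("phenotype", ind))
    matrices$phenotypes <- data_matrix("phenotypes", pv, "decimal")
    dat <- rbind(dat, data.frame(
      name = "phenotypes", investigation_name = investigation_name,
      rowtype = "Trait", coltype = "Individual", valuetype = "decimal",
      stringsAsFactors = FALSE))
  }
  records$Data <- dat
  xg_bundle(records, matrices)
}
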