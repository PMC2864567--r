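# The built-in XGAP object model and the extension mechanism.

.xg_env <- new.env(parent = emptyenv())

#' The built-in XGAP object model
#'
#' Returns the model of a genotype/phenotype investigation: the FuGE-style
#' experiment core (`Investigation`, `Protocol`, `ProtocolApplication`,
#' `Data`, `DimensionElement`), the `Trait`/`Subject` split with its
#' variants (`Marker`, `Probe`, `Gene`, `Metabolite`; `Sample`,
#' `PairedSample`, `Individual`, `Strain`, `InbredStrain`), the `Locus`
#' interface carrying genome coordinates, annotation types
#' (`OntologyTerm`, `DatabaseEntry`, `BibliographicReference`, `URI`,
#' `FileAttachment`, `Description`) and protocol detail types (`Action`,
#' `Software`, `Equipment`, `Parameter`, `ParameterValue`).
#'
#' The model ships as a model-DSL file at
#' `system.file("extdata/models/xgap_core.model", package = "xgaptab")`,
#' which users can read or fork; this function parses and caches it.
#'
#' @return An [xg_model()].
#' @export
builtin_model <- function() {
  if (is.null(.xg_env$builtin)) {
    path <- system.file("extdata", "models", "xgap_core.model",
                        package = "xgaptab", mustWork = TRUE)
    .xg_env$builtin <- parse_model_file(path)
  }
  .xg_env$builtin
}

#' Extend a model with additional entities
#'
#' Merges extension entities (e.g. a new `Trait` variant for a new
#' profiling technology) into a base model. Base entities are never
#' modified; the derived format spec and relational schema of the merged
#' model are supersets of the base's.
#'
#' @param base An [xg_model()].
#' @param extension A model-DSL document (text or lines), a path to one,
#'   or an [xg_model()] holding only the new entities.
#' @return The merged [xg_model()].
#' @export
extend_model <- function(base, extension) {
  ext_entities <- if (inherits(extension, "xg_model")) {
    extension$entities
  } else {
    txt <- extension
    if (length(txt) == 1 && !grepl("\n", txt) && file.exists(txt))
      txt <- readLines(txt, encoding = "UTF-8", warn = FALSE)
    # parse in the context of the base so extends/xref may point at base
    # entities: parse leniently entity-by-entity, then validate merged
    parse_model_extension(txt, base)
  }
  clash <- intersect(names(ext_entities), names(base$entities))
  if (length(clash))
    stop("extension redefines base entit",
         if (length(clash) > 1) "ies: " else "y: ",
         paste(clash, collapse = ", "))
  xg_model(c(unname(base$entities), unname(ext_entities)))
}

# Parse an extension document whose references may target base entities.
# Reuses the main parser by prepending interface-free stubs of the base
# entities, then stripping them again; the merged result is validated by
# extend_model/xg_model.
parse_model_extension <- function(text, base) {
  lines <- if (length(text) == 1 && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1]] else as.character(text)
  stubs <- vapply(base$entities, function(e)
    paste0(if (e$is_interface) "interface " else "entity ", e$name),
    character(1))
  parsed <- parse_model(c(stubs, lines))
  parsed$entities[setdiff(names(parsed$entities), names(base$entities))]
}
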