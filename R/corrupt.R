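# Defect injection with exact ground truth.
#
# Each defect kind draws from its own pool of corruption sites, chosen so
# that one injected defect produces exactly one validator finding and
# defects never mask each other (e.g. a duplicate name is injected by
# appending a copy of a record, so no matrix dimension name goes stale).
# The ground truth therefore matches validate_bundle() output one-to-one
# by (kind, location).

XG_CORRUPT_KINDS <- c("unresolved_reference", "duplicate_name",
                      "missing_required", "type_mismatch",
                      "matrix_name_mismatch")

corruption_sites <- function(bundle) {
  sites <- list()
  add <- function(kind, location, apply_fn) {
    sites[[length(sites) + 1]] <<- list(kind = kind, location = location,
                                        apply = apply_fn)
  }
  # unresolved_reference: rewrite investigation xrefs of Probe and of
  # subject records (nothing resolves names against a record's stated
  # investigation, so no secondary findings arise)
  for (entity in intersect(c("Probe", "Individual", "Strain",
                             "InbredStrain"), names(bundle$records))) {
    df <- bundle$records[[entity]]
    for (i in seq_len(nrow(df))) {
      if (is.na(df$investigation_name[i])) next
      local({
        e <- entity; r <- i
        add("unresolved_reference",
            sprintf("%s[%d].investigation_name", e, r),
            function(b, tag) {
              b$records[[e]]$investigation_name[r] <-
                paste0("missing_inv_", tag)
              b
            })
      })
    }
  }
  # duplicate_name: append a copy of a Marker record (its name stays
  # present, so matrix rows still resolve)
  mdf <- bundle$records[["Marker"]]
  if (!is.null(mdf)) {
    for (i in seq_len(nrow(mdf))) {
      local({
        r <- i
        add("duplicate_name",
            sprintf("Marker:name=%s", mdf$name[r]),
            function(b, tag) {
              b$records$Marker <- rbind(b$records$Marker,
                                        b$records$Marker[r, ])
              rownames(b$records$Marker) <- NULL
              b
            })
      })
    }
  }
  # missing_required: blank names of records nothing references
  # (ProtocolApplication, annotation records), or a required Data field
  # whose dependent checks then skip
  for (entity in intersect(c("ProtocolApplication", "OntologyTerm",
                             "DatabaseEntry"), names(bundle$records))) {
    df <- bundle$records[[entity]]
    for (i in seq_len(nrow(df))) {
      local({
        e <- entity; r <- i
        add("missing_required", sprintf("%s[%d].name", e, r),
            function(b, tag) {
              b$records[[e]]$name[r] <- NA_character_
              b
            })
      })
    }
  }
  ddf <- bundle$records[["Data"]]
  if (!is.null(ddf)) {
    for (i in seq_len(nrow(ddf))) {
      # never blank a field whose dependent checks would silently skip a
      # defect injected by another kind: row/col renames target text
      # matrices, planted non-numeric cells target decimal ones
      flds <- if (!is.na(ddf$valuetype[i]) && ddf$valuetype[i] == "decimal")
        c("rowtype", "coltype") else "valuetype"
      for (fld in flds) {
        local({
          r <- i; f <- fld
          add("missing_required", sprintf("Data[%d].%s", r, f),
              function(b, tag) {
                b$records$Data[[f]][r] <- NA_character_
                b
              })
        })
      }
    }
  }
  # type_mismatch: plant a non-numeric cell in a decimal matrix
  for (mn in names(bundle$matrices)) {
    m <- bundle$matrices[[mn]]
    if (m$valuetype != "decimal") next
    decl <- if (!is.null(ddf)) ddf[match(mn, ddf$name), ] else NULL
    if (is.null(decl) || is.na(decl$valuetype) ||
        decl$valuetype != "decimal") next
    rn <- rownames(m$values); cn <- colnames(m$values)
    for (i in seq_along(rn)) {
      local({
        nm <- mn; r <- i
        add("type_mismatch",
            sprintf("%s[%s,%s]", nm, rn[r], cn[1]),
            function(b, tag) {
              v <- b$matrices[[nm]]$values
              storage.mode(v) <- "character"
              v[r, 1] <- paste0("not_a_number_", tag)
              b$matrices[[nm]] <- data_matrix(nm, v, "text")
              b
            })
      })
    }
  }
  # matrix_name_mismatch: rename a row of a text matrix to an unknown name
  for (mn in names(bundle$matrices)) {
    m <- bundle$matrices[[mn]]
    if (m$valuetype != "text") next
    for (i in seq_len(nrow(m$values))) {
      local({
        nm <- mn; r <- i
        add("matrix_name_mismatch", NA_character_,  # location needs tag
            function(b, tag) {
              rownames(b$matrices[[nm]]$values)[r] <-
                paste0("unknown_row_", tag)
              b
            })
      })
      sites[[length(sites)]]$location_fn <- local({
        nm <- mn
        mi <- if (is.null(ddf)) NA else match(nm, ddf$name)
        rt <- if (is.na(mi)) "?" else ddf$rowtype[mi]
        function(tag) sprintf("%s[row:unknown_row_%s]", nm, tag)
      })
    }
  }
  sites
}

#' Inject a known set of defects into a bundle
#'
#' Produces a corrupted copy of a valid bundle together with the exact
#' ground truth of what was broken; [validate_bundle()] on the result
#' reports precisely these findings (matched by kind and location), which
#' is how the validator's completeness is tested.
#'
#' @param bundle A bundle with zero validation errors.
#' @param n_errors Number of defects to inject.
#' @param kinds Defect kinds to draw from: any subset of
#'   `unresolved_reference`, `duplicate_name`, `missing_required`,
#'   `type_mismatch`, `matrix_name_mismatch`.
#' @param seed Integer seed for site selection.
#' @return List with `bundle` (corrupted) and `defects` (data.frame of
#'   kind + location ground truth, one row per injected defect).
#' @export
corrupt_bundle <- function(bundle, n_errors, kinds = XG_CORRUPT_KINDS,
                           seed = 1) {
  kinds <- match.arg(kinds, XG_CORRUPT_KINDS, several.ok = TRUE)
  sites <- corruption_sites(bundle)
  sites <- sites[vapply(sites, function(s) s$kind %in% kinds, logical(1))]
  if (n_errors > length(sites))
    stop("only ", length(sites), " corruption site(s) available for ",
         "kinds ", paste(kinds, collapse = ", "), "; asked for ", n_errors)
  with_seed(seed, {
    # round-robin over kinds so every requested kind is represented
    by_kind <- split(seq_along(sites),
                     vapply(sites, `[[`, character(1), "kind"))
    by_kind <- by_kind[order(match(names(by_kind), kinds))]
    pick <- integer()
    pools <- lapply(by_kind, function(x) x[sample.int(length(x))])
    k <- 1
    while (length(pick) < n_errors) {
      pool <- pools[[((k - 1) %% length(pools)) + 1]]
      pool <- setdiff(pool, pick)
      if (length(pool)) pick <- c(pick, pool[1])
      k <- k + 1
    }
    defects <- data.frame(kind = character(), location = character(),
                          stringsAsFactors = FALSE)
    out <- bundle
    for (j in seq_along(pick)) {
      s <- sites[[pick[j]]]
      out <- s$apply(out, j)
      loc <- if (!is.null(s$location_fn)) s$location_fn(j) else s$location
      defects[nrow(defects) + 1, ] <- c(s$kind, loc)
    }
    list(bundle = out, defects = defects)
  })
}
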