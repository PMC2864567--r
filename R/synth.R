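# Synthetic genetical-genomics investigations.
#
# The generator emulates the canonical study shape of the field: a panel
# of recombinant inbred strains genotyped at markers laid out evenly
# along chromosomes (two homozygote codes, A/B), plus an expression
# matrix over microarray probes in which a chosen set of (marker, probe)
# pairs carries a genuine cis/trans effect. Genotypes are simulated as a
# two-state Markov chain along each chromosome with recombination
# probability between adjacent markers given by the Haldane map function
# r = (1 - exp(-2 d / 100)) / 2 for spacing d in cM.

#' Parameters for the synthetic investigation generator
#'
#' Defaults follow the classic small recombinant-inbred panel: 30
#' subjects, 100 markers on 5 chromosomes of 100 cM, 200 expression
#' probes, 10 true eQTL of 2 expression units, unit Gaussian noise.
#'
#' @param n_subjects Number of subjects (matrix columns).
#' @param subject_entity `"Individual"`, `"Strain"` or `"InbredStrain"`.
#' @param n_markers Total marker count, spread over chromosomes.
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length_cm Genetic length per chromosome (cM).
#' @param n_probes Number of expression probes.
#' @param n_qtl Number of (marker, probe) pairs with a true effect;
#'   at most `min(n_markers, n_probes)`.
#' @param qtl_effect Expression shift per B allele (expression units).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed; the same seed yields a byte-identical
#'   bundle.
#' @return A validated list of class `xg_synth_params`.
#' @export
synth_params <- function(n_subjects = 30,
                         subject_entity = c("InbredStrain", "Strain",
                                            "Individual"),
                         n_markers = 100, n_chromosomes = 5,
                         chromosome_length_cm = 100, n_probes = 200,
                         n_qtl = 10, qtl_effect = 2, noise_sd = 1,
                         seed = 1) {
  subject_entity <- match.arg(subject_entity)
  p <- list(n_subjects = as.integer(n_subjects),
            subject_entity = subject_entity,
            n_markers = as.integer(n_markers),
            n_chromosomes = as.integer(n_chromosomes),
            chromosome_length_cm = as.numeric(chromosome_length_cm),
            n_probes = as.integer(n_probes), n_qtl = as.integer(n_qtl),
            qtl_effect = as.numeric(qtl_effect),
            noise_sd = as.numeric(noise_sd), seed = as.integer(seed))
  stopifnot(p$n_subjects >= 0, p$n_markers >= 0, p$n_chromosomes >= 1,
            p$n_probes >= 0, p$n_qtl >= 0, p$noise_sd >= 0,
            p$chromosome_length_cm > 0)
  if (p$n_qtl > min(p$n_markers, p$n_probes))
    stop("n_qtl exceeds min(n_markers, n_probes)")
  structure(p, class = "xg_synth_params")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Haldane map function
#'
#' Converts a genetic distance in cM to a recombination probability,
#' assuming no crossover interference.
#'
#' @param d_cm Distance(s) in centimorgan.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @export
haldane_r <- function(d_cm) (1 - exp(-2 * d_cm / 100)) / 2

#' Generate a deterministic synthetic investigation bundle
#'
#' Builds a complete, valid bundle: the Investigation; subject records;
#' Marker records placed evenly along each chromosome (cM positions, and
#' bp positions at 1 Mb per cM); Probe records; a text genotype matrix
#' (codes `A`/`B`, markers by subjects) simulated as a Markov chain with
#' Haldane recombination probabilities; a decimal expression matrix
#' (probes by subjects) equal to a per-probe baseline (Normal(8, 1), a
#' log2-intensity scale) plus `qtl_effect` for each B allele at the
#' probe's QTL marker plus Normal(0, noise_sd) noise; genotyping,
#' array-hybridization and qtl-mapping Protocols with their
#' ProtocolApplications (each assay run delivers its Data via
#' `outputdata`, the computational run takes both matrices as
#' `inputdata`); an
#' OntologyTerm annotating the Investigation's growth environment; a
#' DatabaseEntry annotating the first Probe; and a `species_name`
#' constant.
#'
#' @param params An [synth_params()] object.
#' @return An [xg_bundle()] with zero validation errors.
#' @export
generate_investigation <- function(params = synth_params()) {
  p <- params
  with_seed(p$seed, {
    inv_name <- "synthetic_ggx"
    wid <- function(n) max(2, nchar(n))
    subjects <- sprintf("s%0*d", wid(p$n_subjects), seq_len(p$n_subjects))
    markers <- sprintf("m%0*d", wid(p$n_markers), seq_len(p$n_markers))
    probes <- sprintf("p%0*d", wid(p$n_probes), seq_len(p$n_probes))
    # markers spread as evenly as possible over chromosomes, then evenly
    # spaced within each chromosome
    chr_of <- sort(rep_len(seq_len(p$n_chromosomes), p$n_markers))
    cm <- numeric(p$n_markers); bp <- integer(p$n_markers)
    for (ch in seq_len(p$n_chromosomes)) {
      idx <- which(chr_of == ch)
      k <- length(idx)
      if (!k) next
      pos <- if (k == 1) p$chromosome_length_cm / 2
        else seq(0, p$chromosome_length_cm, length.out = k)
      cm[idx] <- pos
      bp[idx] <- as.integer(round(pos * 1e6) + 1)  # 1 cM ~ 1 Mb
    }
    # genotypes: two-state Markov chain along each chromosome
    g <- matrix(NA_character_, p$n_markers, p$n_subjects,
                dimnames = list(markers, subjects))
    for (ch in seq_len(p$n_chromosomes)) {
      idx <- which(chr_of == ch)
      if (!length(idx)) next
      state <- rbinom(p$n_subjects, 1, 0.5)
      g[idx[1], ] <- c("A", "B")[state + 1]
      for (k in seq_along(idx)[-1]) {
        r <- haldane_r(cm[idx[k]] - cm[idx[k - 1]])
        flip <- rbinom(p$n_subjects, 1, r)
        state <- ifelse(flip == 1, 1 - state, state)
        g[idx[k], ] <- c("A", "B")[state + 1]
      }
    }
    # expression: baseline + QTL effect + noise
    qtl_marker <- if (p$n_qtl) sample.int(p$n_markers, p$n_qtl)
      else integer()
    qtl_probe <- if (p$n_qtl) sample.int(p$n_probes, p$n_qtl)
      else integer()
    baseline <- rnorm(p$n_probes, mean = 8, sd = 1)
    expr <- matrix(rep(baseline, p$n_subjects), p$n_probes, p$n_subjects,
                   dimnames = list(probes, subjects))
    for (k in seq_len(p$n_qtl)) {
      carrier <- g[qtl_marker[k], ] == "B"
      expr[qtl_probe[k], carrier] <- expr[qtl_probe[k], carrier] +
        p$qtl_effect
    }
    if (p$noise_sd > 0)
      expr <- expr + matrix(rnorm(length(expr), sd = p$noise_sd),
                            nrow(expr))
    inv <- data.frame(name = inv_name,
                      description = "synthetic genetical genomics study",
                      stringsAsFactors = FALSE)
    subj <- data.frame(name = subjects, type = NA_character_,
                       investigation_name = inv_name,
                       stringsAsFactors = FALSE)
    if (p$subject_entity %in% c("Strain", "InbredStrain")) {
      subj$parent_strains <- NA_character_
      subj$breeding_method <- "selfing"
      if (p$subject_entity == "InbredStrain")
        subj$inbreeding_type <- "recombinant inbred"
    } else {
      subj$mother <- subj$father <- subj$strain <- NA_character_
    }
    mrec <- data.frame(name = markers, type = NA_character_,
                       investigation_name = inv_name,
                       chromosome = as.character(chr_of),
                       bp_start = as.character(bp),
                       bp_end = as.character(bp),
                       cm = fmt_decimal(cm), stringsAsFactors = FALSE)
    prec <- data.frame(name = probes, type = NA_character_,
                       investigation_name = inv_name, sequence = NA,
                       chromosome = NA, bp_start = NA, bp_end = NA,
                       cm = NA, stringsAsFactors = FALSE)
    prot <- data.frame(name = c("genotyping", "array hybridization",
                                "qtl mapping"),
                       investigation_name = inv_name,
                       description = c("marker genotyping assay",
                                       "single-channel expression array",
                                       "single-marker regression scan"),
                       stringsAsFactors = FALSE)
    pa <- data.frame(name = c("genotyping_run", "hybridization_run",
                              "qtl_run"),
                     investigation_name = inv_name,
                     protocol = c("genotyping", "array hybridization",
                                  "qtl mapping"),
                     inputdata = c(NA_character_, NA_character_,
                                   "genotypes,expressions"),
                     outputdata = c("genotypes", "expressions",
                                    NA_character_),
                     stringsAsFactors = FALSE)
    dat <- data.frame(name = c("genotypes", "expressions"),
                      investigation_name = inv_name,
                      rowtype = c("Marker", "Probe"),
                      coltype = p$subject_entity,
                      valuetype = c("text", "decimal"),
                      stringsAsFactors = FALSE)
    onto <- data.frame(name = "growth_environment",
                       investigation_name = inv_name,
                       target_entity = "Investigation",
                       target_name = inv_name,
                       term = "standard environment",
                       accession = "XCO:0000001", ontology = "XCO",
                       stringsAsFactors = FALSE)
    dbe <- if (p$n_probes) data.frame(
      name = "probe_dbentry", investigation_name = inv_name,
      target_entity = "Probe", target_name = probes[1],
      database_name = "EnsemblSynthetic", accession = "ENSX0000001",
      stringsAsFactors = FALSE) else NULL
    records <- list(Investigation = inv, Protocol = prot,
                    ProtocolApplication = pa, Data = dat,
                    Marker = mrec, Probe = prec,
                    OntologyTerm = onto)
    if (!is.null(dbe)) records$DatabaseEntry <- dbe
    records[[p$subject_entity]] <- subj
    matrices <- list(
      genotypes = data_matrix("genotypes", g, "text"),
      expressions = data_matrix("expressions", expr, "decimal"))
    xg_bundle(records, matrices,
              constants = c(species_name = "Mus musculus"))
  })
}
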