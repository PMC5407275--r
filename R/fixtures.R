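# Packaged Washington, D.C. restaurant audit: loaders that rebuild the
# per-method identifications from the transcribed observations and run the
# full consensus -> judge -> audit chain at call time. Nothing here stores
# a verdict; the mislabeling calls and the percentage are always recomputed.

#' Load the packaged topology-hypothesis table
#' @return Data frame of hypotheses with marginal log-likelihoods, one row
#'   per (sample, hypothesis).
#' @export
dc_hypotheses <- function() {
  read.delim(system.file("extdata", "dc_hypotheses.tsv",
                         package = "barcodeaudit"),
             comment.char = "#", stringsAsFactors = FALSE)
}

#' Load the packaged per-sample method observations
#' @return Data frame with one row per restaurant sample.
#' @export
dc_samples <- function() {
  read.delim(system.file("extdata", "dc_samples.tsv",
                         package = "barcodeaudit"),
             comment.char = "#", stringsAsFactors = FALSE,
             na.strings = "NA")
}

# rebuild a candidate_set-like identity call from "taxon:pid;taxon:pid"
parse_identity_candidates <- function(s, band = 1.0, floor = 90) {
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  cand <- data.frame(
    taxon = vapply(parts, `[`, character(1L), 1L),
    percent_identity = as.numeric(vapply(parts, `[`, character(1L), 2L)),
    stringsAsFactors = FALSE)
  cand <- cand[order(-cand$percent_identity, cand$taxon), ]
  rownames(cand) <- NULL
  best <- cand$percent_identity[1L]
  cand <- cand[cand$percent_identity >= best - band, , drop = FALSE]
  # "Genus sp." records are genus-rank placeholders; a species-level
  # decision needs a single named species with nothing else in the band
  is_placeholder <- grepl("\\bsp\\.$", cand$taxon)
  if (best < floor) {
    level <- "none"
  } else if (length(unique(cand$taxon)) == 1L && !any(is_placeholder)) {
    level <- "species"
  } else {
    genera <- unique(vapply(strsplit(cand$taxon, "\\s+"), `[`,
                            character(1L), 1L))
    level <- if (length(genera) == 1L) "genus" else "none"
  }
  decision <- switch(level,
    species = cand$taxon[1L],
    genus = paste(vapply(strsplit(cand$taxon[1L], "\\s+"), `[`,
                         character(1L), 1L), "sp."),
    none = NA_character_)
  structure(list(query_id = NA_character_,
                 hits = cand, candidates = cand,
                 decision_level = level, decision = decision),
            class = "candidate_set")
}

#' Assemble the per-method identifications for one packaged sample
#'
#' @param row One row of [dc_samples()].
#' @param hyps The full [dc_hypotheses()] table.
#' @param key The packaged diagnostic key.
#' @return A `method_ids` list for [consensus_id()].
#' @export
dc_method_ids <- function(row, hyps = dc_hypotheses(), key = load_key()) {
  out <- list()
  if (!is.na(row$identity_candidates)) {
    out$identity <- parse_identity_candidates(row$identity_candidates)
  }
  h <- hyps[hyps$sample_id == row$sample_id, , drop = FALSE]
  if (nrow(h)) out$bayes <- bayes_topology_call(h)
  if (!is.na(row$phylo_level)) {
    members <- strsplit(row$phylo_members, ";", fixed = TRUE)[[1L]]
    out$phylo <- list(
      query_id = row$sample_id,
      species = if (identical(row$phylo_level, "species"))
        row$phylo_species else NA_character_,
      level = row$phylo_level,
      members = members, sister_taxa = members, sister_species = members,
      bootstrap = row$phylo_boot, posterior = row$phylo_pp / 100,
      label = paste0(row$phylo_boot, "/", row$phylo_pp))
  }
  if (!is.na(row$key_profile)) {
    out$char_key <- match_profile(row$key_profile, key)
  }
  out
}

#' Run the packaged restaurant audit end to end
#'
#' Recomputes every method call (character key matches, Bayes factors from
#' the marginal log-likelihoods, identity candidate decisions), combines
#' them with [consensus_id()], judges each sample against the packaged menu
#' rules and returns the [audit()] report.
#'
#' @param rules Menu rules (default: packaged).
#' @param key Diagnostic key (default: packaged).
#' @return An `audit_report`.
#' @export
dc_audit <- function(rules = load_menu_rules(), key = load_key()) {
  samples <- dc_samples()
  hyps <- dc_hypotheses()
  verdicts <- lapply(seq_len(nrow(samples)), function(i) {
    row <- samples[i, ]
    sample_verdict(row$restaurant, row$menu_listing,
                   dc_method_ids(row, hyps, key), rules)
  })
  audit(verdicts)
}
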