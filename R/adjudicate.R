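# Combining identifications across methods and auditing menu listings.
#
# Method precedence for the final call: (1) an exact character-key match,
# (2) a Bayes-factor-supported grouping (|log BF| > 5), (3) a supported ML
# clade placement, (4) the percent-identity top hit. The ordering reflects
# the information content of each method on low-divergence groups (the key
# and the topology tests resolve cases where raw identity cannot); it is
# configurable and recorded in the verdict's provenance.

#' Load menu-listing acceptability rules
#'
#' YAML schema: a top-level `rules` map of normalized listing phrase ->
#' `acceptable` (species names and/or genus wildcards `"Genus *"`) and
#' `species_specific` (logical). A listing matches the rule whose phrase it
#' contains; species-specific rules outrank generic ones, then longer
#' phrases win.
#'
#' @param path YAML file; defaults to the packaged rules (only listings the
#'   packaged restaurant audit itself adjudicates).
#' @return A named list of `menu_rule`s.
#' @export
load_menu_rules <- function(path = system.file("extdata", "menu_rules.yaml",
                                               package = "barcodeaudit")) {
  raw <- yaml::read_yaml(path)$rules
  if (is.null(raw) || !length(raw)) stop2("No rules found in ", path)
  out <- lapply(names(raw), function(nm) {
    r <- raw[[nm]]
    if (!length(r$acceptable)) stop2("Rule '", nm, "' has no acceptable taxa")
    structure(list(listing_pattern = normalize_listing(nm),
                   acceptable_taxa = unlist(r$acceptable),
                   species_specific = isTRUE(r$species_specific)),
              class = "menu_rule")
  })
  names(out) <- vapply(out, `[[`, character(1L), "listing_pattern")
  out
}

normalize_listing <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Find the rule matching a menu listing
#' @param listing Menu phrase as printed.
#' @param rules Named list from [load_menu_rules()].
#' @return A `menu_rule` or `NULL` if no rule matches.
#' @export
match_rule <- function(listing, rules) {
  l <- normalize_listing(listing)
  hits <- Filter(function(r) grepl(r$listing_pattern, l, fixed = TRUE), rules)
  if (!length(hits)) return(NULL)
  spec <- vapply(hits, `[[`, logical(1L), "species_specific")
  len <- nchar(vapply(hits, `[[`, character(1L), "listing_pattern"))
  hits[[order(-spec, -len)[1L]]]
}

taxon_acceptable <- function(taxon, rule) {
  for (a in rule$acceptable_taxa) {
    if (grepl("\\*$", a)) {
      genus <- sub("\\s*\\*$", "", a)
      if (strsplit(taxon, "\\s+")[[1L]][1L] == genus) return(TRUE)
    } else if (identical(taxon, a)) return(TRUE)
  }
  FALSE
}

# ---- Bayes-factor method call ---------------------------------------------

#' Derive an identification from a topology-hypothesis table
#'
#' Input: one sample's tested hypotheses with their marginal log-likelihoods
#' (columns `mode` = monophyletic|not_monophyletic, `target_taxon`, `level`
#' = species|genus, `marginal_lnL`). A species-level call requires the best
#' species hypothesis to beat every incompatible hypothesis (other species
#' groupings, non-monophyly of itself or its genus) by more than
#' `threshold` log units; otherwise a supported genus-level grouping is
#' reported, with the species-level targets of that genus as members.
#'
#' @param hyps Data frame of hypotheses for one sample.
#' @param threshold Strong-support threshold on the log Bayes factor.
#' @return List `(species, level, members, log_bf)` or `NULL` when nothing
#'   is supported.
#' @export
bayes_topology_call <- function(hyps, threshold = 5) {
  if (is.null(hyps) || nrow(hyps) == 0L) return(NULL)
  genus_of <- function(x) strsplit(x, "\\s+")[[1L]][1L]
  sp_rows <- hyps$mode == "monophyletic" & hyps$level == "species"
  if (any(sp_rows)) {
    cand <- hyps[sp_rows, , drop = FALSE]
    best <- cand[which.max(cand$marginal_lnL), , drop = FALSE]
    s <- best$target_taxon
    compatible <- hyps$mode == "monophyletic" &
      (hyps$target_taxon == s |
         (hyps$level == "genus" & hyps$target_taxon == genus_of(s)))
    comp <- hyps[!compatible, , drop = FALSE]
    if (nrow(comp)) {
      lbf <- best$marginal_lnL - max(comp$marginal_lnL)
      if (lbf > threshold) {
        return(list(species = s, level = "species", members = s,
                    log_bf = lbf))
      }
    } else {
      return(list(species = s, level = "species", members = s,
                  log_bf = Inf))
    }
  }
  g_rows <- which(hyps$mode == "monophyletic" & hyps$level == "genus")
  for (gi in g_rows[order(-hyps$marginal_lnL[g_rows])]) {
    g <- hyps$target_taxon[gi]
    against <- hyps$mode == "not_monophyletic" & hyps$target_taxon == g
    if (!any(against)) next
    lbf <- hyps$marginal_lnL[gi] - max(hyps$marginal_lnL[against])
    if (lbf > threshold) {
      members <- unique(hyps$target_taxon[hyps$level == "species" &
        vapply(hyps$target_taxon, genus_of, character(1L)) == g])
      return(list(species = NA_character_, level = "genus", members = members,
                  genus = g, log_bf = lbf))
    }
  }
  NULL
}

# ---- consensus -------------------------------------------------------------

#' Combine per-method identifications into a final call
#'
#' @param method_ids A list with any of:
#'   * `char_key`: a `key_match` (used when exact and unambiguous),
#'   * `bayes`: result of [bayes_topology_call()],
#'   * `phylo`: result of [place_query()],
#'   * `identity`: a `candidate_set` from [identity_search()].
#' @param bf_threshold |log BF| needed for a Bayes-supported call.
#' @param boot_threshold Minimum bootstrap % for a supported ML placement.
#' @return A `final_id`: list `(species, level, members, provenance,
#'   agreement, note)`. `level` is `"species"`, `"genus"` or
#'   `"unidentified"`.
#' @export
consensus_id <- function(method_ids, bf_threshold = 5, boot_threshold = 70) {
  calls <- list()
  ck <- method_ids$char_key
  if (!is.null(ck) && isTRUE(ck$exact)) {
    calls$char_key <- ck$best_species
  }
  by <- method_ids$bayes
  if (!is.null(by) && by$level == "species" && by$log_bf > bf_threshold) {
    calls$bayes <- by$species
  }
  ph <- method_ids$phylo
  if (!is.null(ph) && identical(ph$level, "species") &&
      !is.na(ph$bootstrap) && ph$bootstrap >= boot_threshold) {
    calls$phylo <- ph$species
  }
  idn <- method_ids$identity
  if (!is.null(idn) && identical(idn$decision_level, "species")) {
    calls$identity <- idn$decision
  }
  if (length(calls)) {
    prov <- names(calls)[1L]
    species <- calls[[1L]]
    agree <- names(calls)[vapply(calls, identical, logical(1L), species)]
    conflict <- setdiff(names(calls), agree)
    note <- if (length(conflict)) {
      paste0("conflicts: ", paste(conflict, "=", unlist(calls[conflict]),
                                  collapse = "; "))
    } else ""
    return(structure(list(species = species, level = "species",
                          members = species, provenance = prov,
                          agreement = agree, note = note),
                     class = "final_id"))
  }
  # genus-level fallbacks, same precedence order
  if (!is.null(by) && by$level == "genus") {
    return(structure(list(species = NA_character_, level = "genus",
                          members = by$members, provenance = "bayes",
                          agreement = "bayes", note = ""),
                     class = "final_id"))
  }
  if (!is.null(ph) && identical(ph$level, "genus-or-higher")) {
    mem <- sort(unique(ph$sister_species %||% character(0)))
    return(structure(list(species = NA_character_, level = "genus",
                          members = mem, provenance = "phylo",
                          agreement = "phylo", note = ""),
                     class = "final_id"))
  }
  if (!is.null(idn) && identical(idn$decision_level, "genus")) {
    return(structure(list(species = NA_character_, level = "genus",
                          members = idn$candidates$taxon,
                          provenance = "identity", agreement = "identity",
                          note = ""), class = "final_id"))
  }
  structure(list(species = NA_character_, level = "unidentified",
                 members = character(0), provenance = NA_character_,
                 agreement = character(0), note = "no method produced a call"),
            class = "final_id")
}

#' Judge a final identification against a menu rule
#'
#' A species-level call is mislabeled iff the species is not in the rule's
#' acceptable set (genus wildcards expand). A genus-level call is acceptable
#' iff every member species is acceptable.
#'
#' @param final_id A `final_id` from [consensus_id()].
#' @param rule A `menu_rule` (or `NULL`: verdict `"unreviewed"`).
#' @return List `(mislabeled, status, note)`; `mislabeled` is `NA` when the
#'   sample is unidentified or unreviewed.
#' @export
judge <- function(final_id, rule) {
  if (is.null(rule)) {
    return(list(mislabeled = NA, status = "unreviewed",
                note = "no rule for listing"))
  }
  if (final_id$level == "unidentified") {
    return(list(mislabeled = NA, status = "unidentified", note = ""))
  }
  taxa <- if (final_id$level == "species") final_id$species else
    final_id$members
  ok <- all(vapply(taxa, taxon_acceptable, logical(1L), rule = rule))
  list(mislabeled = !ok, status = if (ok) "acceptable" else "mislabeled",
       note = "")
}

#' Audit a set of sample verdicts
#'
#' @param verdicts List of `sample_verdict`s (see [sample_verdict()]).
#' @return An `audit_report`: `table` (one row per sample),
#'   `n`, `n_mislabeled`, `percent_mislabeled` (whole percent, recomputed).
#' @export
audit <- function(verdicts) {
  if (!length(verdicts)) stop2("Need at least one verdict")
  tab <- do.call(rbind, lapply(verdicts, function(v) {
    data.frame(
      restaurant = v$restaurant,
      menu_listing = v$menu_listing,
      identity_id = v$method_labels["identity"] %||% NA_character_,
      phylo_id = v$method_labels["phylo"] %||% NA_character_,
      charkey_id = v$method_labels["char_key"] %||% NA_character_,
      bayes_id = v$method_labels["bayes"] %||% NA_character_,
      final_id = if (v$final$level == "species") v$final$species else
        if (v$final$level == "genus")
          paste(paste(v$final$members, collapse = "/")) else "unidentified",
      mislabeled = v$mislabeled,
      note = v$note,
      stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  m <- sum(tab$mislabeled %in% TRUE)
  structure(list(table = tab, n = nrow(tab), n_mislabeled = m,
                 percent_mislabeled = round(100 * m / nrow(tab))),
            class = "audit_report")
}

#' Build one sample's verdict
#'
#' Runs [consensus_id()] and [judge()] for a sample and keeps per-method
#' labels for the report.
#'
#' @param restaurant,menu_listing Sample metadata.
#' @param method_ids See [consensus_id()].
#' @param rules Menu rules list.
#' @param ... Passed to [consensus_id()].
#' @return A `sample_verdict`.
#' @export
sample_verdict <- function(restaurant, menu_listing, method_ids, rules, ...) {
  final <- consensus_id(method_ids, ...)
  rule <- match_rule(menu_listing, rules)
  j <- judge(final, rule)
  labels <- c(
    identity = if (!is.null(method_ids$identity))
      method_ids$identity$decision %||% NA_character_ else NA_character_,
    phylo = if (!is.null(method_ids$phylo))
      paste0(if (identical(method_ids$phylo$level, "species"))
        method_ids$phylo$species else method_ids$phylo$label,
        " (", method_ids$phylo$label, ")") else NA_character_,
    char_key = if (!is.null(method_ids$char_key))
      method_ids$char_key$best_species else NA_character_,
    bayes = if (!is.null(method_ids$bayes))
      paste0(if (method_ids$bayes$level == "species")
        method_ids$bayes$species else method_ids$bayes$genus,
        " (logBF ", round(method_ids$bayes$log_bf, 2), ")")
      else NA_character_)
  structure(list(restaurant = restaurant, menu_listing = menu_listing,
                 method_labels = labels, final = final,
                 mislabeled = j$mislabeled, status = j$status,
                 note = paste(c(final$note, j$note)[nzchar(c(final$note, j$note))],
                              collapse = "; ")),
            class = "sample_verdict")
}

#' @export
print.audit_report <- function(x, ...) {
  print(x$table[, c("restaurant", "menu_listing", "final_id", "mislabeled")])
  cat(sprintf("\n%d of %d samples potentially mislabeled (%d%%)\n",
              x$n_mislabeled, x$n, x$percent_mislabeled))
  invisible(x)
}

#' Write an audit report as TSV
#' @param report An `audit_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_audit_report <- function(report, path) {
  write.table(report$table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
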