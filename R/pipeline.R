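# End-to-end pipeline over a simulated scenario: identity search and
# character key per query, consensus, judgment against the scenario's menu
# rules, and the audit report. Used to validate truth recovery.

#' Build a diagnostic key from a scenario's reference panel
#'
#' Candidate positions are columns where every species' reference copies
#' agree; positions are ranked by across-species state diversity and the
#' top `n_positions` (ties by column index) form the key.
#'
#' @param scenario Output of [make_scenario()].
#' @param n_positions Number of key positions (default 14).
#' @return A `diagnostic_key`, or `NULL` if no diagnostic set exists.
#' @export
scenario_key <- function(scenario, n_positions = 14L) {
  panel <- as_aligned_matrix(scenario$refs)
  species <- unique(panel$taxa)
  consistent <- rep(TRUE, panel$length)
  states <- matrix("", length(species), panel$length)
  for (i in seq_along(species)) {
    rows <- panel$matrix[panel$taxa == species[i], , drop = FALSE]
    same <- apply(rows, 2L, function(col) length(unique(col)) == 1L)
    consistent <- consistent & same
    states[i, ] <- rows[1L, ]
  }
  cand <- which(consistent)
  if (length(cand) < n_positions) return(NULL)
  div <- apply(states[, cand, drop = FALSE], 2L,
               function(col) length(unique(col)))
  pos <- sort(cand[order(-div, cand)][seq_len(n_positions)])
  tryCatch(make_key(panel, pos), error = function(e) NULL)
}

#' Audit a simulated scenario end to end
#'
#' Runs [identity_search()] (and, when a diagnostic key is constructible,
#' the character key) for every query, combines calls with
#' [consensus_id()], judges against the scenario's rules and audits.
#'
#' @param scenario Output of [make_scenario()].
#' @param band,floor Passed to [identity_search()].
#' @param use_key Attempt a [scenario_key()] (default `TRUE`).
#' @return List: `report` (an `audit_report`), `final_species` (named by
#'   query id; `NA` for genus-level calls), `truth` (the scenario's truth).
#' @export
run_scenario_audit <- function(scenario, band = 1.0, floor = 90,
                               use_key = TRUE) {
  key <- if (use_key) scenario_key(scenario) else NULL
  verdicts <- list(); finals <- character(0)
  for (i in seq_len(nrow(scenario$queries))) {
    q <- scenario$queries[i, , drop = FALSE]
    class(q) <- class(scenario$queries)
    ids <- list(identity = identity_search(q, scenario$refs, band = band,
                                           floor = floor, aligned = TRUE))
    if (!is.null(key)) {
      ids$char_key <- tryCatch(
        match_profile(extract_profile(q, key), key),
        error = function(e) NULL)
    }
    v <- sample_verdict("simulated", scenario$truth$listing[i], ids,
                        scenario$rules)
    verdicts[[i]] <- v
    finals[q$id] <- if (v$final$level == "species") v$final$species else
      NA_character_
  }
  list(report = audit(verdicts), final_species = finals,
       truth = scenario$truth)
}
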