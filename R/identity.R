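# Percent-identity identification against a local reference panel.
#
# Emulates a BOLD/BLAST top-hit search: each reference is aligned to the
# query (codon-aware, pairwise), scored by gap-excluded percent identity,
# and candidate taxa within a reporting band of the best hit are collected.

#' Percent identity between two aligned rows
#'
#' Identity is `100 * matches / overlap`, where overlap counts the columns in
#' which both rows carry a non-gap base, and an IUPAC-ambiguous position
#' counts as a match iff the two base sets intersect (so `N` matches
#' anything). Symmetric in its arguments.
#'
#' @param a,b Aligned sequence strings of equal length (gaps as `-`).
#' @return A list with `percent_identity` (full precision), `matches` and
#'   `overlap`. Reported tables round identity to 2 decimals.
#' @export
percent_identity <- function(a, b) {
  ca <- seq_chars(toupper(a)); cb <- seq_chars(toupper(b))
  if (length(ca) != length(cb)) stop2("Rows differ in aligned length")
  both <- ca != "-" & cb != "-"
  if (!any(both)) stop2("Zero overlap: identity undefined")
  ia <- ca[both]; ib <- cb[both]
  match <- ia == ib
  amb <- !match & (!(ia %in% c("A", "C", "G", "T")) |
                   !(ib %in% c("A", "C", "G", "T")))
  if (any(amb)) {
    match[amb] <- mapply(function(x, y) {
      length(intersect(.iupac[[x]], .iupac[[y]])) > 0L
    }, ia[amb], ib[amb])
  }
  list(percent_identity = 100 * sum(match) / sum(both),
       matches = sum(match), overlap = sum(both))
}

#' Search a query against a reference panel by percent identity
#'
#' Every reference is pairwise codon-aware aligned to the query and scored
#' with [percent_identity()]. Candidate taxa are those whose best hit falls
#' within `band` percentage points of the global best hit; the decision level
#' is `species` if a single species remains, `genus` if all candidates are
#' congeneric (first word of the taxon label), otherwise `none`. A best hit
#' below `floor` yields decision `none`.
#'
#' @param query A single-row `barcode_set`.
#' @param refs A `barcode_set` of references with taxon labels.
#' @param band Reporting band in percentage points (default 1.0).
#' @param floor Minimum best-hit identity for any identification (default 90).
#' @param aligned If `TRUE`, query and refs are rows of one alignment already
#'   (equal lengths); skip per-reference alignment.
#' @return A list of class `candidate_set`: `query_id`, `hits` (data frame of
#'   all scored references, ranked), `candidates` (per-taxon best hits within
#'   the band), `decision_level` and `decision`.
#' @export
identity_search <- function(query, refs, band = 1.0, floor = 90,
                            aligned = FALSE) {
  if (nrow(refs) == 0L) stop2("Empty reference panel")
  stopifnot(nrow(query) == 1L)
  pid <- numeric(nrow(refs)); ovl <- integer(nrow(refs))
  for (i in seq_len(nrow(refs))) {
    if (aligned) {
      rowq <- query$sequence; rowr <- refs$sequence[i]
    } else {
      pair <- rbind(query, refs[i, , drop = FALSE])
      class(pair) <- class(query)
      al <- codon_aware_align(pair)
      rowq <- aligned_row(al, query$id); rowr <- aligned_row(al, refs$id[i])
    }
    h <- percent_identity(rowq, rowr)
    pid[i] <- h$percent_identity; ovl[i] <- h$overlap
  }
  hits <- data.frame(query_id = query$id, reference_id = refs$id,
                     taxon = refs$taxon, percent_identity = round(pid, 2),
                     overlap = ovl, stringsAsFactors = FALSE)
  # deterministic ranking: identity desc, then reference id
  hits <- hits[order(-pid, refs$id), ]
  hits$rank <- seq_len(nrow(hits))
  rownames(hits) <- NULL

  best <- hits$percent_identity[1L]
  cand <- hits[!duplicated(hits$taxon), c("taxon", "percent_identity")]
  cand <- cand[cand$percent_identity >= best - band, , drop = FALSE]
  rownames(cand) <- NULL
  if (best < floor) {
    level <- "none"
  } else if (nrow(cand) == 1L) {
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
  structure(list(query_id = query$id, hits = hits, candidates = cand,
                 decision_level = level, decision = decision),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("Query", x$query_id, "->", x$decision_level,
      if (!is.na(x$decision)) paste0("(", x$decision, ")"), "\n")
  print(utils::head(x$hits, 5L))
  invisible(x)
}

#' Write an identity hit table as TSV
#' @param x A `candidate_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(x, path) {
  write.table(format(x$hits, nsmall = 2), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
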