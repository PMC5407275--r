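# Barcode records: FASTA input, validation, and the barcode_set container.

#' Read barcode sequences from a FASTA file
#'
#' Parses a multi-record FASTA file into a `barcode_set`: a data frame with
#' one row per sequence and columns `id`, `taxon`, `sequence`, `role` and
#' `genetic_code`. The FASTA header is interpreted as `id [taxon...]`: the
#' first whitespace-delimited token is the record id, the remainder (if any)
#' the taxon label.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @param role Either `"query"` or `"reference"`, attached to every record.
#' @param genetic_code NCBI translation table id; 2 (vertebrate mitochondrial)
#'   and 5 (invertebrate mitochondrial) are the codes used for COI barcodes.
#' @return A `barcode_set` data frame. An empty file yields zero rows.
#' @export
read_fasta <- function(path, role = c("query", "reference"), genetic_code = 2) {
  role <- match.arg(role)
  if (!file.exists(path)) stop2("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(barcode_set(character(), character(), character(), role, genetic_code))
  }
  if (!startsWith(trimws(lines[1L]), ">")) {
    stop2("Malformed FASTA at line 1 of ", path, ": expected '>' header")
  }
  headers <- grepl("^>", lines)
  idx <- cumsum(headers)
  hdr <- sub("^>", "", trimws(lines[headers]))
  seqs <- vapply(split(lines[!headers], idx[!headers]), function(x) {
    toupper(gsub("[ \t]", "", paste(x, collapse = "")))
  }, character(1L))
  # entries with no sequence lines are missing from split(); fill as empty
  full <- setNames(character(length(hdr)), as.character(seq_along(hdr)))
  full[names(seqs)] <- seqs
  ids <- vapply(strsplit(hdr, "\\s+"), `[`, character(1L), 1L)
  taxa <- trimws(sub("^\\S+\\s*", "", hdr))
  taxa[taxa == ""] <- NA_character_
  bad <- which(!nzchar(full))
  if (length(bad)) {
    stop2("Malformed FASTA: entry '", ids[bad[1L]], "' (line ",
          which(headers)[bad[1L]], ") has no sequence")
  }
  barcode_set(ids, taxa, unname(full), role, genetic_code)
}

#' Construct a set of barcode records
#'
#' @param id Character vector of unique record ids.
#' @param taxon Species or higher-rank labels (`NA` allowed for queries).
#' @param sequence IUPAC DNA strings (characters `ACGTRYSWKMBDHVN-`).
#' @param role `"query"` or `"reference"`, recycled.
#' @param genetic_code NCBI translation table id, recycled.
#' @return A data frame of class `barcode_set`.
#' @export
barcode_set <- function(id, taxon = NA_character_, sequence = character(),
                        role = "query", genetic_code = 2) {
  n <- length(id)
  x <- data.frame(
    id = as.character(id),
    taxon = rep_len(as.character(taxon), n),
    sequence = toupper(rep_len(as.character(sequence), n)),
    role = rep_len(role, n),
    genetic_code = rep_len(as.integer(genetic_code), n),
    stringsAsFactors = FALSE
  )
  class(x) <- c("barcode_set", "data.frame")
  validate_barcode_set(x)
  x
}

validate_barcode_set <- function(x) {
  if (anyDuplicated(x$id)) {
    stop2("Duplicate record id(s): ",
          paste(unique(x$id[duplicated(x$id)]), collapse = ", "))
  }
  if (nrow(x)) {
    if (any(!nzchar(x$sequence))) stop2("Empty sequence for id ",
                                        x$id[!nzchar(x$sequence)][1L])
    chars <- unique(seq_chars(paste(x$sequence, collapse = "")))
    bad <- setdiff(chars, .valid_seq_chars)
    if (length(bad)) {
      stop2("Invalid sequence character(s): ", paste(bad, collapse = ", "))
    }
    if (!all(x$role %in% c("query", "reference"))) {
      stop2("role must be 'query' or 'reference'")
    }
  }
  invisible(x)
}

#' Write barcode records to FASTA
#'
#' @param x A `barcode_set`.
#' @param path Output file path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    hdr <- if (is.na(x$taxon[i])) x$id[i] else paste(x$id[i], x$taxon[i])
    writeLines(paste0(">", hdr), con)
    s <- x$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
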