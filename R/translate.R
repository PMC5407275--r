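# Mitochondrial translation and reading-frame selection.

# Codon -> amino acid map for an NCBI translation table id.
genetic_code_table <- function(genetic_code) {
  id <- as.character(genetic_code)
  tab <- tryCatch(Biostrings::getGeneticCode(id),
                  error = function(e) NULL)
  if (is.null(tab)) stop2("Unknown NCBI genetic code id: ", genetic_code)
  tab
}

#' Translate a DNA sequence under a mitochondrial genetic code
#'
#' Translates complete codons starting at `frame`. Stop codons are emitted as
#' `'*'`; any codon containing a gap or an ambiguity code (anything outside
#' `ACGT`) is emitted as `'X'`.
#'
#' @param sequence DNA string.
#' @param frame Reading-frame offset: 0, 1 or 2.
#' @param genetic_code NCBI translation table id (2 = vertebrate
#'   mitochondrial, 5 = invertebrate mitochondrial).
#' @return Amino-acid string of length `floor((nchar(sequence) - frame) / 3)`.
#' @export
translate_dna <- function(sequence, frame = 0L, genetic_code = 2) {
  stopifnot(frame %in% 0:2)
  tab <- genetic_code_table(genetic_code)
  s <- seq_chars(toupper(sequence))
  n <- length(s) - frame
  ncod <- n %/% 3L
  if (ncod <= 0L) return("")
  i0 <- frame + 3L * (seq_len(ncod) - 1L)
  codons <- paste0(s[i0 + 1L], s[i0 + 2L], s[i0 + 3L])
  aa <- unname(tab[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Choose the reading frame of a COI barcode sequence
#'
#' Translates the sequence in all three frames and returns the frame whose
#' translation contains the fewest stop codons (ties broken by the smallest
#' frame index). If every frame has a stop within the first 90% of its codons
#' the sequence is numt-suspect; the frame is still returned, with a warning.
#'
#' @param record One row of a `barcode_set` (or a list with `sequence` and
#'   `genetic_code`).
#' @return Integer frame 0, 1 or 2, with attribute `numt_suspect` (logical).
#' @export
pick_reading_frame <- function(record) {
  seqs <- record$sequence
  code <- record$genetic_code
  if (nchar(seqs) < 60L) stop2("Sequence too short for frame selection (< 60 bp)")
  stops <- integer(3L)
  early <- logical(3L)
  for (f in 0:2) {
    aa <- seq_chars(translate_dna(seqs, f, code))
    stops[f + 1L] <- sum(aa == "*")
    cutoff <- floor(0.9 * length(aa))
    early[f + 1L] <- any(aa[seq_len(cutoff)] == "*")
  }
  frame <- which.min(stops) - 1L
  suspect <- all(early)
  if (suspect) {
    warning("All frames contain early stop codons; sequence '",
            record$id %||% "?", "' is numt-suspect", call. = FALSE)
  }
  structure(frame, numt_suspect = suspect)
}
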