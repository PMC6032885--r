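#' Construct a set of labelled protein sequences
#'
#' The basic sequence container is a data frame with one row per protein and
#' columns `seq_id`, `taxon_id`, `supergroup`, `eu_domain`, `subfamily`
#' (`NA` when unknown; carries simulation ground truth or classification
#' results) and `residues`. FASTA round-trips preserve all labels by packing
#' them into the description line.
#'
#' @param seq_id character vector of unique sequence identifiers.
#' @param residues character vector of residue strings (alphabet: 20 amino
#'   acids plus `X`).
#' @param taxon_id,supergroup,eu_domain,subfamily optional label vectors,
#'   recycled to length.
#' @return A `data.frame` of class `seq_set`.
#' @export
seq_set <- function(seq_id, residues, taxon_id = NA_character_,
                    supergroup = NA_character_, eu_domain = NA_character_,
                    subfamily = NA_character_) {
  seq_id <- as.character(seq_id)
  residues <- toupper(as.character(residues))
  if (anyDuplicated(seq_id)) stop("seq_id values must be unique")
  if (any(!nzchar(residues))) stop("residues must be non-empty")
  bad <- grepl(paste0("[^", paste(AA21, collapse = ""), "]"), residues)
  if (any(bad)) stop("non-amino-acid characters in sequences: ",
                     paste(head(seq_id[bad], 3), collapse = ", "))
  n <- length(seq_id)
  out <- data.frame(seq_id = seq_id, taxon_id = rep_len(taxon_id, n),
                    supergroup = rep_len(supergroup, n),
                    eu_domain = rep_len(eu_domain, n),
                    subfamily = rep_len(as.character(subfamily), n),
                    residues = residues, stringsAsFactors = FALSE)
  class(out) <- c("seq_set", "data.frame")
  out
}

#' Write a sequence set to FASTA
#'
#' Labels are packed into the header as `id|taxon|supergroup|eu_domain|subfamily`
#' (`NA` for missing); lines wrap at 60 columns.
#'
#' @param seqs a [seq_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  hdr <- paste(seqs$seq_id, seqs$taxon_id, seqs$supergroup, seqs$eu_domain,
               seqs$subfamily, sep = "|")
  x <- Biostrings::AAStringSet(seqs$residues)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' Read a sequence set from FASTA
#'
#' Headers written by [write_fasta()] are unpacked back into label columns;
#' plain headers become `seq_id` with all labels `NA`.
#'
#' @param path FASTA file path.
#' @return A [seq_set()].
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  field <- function(i) vapply(parts, function(p) {
    v <- if (length(p) >= i) p[i] else NA_character_
    if (identical(v, "NA")) NA_character_ else v
  }, character(1))
  seq_set(seq_id = field(1), residues = as.character(x),
          taxon_id = field(2), supergroup = field(3), eu_domain = field(4),
          subfamily = field(5))
}
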