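#' Construct a backbone profile alignment
#'
#' A `profile_alignment` holds an immutable set of curated backbone rows
#' (fixed column set of width W), rows augmented onto it by
#' [align_to_profile()], and a per-column retention mask. Only backbone rows
#' define the columns and the mask; augmentation never modifies them.
#'
#' @param backbone_rows named character vector of equal-length aligned rows
#'   (residues and `-`); names are sequence ids.
#' @return A `profile_alignment` list: `backbone` (named character),
#'   `augmented` (named character), `dropped` (named integer, residues
#'   dropped per augmented row), `mask` (logical, length W).
#' @export
profile_alignment <- function(backbone_rows) {
  if (length(backbone_rows) == 0) stop("backbone must be non-empty")
  if (is.null(names(backbone_rows)) || anyDuplicated(names(backbone_rows)))
    stop("backbone rows must have unique names")
  W <- unique(nchar(backbone_rows))
  if (length(W) != 1) stop("backbone rows must have equal width")
  structure(list(backbone = toupper(backbone_rows),
                 augmented = setNames(character(0), character(0)),
                 dropped = setNames(integer(0), character(0)),
                 mask = rep(TRUE, W)),
            class = "profile_alignment")
}

#' @export
print.profile_alignment <- function(x, ...) {
  cat("profile_alignment:", length(x$backbone), "backbone rows,",
      length(x$augmented), "augmented rows, width", nchar(x$backbone[1]),
      "(", sum(x$mask), "columns retained )\n")
  invisible(x)
}

# Per-column profile scores for all 21 residue states: the score of residue
# r in column c is the mean substitution score of r against the column's
# non-gap backbone residues; in columns where some backbone rows are gapped,
# the gapped rows contribute -gap_extend to the mean.
.profile_scores <- function(backbone, sub_matrix, gap_extend) {
  ch <- do.call(rbind, strsplit(backbone, "", fixed = TRUE))
  W <- ncol(ch)
  prof <- matrix(0, nrow = 21, ncol = W)
  sm <- sub_matrix[AA21, AA21]
  for (j in seq_len(W)) {
    col <- ch[, j]
    res <- col[col != "-"]
    if (length(res) == 0) { # all-gap column: every state costs a gap
      prof[, j] <- -gap_extend
    } else {
      base <- rowMeans(sm[, res, drop = FALSE]) * length(res)
      prof[, j] <- (base - gap_extend * (length(col) - length(res))) /
        length(col)
    }
  }
  prof
}

#' Align one sequence onto a fixed-column backbone profile
#'
#' Global alignment of the sequence against the backbone's per-column
#' profile. Backbone columns are never split: query residues that would
#' insert between columns are dropped (with an affine penalty) and counted;
#' skipping a column places a gap in the augmented row. Traceback is
#' deterministic (match preferred over gaps, residue-drop over column-gap).
#'
#' @param residues residue string (or single-row [seq_set()]) to place.
#' @param backbone a [profile_alignment()].
#' @param sub_matrix,gap_open,gap_extend scoring parameters (defaults as in
#'   [local_align()]).
#' @return A list: `row` (character of width W), `dropped` (integer),
#'   `score`.
#' @export
align_to_profile <- function(residues, backbone,
                             sub_matrix = default_submatrix(),
                             gap_open = 11, gap_extend = 1) {
  if (inherits(residues, "seq_set")) residues <- residues$residues[1]
  if (!nzchar(residues)) stop("sequence must be non-empty")
  prof <- .profile_scores(backbone$backbone, sub_matrix, gap_extend)
  q <- encode_residues(residues)
  r <- .profile_align_cpp(q, prof, gap_open, gap_extend)
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  row <- ifelse(r$placement > 0, chars[pmax(r$placement, 1L)], "-")
  list(row = paste(row, collapse = ""), dropped = r$dropped, score = r$score)
}

#' Augment a backbone with a set of candidate sequences
#'
#' Each sequence is aligned independently against the original backbone
#' (never against previously augmented rows), so the result is independent
#' of input order. Dropped-residue counts are recorded per row as a
#' divergence warning signal.
#'
#' @param backbone a [profile_alignment()].
#' @param seqs a [seq_set()] of sequences to place.
#' @inheritParams align_to_profile
#' @return The backbone with `augmented` and `dropped` filled in.
#' @export
iterative_augment <- function(backbone, seqs,
                              sub_matrix = default_submatrix(),
                              gap_open = 11, gap_extend = 1) {
  if (is.null(seqs) || nrow(seqs) == 0) return(backbone)
  if (any(seqs$seq_id %in% names(backbone$backbone)))
    stop("augmented ids collide with backbone ids")
  rows <- character(nrow(seqs))
  dropped <- integer(nrow(seqs))
  for (i in seq_len(nrow(seqs))) {
    al <- align_to_profile(seqs$residues[i], backbone, sub_matrix,
                           gap_open, gap_extend)
    rows[i] <- al$row
    dropped[i] <- al$dropped
  }
  backbone$augmented <- c(backbone$augmented, setNames(rows, seqs$seq_id))
  backbone$dropped <- c(backbone$dropped, setNames(dropped, seqs$seq_id))
  backbone
}

#' Mask alignment columns by backbone occupancy
#'
#' A column is retained iff the fraction of non-gap characters among the
#' backbone rows is at least `min_occupancy` (boundary inclusive). Augmented
#' rows never influence the mask, mirroring a curation step applied to the
#' trusted backbone only.
#'
#' @param aln a [profile_alignment()].
#' @param min_occupancy retention threshold in (0, 1]; default 0.5.
#' @return The alignment with its `mask` replaced.
#' @export
mask_columns <- function(aln, min_occupancy = 0.5) {
  stopifnot(min_occupancy > 0, min_occupancy <= 1)
  ch <- do.call(rbind, strsplit(aln$backbone, "", fixed = TRUE))
  occ <- colMeans(ch != "-")
  aln$mask <- occ >= min_occupancy
  aln
}

#' Read/write a profile alignment as aligned FASTA plus a mask file
#'
#' The aligned FASTA holds backbone rows first, then augmented rows; the
#' mask is a single line of 0/1 characters of width W.
#'
#' @param aln a [profile_alignment()].
#' @param fasta_path,mask_path file paths.
#' @param n_backbone when reading, the number of leading rows that are
#'   backbone (defaults to all rows).
#' @return `write_profile` returns `fasta_path` invisibly; `read_profile`
#'   returns a `profile_alignment`.
#' @export
write_profile <- function(aln, fasta_path, mask_path = NULL) {
  rows <- c(aln$backbone, aln$augmented)
  x <- Biostrings::AAStringSet(rows)
  names(x) <- names(rows)
  Biostrings::writeXStringSet(x, filepath = fasta_path, width = 60L)
  if (!is.null(mask_path))
    writeLines(paste(as.integer(aln$mask), collapse = ""), mask_path)
  invisible(fasta_path)
}

#' @rdname write_profile
#' @export
read_profile <- function(fasta_path, mask_path = NULL, n_backbone = NULL) {
  x <- Biostrings::readAAStringSet(fasta_path)
  rows <- setNames(as.character(x), names(x))
  if (is.null(n_backbone)) n_backbone <- length(rows)
  aln <- profile_alignment(rows[seq_len(n_backbone)])
  if (n_backbone < length(rows)) {
    aln$augmented <- rows[(n_backbone + 1L):length(rows)]
    aln$dropped <- setNames(rep(NA_integer_, length(aln$augmented)),
                            names(aln$augmented))
  }
  if (!is.null(mask_path)) {
    m <- readLines(mask_path, warn = FALSE)[1]
    aln$mask <- strsplit(m, "", fixed = TRUE)[[1]] == "1"
  }
  aln
}
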