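#' Build a position-specific scoring model from aligned domain columns
#'
#' Per-column log-odds scores against a uniform background of 1/20:
#' `score(r, c) = 2 * log2((freq(r, c) + pseudocount * bg) / (bg * (1 + pseudocount)))`
#' in half-bits. Gap characters are ignored when counting column frequencies;
#' `X` always scores 0.
#'
#' @param aligned_block character vector of equal-length aligned rows
#'   (residues and `-`), at least 2 rows, no all-gap columns.
#' @param name model name (e.g. `"Vps9"`).
#' @param pseudocount additive pseudocount weight (default 1).
#' @param threshold hit threshold in half-bits for [scan_domains()]. The
#'   default, half of the model's maximum attainable window score, accepts
#'   windows retaining at least half of the consensus signal.
#' @return A `domain_model` list: `name`, `L`, `scores` (L x 21 matrix,
#'   half-bits), `threshold`.
#' @export
build_pssm <- function(aligned_block, name = "domain", pseudocount = 1,
                       threshold = NULL) {
  rows <- toupper(aligned_block)
  if (length(rows) < 2) stop("need at least 2 aligned rows")
  W <- unique(nchar(rows))
  if (length(W) != 1) stop("aligned rows must have equal length")
  ch <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  bg <- 1 / 20
  scores <- matrix(0, nrow = W, ncol = 21, dimnames = list(NULL, AA21))
  for (j in seq_len(W)) {
    col <- ch[, j]
    col <- col[col != "-"]
    if (length(col) == 0) stop("all-gap column at position ", j)
    freq <- table(factor(col, levels = AA20)) / length(col)
    scores[j, AA20] <- 2 * log2((as.numeric(freq) + pseudocount * bg) /
                                  (bg * (1 + pseudocount)))
  }
  if (is.null(threshold)) threshold <- 0.5 * sum(apply(scores, 1, max))
  structure(list(name = name, L = W, scores = scores, threshold = threshold),
            class = "domain_model")
}

#' Annotate domain architecture by sliding-window PSSM scan
#'
#' For each model, every length-L window of the sequence is scored gaplessly
#' against the model's position-specific scores; windows at or above the
#' model threshold are accepted, and the highest-scoring non-overlapping set
#' is kept greedily (score ties resolve to the leftmost window). Hits from
#' all models are merged into a single non-overlapping, coordinate-sorted
#' architecture.
#'
#' @param residues a residue string (or a single-row [seq_set()]).
#' @param models a list of `domain_model` objects from [build_pssm()].
#' @return A data.frame `architecture`: `domain`, `start`, `end` (0-based
#'   half-open), `score`; and attribute `"string"` like `"MORN-MORN-Vps9"`.
#' @export
scan_domains <- function(residues, models) {
  if (inherits(residues, "seq_set")) residues <- residues$residues[1]
  if (inherits(models, "domain_model")) models <- list(models)
  enc <- encode_residues(residues) + 1L
  n <- length(enc)
  hits <- list()
  for (m in models) {
    L <- m$L
    if (n < L) next
    nw <- n - L + 1L
    sc <- vapply(seq_len(nw), function(s) {
      sum(m$scores[cbind(seq_len(L), enc[s:(s + L - 1L)])])
    }, numeric(1))
    keep <- which(sc >= m$threshold)
    if (length(keep))
      hits[[length(hits) + 1L]] <- data.frame(
        domain = m$name, start = keep - 1L, end = keep - 1L + L,
        score = sc[keep], stringsAsFactors = FALSE)
  }
  arch <- data.frame(domain = character(), start = integer(),
                     end = integer(), score = numeric(),
                     stringsAsFactors = FALSE)
  if (length(hits)) {
    all_hits <- do.call(rbind, hits)
    all_hits <- all_hits[order(-all_hits$score, all_hits$start,
                               all_hits$domain), ]
    taken <- rep(FALSE, n)
    for (i in seq_len(nrow(all_hits))) {
      span <- (all_hits$start[i] + 1L):all_hits$end[i]
      if (!any(taken[span])) {
        taken[span] <- TRUE
        arch <- rbind(arch, all_hits[i, ])
      }
    }
    arch <- arch[order(arch$start), ]
    rownames(arch) <- NULL
  }
  attr(arch, "string") <- paste(arch$domain, collapse = "-")
  arch
}
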