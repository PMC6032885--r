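#' Local pairwise alignment (Smith-Waterman with affine gaps)
#'
#' Computes the maximal-scoring local alignment between two residue strings
#' under a substitution matrix and affine gap penalties (a gap of length k
#' costs `gap_open + k * gap_extend`). Score ties are broken toward the
#' alignment with the lexicographically smallest start coordinates.
#' Unknown residues (`X`) score 0 against everything under the default
#' matrix; any other non-amino-acid character is an error.
#'
#' @param a,b residue strings.
#' @param sub_matrix substitution matrix with residue dimnames
#'   (default [default_submatrix()]).
#' @param gap_open,gap_extend affine gap penalties (positive costs);
#'   defaults 11 and 1, the conventional protein-search values.
#' @return A list with `score` (raw matrix units), `span_a` and `span_b`
#'   (0-based half-open integer vectors `c(start, end)`).
#' @export
local_align <- function(a, b, sub_matrix = default_submatrix(),
                        gap_open = 11, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  sm <- sub_matrix[AA21, AA21]
  r <- .sw_align_cpp(encode_residues(a), encode_residues(b), sm,
                     gap_open, gap_extend)
  list(score = r[1], span_a = as.integer(r[c(2, 3)]),
       span_b = as.integer(r[c(4, 5)]))
}

#' Karlin-Altschul E-value for a raw local alignment score
#'
#' Converts a raw score to a bit score `S' = (lambda * S - ln K) / ln 2`
#' and returns the expected number of chance alignments
#' `E = m * n * 2^(-S')` for a search space of query length `m` against
#' target length `n`.
#'
#' @param S raw alignment score.
#' @param m,n query and target sequence lengths.
#' @param lambda,K Karlin-Altschul parameters; defaults 0.267 and 0.041
#'   (gapped BLOSUM62 with gap costs 11/1).
#' @return A list with `bits` and `evalue`.
#' @export
evalue <- function(S, m, n, lambda = 0.267, K = 0.041) {
  stopifnot(m >= 1, n >= 1, lambda > 0, K > 0)
  bits <- (lambda * S - log(K)) / log(2)
  list(bits = bits, evalue = m * n * 2^(-bits))
}

# Best hit of one query against a proteome: highest raw score, ties by
# lexicographic target id. Returns a one-row data.frame or NULL.
.best_hit <- function(query_res, query_id, proteome, sub_matrix, gap_open,
                      gap_extend, lambda, K) {
  if (nrow(proteome) == 0) return(NULL)
  scores <- numeric(nrow(proteome))
  spans <- vector("list", nrow(proteome))
  for (i in seq_len(nrow(proteome))) {
    al <- local_align(query_res, proteome$residues[i], sub_matrix,
                      gap_open, gap_extend)
    scores[i] <- al$score
    spans[[i]] <- al
  }
  ord <- order(-scores, proteome$seq_id)
  i <- ord[1]
  ev <- evalue(scores[i], nchar(query_res), nchar(proteome$residues[i]),
               lambda, K)
  data.frame(query_id = query_id, target_id = proteome$seq_id[i],
             score = scores[i], bits = ev$bits, evalue = ev$evalue,
             q_start = spans[[i]]$span_a[1], q_end = spans[[i]]$span_a[2],
             t_start = spans[[i]]$span_b[1], t_end = spans[[i]]$span_b[2],
             stringsAsFactors = FALSE)
}

#' Reciprocal-best-hit candidate screening
#'
#' Identifies candidate family members in a target proteome: a target
#' sequence is retained for a query iff (i) it is the query's best forward
#' hit set member with E-value below `e_max`, and (ii) searching the
#' candidate back against the source proteome returns the query -- or a
#' member of the query's designated orthologue set -- as the top hit, again
#' with E-value below `e_max`. "Clear orthologue" sets are explicit, never
#' inferred.
#'
#' @param queries a [seq_set()] of query sequences (must be drawn from
#'   `source`'s proteome ids unless `orthologue_sets` covers them).
#' @param source the source proteome ([seq_set()]) searched in the reverse
#'   direction.
#' @param target the target proteome screened for candidates.
#' @param e_max E-value gate applied to both directions (default 0.05).
#' @param orthologue_sets optional named list: for each query id, a character
#'   vector of source ids accepted as "clear orthologues" in the reverse
#'   search (the query id itself is always accepted).
#' @param sub_matrix,gap_open,gap_extend,lambda,K scoring parameters passed
#'   to [local_align()] and [evalue()].
#' @return A data.frame with one row per retained candidate: `candidate_id`,
#'   `query_id`, forward/reverse scores and E-values.
#' @export
reciprocal_best_hits <- function(queries, source, target, e_max = 0.05,
                                 orthologue_sets = list(),
                                 sub_matrix = default_submatrix(),
                                 gap_open = 11, gap_extend = 1,
                                 lambda = 0.267, K = 0.041) {
  out <- list()
  if (nrow(target) == 0 || nrow(source) == 0) {
    return(data.frame(candidate_id = character(), query_id = character(),
                      fwd_score = numeric(), fwd_evalue = numeric(),
                      rev_score = numeric(), rev_evalue = numeric(),
                      stringsAsFactors = FALSE))
  }
  # forward: score every query against every target once
  fwd_scores <- matrix(0, nrow(queries), nrow(target),
                       dimnames = list(queries$seq_id, target$seq_id))
  fwd_ev <- fwd_scores
  for (qi in seq_len(nrow(queries))) {
    for (ti in seq_len(nrow(target))) {
      al <- local_align(queries$residues[qi], target$residues[ti],
                        sub_matrix, gap_open, gap_extend)
      fwd_scores[qi, ti] <- al$score
      fwd_ev[qi, ti] <- evalue(al$score, nchar(queries$residues[qi]),
                               nchar(target$residues[ti]), lambda, K)$evalue
    }
  }
  # candidates: per query, every target whose E passes the gate and which is
  # a best hit for that query (ties on E by higher raw score then id)
  for (qi in seq_len(nrow(queries))) {
    qid <- queries$seq_id[qi]
    ok <- which(fwd_ev[qi, ] < e_max)
    if (length(ok) == 0) next
    accepted <- unique(c(qid, orthologue_sets[[qid]]))
    for (ti in ok) {
      rev <- .best_hit(target$residues[ti], target$seq_id[ti], source,
                       sub_matrix, gap_open, gap_extend, lambda, K)
      if (is.null(rev)) next
      if (rev$target_id %in% accepted && rev$evalue < e_max) {
        out[[length(out) + 1L]] <- data.frame(
          candidate_id = target$seq_id[ti], query_id = qid,
          fwd_score = fwd_scores[qi, ti], fwd_evalue = fwd_ev[qi, ti],
          rev_score = rev$score, rev_evalue = rev$evalue,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(candidate_id = character(), query_id = character(),
                      fwd_score = numeric(), fwd_evalue = numeric(),
                      rev_score = numeric(), rev_evalue = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  # a candidate may pass for several queries; keep its best (lowest reverse
  # E, then highest forward score, then query id) assignment
  res <- res[order(res$candidate_id, res$rev_evalue, -res$fwd_score,
                   res$query_id), ]
  res <- res[!duplicated(res$candidate_id), ]
  rownames(res) <- NULL
  res
}
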