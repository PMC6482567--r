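# Default nucleotide scoring for local alignment (BLASTN-like):
# match +2, mismatch -3, gap open -5, gap extend -2.
.default_scoring <- function() {
  list(match = 2, mismatch = -3, gap_open = 5, gap_extend = 2)
}

#' Optimal local alignment of two nucleotide sequences
#'
#' Exact Smith-Waterman (dynamic programming via Biostrings), replacing a
#' heuristic BLASTN search: deterministic and optimal on gene-family-sized
#' inputs. Identity is computed over aligned columns excluding gap columns
#' (BLAST convention); `aligned_len` counts columns where both sequences
#' have a residue.
#'
#' @param seq_a,seq_b nucleotide strings.
#' @param scoring list with `match`, `mismatch`, `gap_open`, `gap_extend`
#'   (penalties as positive costs).
#' @return list with `score`, `aligned_len`, `identity`, and the two
#'   aligned (gapped) strings `aln_a`, `aln_b`.
#' @export
local_align <- function(seq_a, seq_b, scoring = .default_scoring()) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence in local_align()")
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
    type = "local", substitutionMatrix = mat,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  a <- as.character(Biostrings::alignedPattern(al))
  b <- as.character(Biostrings::alignedSubject(al))
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  both <- ca != "-" & cb != "-"
  list(score = Biostrings::score(al),
       aligned_len = sum(both),
       identity = if (any(both)) sum(ca[both] == cb[both]) / sum(both) else 0,
       aln_a = a, aln_b = b)
}

#' Find paralogous pairs within one species
#'
#' All unordered pairs are locally aligned; pairs with strictly more than
#' `min_aligned` aligned base pairs and identity at or above `min_identity`
#' are reported. A gene may join several pairs.
#'
#' @param seqs named character vector of CDS/transcript sequences.
#' @param min_aligned aligned-length threshold (exclusive), default 300 bp.
#' @param min_identity identity threshold (inclusive), default 0.40.
#' @param scoring see [local_align()].
#' @return data.frame `id_a`, `id_b` (lexicographic within and across
#'   rows), `relation = "paralog"`, `score`, `aligned_len`, `identity`.
#' @export
find_paralogs <- function(seqs, min_aligned = 300L, min_identity = 0.40,
                          scoring = .default_scoring()) {
  ids <- sort(names(seqs))
  if (length(ids) < 2L) stop("need at least 2 sequences")
  out <- list()
  for (i in seq_len(length(ids) - 1L)) {
    for (j in (i + 1L):length(ids)) {
      st <- local_align(seqs[[ids[i]]], seqs[[ids[j]]], scoring)
      if (st$aligned_len > min_aligned && st$identity >= min_identity)
        out[[length(out) + 1L]] <- data.frame(
          id_a = ids[i], id_b = ids[j], relation = "paralog",
          score = st$score, aligned_len = st$aligned_len,
          identity = st$identity)
    }
  }
  if (!length(out))
    return(data.frame(id_a = character(), id_b = character(),
                      relation = character(), score = numeric(),
                      aligned_len = integer(), identity = numeric()))
  res <- do.call(rbind, out)
  res[order(res$id_a, res$id_b), , drop = FALSE]
}

#' Find orthologous pairs between two species by reciprocal best hit
#'
#' Every sequence of set A is aligned against every sequence of set B;
#' `(a, b)` is orthologous when each is the other's best-scoring hit and
#' their alignment covers strictly more than `min_aligned` base pairs.
#' Best-hit ties are broken lexicographically (and noted in the
#' `tie_broken` column).
#'
#' @param seqs_a,seqs_b named character vectors for species A and B.
#' @param min_aligned aligned-length threshold (exclusive), default 300 bp.
#' @param scoring see [local_align()].
#' @return data.frame `id_a`, `id_b`, `relation = "ortholog"`, `score`,
#'   `aligned_len`, `identity`, `tie_broken`.
#' @export
find_orthologs <- function(seqs_a, seqs_b, min_aligned = 300L,
                           scoring = .default_scoring()) {
  if (!length(seqs_a) || !length(seqs_b)) stop("both sequence sets must be non-empty")
  ids_a <- sort(names(seqs_a))
  ids_b <- sort(names(seqs_b))
  score <- matrix(0, length(ids_a), length(ids_b), dimnames = list(ids_a, ids_b))
  alen <- score
  ident <- score
  for (a in ids_a) for (b in ids_b) {
    st <- local_align(seqs_a[[a]], seqs_b[[b]], scoring)
    score[a, b] <- st$score
    alen[a, b] <- st$aligned_len
    ident[a, b] <- st$identity
  }
  best_b <- apply(score, 1L, function(r) colnames(score)[which.max(r)])  # ids sorted: which.max = lexicographic tie-break
  best_a <- apply(score, 2L, function(cl) rownames(score)[which.max(cl)])
  tie_b <- apply(score, 1L, function(r) sum(r == max(r)) > 1L)
  tie_a <- apply(score, 2L, function(cl) sum(cl == max(cl)) > 1L)
  out <- list()
  for (a in ids_a) {
    b <- best_b[[a]]
    if (best_a[[b]] == a && alen[a, b] > min_aligned)
      out[[length(out) + 1L]] <- data.frame(
        id_a = a, id_b = b, relation = "ortholog", score = score[a, b],
        aligned_len = alen[a, b], identity = ident[a, b],
        tie_broken = tie_b[[a]] || tie_a[[b]])
  }
  if (!length(out))
    return(data.frame(id_a = character(), id_b = character(),
                      relation = character(), score = numeric(),
                      aligned_len = integer(), identity = numeric(),
                      tie_broken = logical()))
  res <- do.call(rbind, out)
  res[order(res$id_a, res$id_b), , drop = FALSE]
}
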