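# Independent brute-force oracles. These deliberately re-derive everything
# from first principles (explicit enumeration, no shared helpers with the
# package internals beyond the standard genetic code constant).

GC <- Biostrings::GENETIC_CODE
NUC <- c("A", "C", "G", "T")

# --- NG86 oracle ------------------------------------------------------------

# synonymous site count of one codon: per position, fraction of synonymous
# changes among changes not producing a stop codon
oracle_syn_sites <- function(codon) {
  total <- 0
  for (pos in 1:3) {
    alts <- setdiff(NUC, substr(codon, pos, pos))
    muts <- vapply(alts, function(b) {
      m <- codon; substr(m, pos, pos) <- b; m
    }, character(1))
    keep <- GC[muts] != "*"
    if (!any(keep)) next
    total <- total + sum(GC[muts[keep]] == GC[codon]) / sum(keep)
  }
  total
}

# all orderings of the differing positions, as a list of integer vectors
oracle_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in oracle_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# average syn/nonsyn differences between two codons over minimal pathways,
# excluding pathways through stops (all pathways if every one is blocked)
oracle_codon_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(0, 0))
  count_path <- function(order, skip) {
    cur <- c1; sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (skip && GC[nxt] == "*" && nxt != c2) return(NULL)
      if (GC[cur] == GC[nxt] && GC[cur] != "*") sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  paths <- Filter(Negate(is.null),
                  lapply(oracle_perms(pos), count_path, skip = TRUE))
  if (!length(paths)) paths <- lapply(oracle_perms(pos), count_path, skip = FALSE)
  colMeans(do.call(rbind, paths))
}

# full NG86 counts for two equal-length gapless CDS
oracle_ng86_counts <- function(cds_a, cds_b) {
  n <- nchar(cds_a)
  ca <- substring(cds_a, seq(1, n, 3), seq(3, n, 3))
  cb <- substring(cds_b, seq(1, n, 3), seq(3, n, 3))
  S <- (sum(vapply(ca, oracle_syn_sites, numeric(1))) +
        sum(vapply(cb, oracle_syn_sites, numeric(1)))) / 2
  d <- rowSums(mapply(oracle_codon_diffs, ca, cb))
  list(S = S, N = n - S, Sd = d[1], Nd = d[2])
}

# --- IUPAC scan oracle ------------------------------------------------------

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A","G"), Y = c("C","T"), S = c("C","G"),
                   W = c("A","T"), K = c("G","T"), M = c("A","C"),
                   B = c("C","G","T"), D = c("A","G","T"),
                   H = c("A","C","T"), V = c("A","C","G"),
                   N = c("A","C","G","T"))

oracle_complement <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                       S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                       D = "H", H = "D", N = "N")

oracle_revcomp <- function(x) {
  paste(rev(oracle_complement[strsplit(x, "")[[1]]]), collapse = "")
}

# 0-based starts of every window of `subject` compatible with the consensus
oracle_iupac_starts <- function(consensus, subject) {
  cs <- strsplit(consensus, "")[[1]]
  ss <- strsplit(subject, "")[[1]]
  w <- length(cs)
  if (length(ss) < w) return(integer())
  hits <- integer()
  for (s in 0:(length(ss) - w)) {
    ok <- TRUE
    for (k in seq_len(w)) {
      if (!(ss[s + k] %in% IUPAC_SETS[[cs[k]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

# full two-strand hit list with palindrome dedupe, mirroring the contract
oracle_scan_one <- function(consensus, subject) {
  fwd <- oracle_iupac_starts(consensus, subject)
  rc <- oracle_revcomp(consensus)
  rev <- oracle_iupac_starts(rc, subject)
  if (rc == consensus) rev <- setdiff(rev, fwd)
  data.frame(start = c(fwd, rev),
             strand = rep(c("+", "-"), c(length(fwd), length(rev))))
}

# --- homology oracle --------------------------------------------------------

# literal application of the paralog thresholds to every unordered pair
oracle_paralogs <- function(seqs, min_aligned = 300, min_identity = 0.40) {
  ids <- sort(names(seqs))
  out <- list()
  for (i in seq_len(length(ids) - 1)) for (j in (i + 1):length(ids)) {
    st <- local_align(seqs[[ids[i]]], seqs[[ids[j]]])
    if (st$aligned_len > min_aligned && st$identity >= min_identity)
      out[[length(out) + 1]] <- c(ids[i], ids[j])
  }
  out
}

# literal reciprocal-best-hit enumeration
oracle_rbh <- function(seqs_a, seqs_b, min_aligned = 300) {
  score <- function(x, y) local_align(x, y)$score
  ids_a <- sort(names(seqs_a)); ids_b <- sort(names(seqs_b))
  S <- outer(ids_a, ids_b, Vectorize(function(a, b) score(seqs_a[[a]], seqs_b[[b]])))
  dimnames(S) <- list(ids_a, ids_b)
  out <- list()
  for (a in ids_a) {
    b <- ids_b[which.max(S[a, ])]
    if (ids_a[which.max(S[, b])] == a &&
        local_align(seqs_a[[a]], seqs_b[[b]])$aligned_len > min_aligned)
      out[[length(out) + 1]] <- c(a, b)
  }
  out
}

# --- misc helpers -----------------------------------------------------------

# additive distance matrix from a random tree with strictly positive branches
random_additive_matrix <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = function(n) stats::runif(n, 0.1, 1))
  tr <- ape::unroot(tr)
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# mutate a protein sequence at k positions (for distance fixtures)
mutate_protein <- function(aa, k) {
  ch <- strsplit(aa, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(names(famevol:::.RESIDUE_MASS), ch[p]), 1)
  paste(ch, collapse = "")
}
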