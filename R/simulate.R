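# ---- coding-sequence evolution under the NG86 site model ------------------

.SENSE_CODONS <- local({
  all <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                           c("A","C","G","T"), stringsAsFactors = FALSE)[, 3:1],
               1, paste, collapse = "")
  all[Biostrings::GENETIC_CODE[all] != "*"]
})

#' Random coding sequence without stop codons
#'
#' Codons are drawn uniformly from the 61 sense codons; the first codon is
#' forced to ATG. Uses the session RNG (seed it in the caller).
#'
#' @param n_codons number of codons.
#' @return CDS string of length `3 * n_codons`.
#' @export
random_cds <- function(n_codons) {
  stopifnot(n_codons >= 2L)
  paste(c("ATG", sample(.SENSE_CODONS, n_codons - 1L, replace = TRUE)),
        collapse = "")
}

#' Evolve a coding sequence to a target synonymous divergence
#'
#' Single-nucleotide substitutions are proposed at random positions;
#' proposals creating a stop codon are rejected, synonymous changes are
#' accepted with probability 1 and nonsynonymous changes with probability
#' `omega`. Accepted events are counted until the expected per-site
#' synonymous divergence (synonymous events per ancestral synonymous site)
#' reaches `target_ks`. Uses the session RNG.
#'
#' @param cds ancestral coding sequence (no internal stops).
#' @param target_ks target synonymous substitutions per synonymous site.
#' @param omega relative acceptance probability of nonsynonymous changes.
#' @return list `seq` (evolved CDS), `syn_events`, `nonsyn_events`,
#'   `s_sites`, `n_sites` (ancestral NG86 site counts), `ks_true`,
#'   `ka_true` (realized events per ancestral site).
#' @export
evolve_cds <- function(cds, target_ks, omega) {
  stopifnot(target_ks >= 0, omega > 0)
  n <- nchar(cds)
  sites <- .codon_sites()
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  S <- sum(sites[codons])
  N <- n - S
  cur <- strsplit(cds, "")[[1]]
  syn_ev <- 0L; nonsyn_ev <- 0L
  max_iter <- max(1000L, 4000L * n)
  iter <- 0L
  while (S > 0 && syn_ev / S < target_ks) {
    iter <- iter + 1L
    if (iter > max_iter)
      stop("target Ks ", target_ks, " unreachable (saturation); use a lower value")
    pos <- sample.int(n, 1L)
    old <- cur[pos]
    new <- sample(setdiff(c("A","C","G","T"), old), 1L)
    ci <- (pos - 1L) %/% 3L
    cod_old <- paste(cur[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
    cod_new <- cod_old
    substr(cod_new, pos - ci * 3L, pos - ci * 3L) <- new
    aa_old <- .GENETIC_CODE[cod_old]
    aa_new <- .GENETIC_CODE[cod_new]
    if (aa_new == "*") next
    syn <- aa_new == aa_old
    if (!syn && stats::runif(1) > omega) next
    cur[pos] <- new
    if (syn) syn_ev <- syn_ev + 1L else nonsyn_ev <- nonsyn_ev + 1L
  }
  list(seq = paste(cur, collapse = ""), syn_events = syn_ev,
       nonsyn_events = nonsyn_ev, s_sites = S, n_sites = N,
       ks_true = syn_ev / S, ka_true = nonsyn_ev / N)
}

#' Simulate a gene family of duplicate pairs with known divergence
#'
#' Each duplication event keeps the ancestral copy and evolves a duplicate
#' to its target synonymous divergence under the given omega, so realized
#' event counts are the ground truth for estimator-recovery tests.
#'
#' @param pairs data.frame with columns `pair_id`, `ks`, `omega`.
#' @param codon_length CDS length in codons (default 500).
#' @param n_decoys unrelated random genes added to the set (default 0).
#' @param seed mandatory RNG seed.
#' @return list `seqs` (named CDS vector: `<pair_id>a`, `<pair_id>b`,
#'   `decoy<k>`) and `truth` (per-pair realized `ks_true`, `ka_true`,
#'   event and site counts).
#' @export
simulate_family <- function(pairs, codon_length = 500L, n_decoys = 0L, seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(all(c("pair_id", "ks", "omega") %in% names(pairs)))
  set.seed(seed)
  seqs <- character(0)
  truth <- list()
  for (i in seq_len(nrow(pairs))) {
    anc <- random_cds(codon_length)
    ev <- evolve_cds(anc, pairs$ks[i], pairs$omega[i])
    ids <- paste0(pairs$pair_id[i], c("a", "b"))
    seqs[ids] <- c(anc, ev$seq)
    truth[[i]] <- data.frame(pair_id = pairs$pair_id[i], id_a = ids[1],
                             id_b = ids[2], target_ks = pairs$ks[i],
                             omega = pairs$omega[i], ks_true = ev$ks_true,
                             ka_true = ev$ka_true, syn_events = ev$syn_events,
                             nonsyn_events = ev$nonsyn_events,
                             s_sites = ev$s_sites, n_sites = ev$n_sites)
  }
  if (n_decoys > 0L)
    for (k in seq_len(n_decoys)) seqs[paste0("decoy", k)] <- random_cds(codon_length)
  list(seqs = sequence_set(seqs, "dna"), truth = do.call(rbind, truth))
}

#' Simulate one-to-one ortholog pairs across two species
#'
#' Each pair descends from a common ancestor; each species' copy evolves
#' half the target divergence independently. Decoy genes (unrelated) can be
#' added to either species.
#'
#' @param pairs data.frame with columns `pair_id`, `ks`, `omega`.
#' @param codon_length CDS length in codons.
#' @param n_decoys_a,n_decoys_b unrelated genes per species.
#' @param prefixes length-2 character vector of species id prefixes.
#' @param seed mandatory RNG seed.
#' @return list `seqs_a`, `seqs_b` (named CDS vectors) and `truth`.
#' @export
simulate_two_species <- function(pairs, codon_length = 500L, n_decoys_a = 0L,
                                 n_decoys_b = 0L, prefixes = c("pe", "os"),
                                 seed) {
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  seqs_a <- character(0); seqs_b <- character(0)
  truth <- list()
  for (i in seq_len(nrow(pairs))) {
    anc <- random_cds(codon_length)
    ev_a <- evolve_cds(anc, pairs$ks[i] / 2, pairs$omega[i])
    ev_b <- evolve_cds(anc, pairs$ks[i] / 2, pairs$omega[i])
    id_a <- paste0(prefixes[1], pairs$pair_id[i])
    id_b <- paste0(prefixes[2], pairs$pair_id[i])
    seqs_a[id_a] <- ev_a$seq
    seqs_b[id_b] <- ev_b$seq
    truth[[i]] <- data.frame(pair_id = pairs$pair_id[i], id_a = id_a,
                             id_b = id_b, target_ks = pairs$ks[i],
                             ks_true = ev_a$ks_true + ev_b$ks_true,
                             ka_true = ev_a$ka_true + ev_b$ka_true)
  }
  if (n_decoys_a > 0L)
    for (k in seq_len(n_decoys_a))
      seqs_a[paste0(prefixes[1], "_decoy", k)] <- random_cds(codon_length)
  if (n_decoys_b > 0L)
    for (k in seq_len(n_decoys_b))
      seqs_b[paste0(prefixes[2], "_decoy", k)] <- random_cds(codon_length)
  list(seqs_a = sequence_set(seqs_a, "dna"),
       seqs_b = sequence_set(seqs_b, "dna"),
       truth = do.call(rbind, truth))
}

.IUPAC_EXPAND <- list(A = "A", C = "C", G = "G", T = "T",
                      R = c("A","G"), Y = c("C","T"), S = c("C","G"),
                      W = c("A","T"), K = c("G","T"), M = c("A","C"),
                      B = c("C","G","T"), D = c("A","G","T"),
                      H = c("A","C","T"), V = c("A","C","G"),
                      N = c("A","C","G","T"))

.realize_iupac <- function(consensus) {
  paste(vapply(strsplit(consensus, "")[[1]],
               function(ch) sample(.IUPAC_EXPAND[[ch]], 1L), character(1)),
        collapse = "")
}

# hit count of one element on both strands with palindrome dedupe
.element_count <- function(consensus, subject) {
  fwd <- .iupac_matches(consensus, subject)
  rev <- .iupac_matches(revcomp(consensus), subject)
  rev <- setdiff(rev, fwd[revcomp(consensus) == consensus])
  length(fwd) + length(rev)
}

#' Simulate promoters with planted cis-elements at known positions
#'
#' Backgrounds are i.i.d. uniform ACGT; for every element requested for a
#' gene (including zero-count requests) the background plus plants is
#' rejection-sampled until the scan count equals the request exactly, so
#' planted coordinates are exhaustive ground truth.
#'
#' @param plants data.frame with columns `gene_id`, `element`, `count`.
#' @param dict element dictionary.
#' @param promoter_len promoter length in bp (default 2000).
#' @param seed mandatory RNG seed.
#' @param max_attempts rejection-sampling attempts per promoter.
#' @return list `promoters` (named character) and `truth` (data.frame
#'   `gene_id`, `element`, `start` 0-based, `strand`).
#' @export
simulate_promoters <- function(plants, dict = read_element_dictionary(),
                               promoter_len = 2000L, seed, max_attempts = 200L) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(all(c("gene_id", "element", "count") %in% names(plants)))
  unknown <- setdiff(plants$element, dict$element)
  if (length(unknown)) stop("elements not in dictionary: ",
                            paste(unknown, collapse = ", "))
  set.seed(seed)
  promoters <- character(0)
  truth <- list()
  for (g in unique(plants$gene_id)) {
    req <- plants[plants$gene_id == g, , drop = FALSE]
    widths <- nchar(dict$iupac[match(req$element, dict$element)])
    if (sum(req$count * widths) > promoter_len)
      stop("requested plants exceed promoter capacity for gene ", g)
    consensi <- dict$iupac[match(req$element, dict$element)]
    # spurious-match spans (both strands) of the requested elements
    spurious <- function(seq, occupied) {
      spans <- list()
      for (cons in consensi) {
        w <- nchar(cons)
        starts <- unique(c(.iupac_matches(cons, seq),
                           .iupac_matches(revcomp(cons), seq)))
        for (s in starts) {
          span <- (s + 1L):(s + w)
          if (!all(occupied[span])) spans[[length(spans) + 1L]] <- span
        }
      }
      spans
    }
    done <- FALSE
    for (attempt in seq_len(max_attempts)) {
      bases <- sample(c("A","C","G","T"), promoter_len, replace = TRUE)
      seq <- paste(bases, collapse = "")
      occupied <- rep(FALSE, promoter_len)
      rec <- list()
      ok <- TRUE
      # plant at random non-overlapping positions
      for (r in seq_len(nrow(req))) {
        cons <- consensi[r]
        w <- nchar(cons)
        placed <- 0L
        guard <- 0L
        while (placed < req$count[r]) {
          guard <- guard + 1L
          if (guard > 1000L) { ok <- FALSE; break }
          start <- sample.int(promoter_len - w + 1L, 1L)
          span <- start:(start + w - 1L)
          if (any(occupied[span])) next
          strand <- sample(c("+", "-"), 1L)
          ins <- .realize_iupac(cons)
          if (strand == "-") ins <- revcomp(ins)
          substr(seq, start, start + w - 1L) <- ins
          occupied[span] <- TRUE
          rec[[length(rec) + 1L]] <- data.frame(
            gene_id = g, element = req$element[r], start = start - 1L,
            strand = strand)
          placed <- placed + 1L
        }
        if (!ok) break
      }
      if (!ok) next
      # scrub accidental background matches by resampling their free bases
      for (scrub in 1:100) {
        spans <- spurious(seq, occupied)
        if (!length(spans)) break
        fixable <- TRUE
        for (span in spans) {
          free <- span[!occupied[span]]
          if (!length(free)) { fixable <- FALSE; break }
          for (p in free) substr(seq, p, p) <- sample(c("A","C","G","T"), 1L)
        }
        if (!fixable) break
      }
      # accept only if the scan count equals the request for every element
      counts <- vapply(consensi, .element_count, integer(1), subject = seq)
      if (all(counts == req$count)) {
        promoters[g] <- seq
        if (length(rec)) truth[[length(truth) + 1L]] <- do.call(rbind, rec)
        done <- TRUE
        break
      }
    }
    if (!done) stop("could not realize requested plants for gene ", g,
                    " in ", max_attempts, " attempts")
  }
  list(promoters = promoters,
       truth = if (length(truth)) do.call(rbind, truth)
               else data.frame(gene_id = character(), element = character(),
                               start = integer(), strand = character()))
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' The reference gene has constant expected Ct; each target gene's expected
#' Ct is `base_ct - log2(true fold)`. Gaussian measurement noise is added
#' to every well. The calibrator condition has true fold 1 by construction.
#'
#' @param true_folds data.frame with columns `gene_id`, `condition`,
#'   `fold` (> 0); the calibrator rows must have fold 1.
#' @param calibrator calibrator condition id.
#' @param reference_gene reference gene id (default `"TIP41"`).
#' @param base_ct expected target Ct at fold 1 (default 24).
#' @param ref_ct expected reference Ct (default 20).
#' @param noise_sd Gaussian noise per well in cycles (default 0.15).
#' @param n_bio,n_tech biological/technical replicates (defaults 3 and 3).
#' @param seed mandatory RNG seed.
#' @return list `ct` (table for [ddct()]) and `truth` (the fold table).
#' @export
simulate_ct <- function(true_folds, calibrator, reference_gene = "TIP41",
                        base_ct = 24, ref_ct = 20, noise_sd = 0.15,
                        n_bio = 3L, n_tech = 3L, seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(all(c("gene_id", "condition", "fold") %in% names(true_folds)),
            all(true_folds$fold > 0))
  cal <- true_folds[true_folds$condition == calibrator, ]
  if (any(cal$fold != 1)) stop("calibrator rows must have fold 1")
  set.seed(seed)
  conditions <- unique(true_folds$condition)
  rows <- list()
  grid <- expand.grid(bio_rep = seq_len(n_bio), tech_rep = seq_len(n_tech))
  for (cond in conditions) {
    for (k in seq_len(nrow(grid)))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = reference_gene, condition = cond,
        bio_rep = grid$bio_rep[k], tech_rep = grid$tech_rep[k],
        ct = ref_ct + stats::rnorm(1, 0, noise_sd))
    sub <- true_folds[true_folds$condition == cond, ]
    for (r in seq_len(nrow(sub)))
      for (k in seq_len(nrow(grid)))
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = sub$gene_id[r], condition = cond,
          bio_rep = grid$bio_rep[k], tech_rep = grid$tech_rep[k],
          ct = base_ct - log2(sub$fold[r]) + stats::rnorm(1, 0, noise_sd))
  }
  list(ct = do.call(rbind, rows), truth = true_folds)
}

#' Simulate a tissue expression matrix with planted dominant tissues
#'
#' Baseline abundances are log-normal; each gene's dominant tissue is
#' multiplied by its effect size.
#'
#' @param dominant data.frame with columns `gene_id`, `tissue`, `effect`
#'   (fold increase in the dominant tissue, > 1).
#' @param tissues tissue labels (default the seven labels L, P1, P2, R,
#'   RH, S1, S2).
#' @param base_meanlog,base_sdlog log-normal baseline parameters.
#' @param seed mandatory RNG seed.
#' @return list `mat` (genes x tissues) and `truth` (the dominant table).
#' @export
simulate_tissue_matrix <- function(dominant,
                                   tissues = c("L","P1","P2","R","RH","S1","S2"),
                                   base_meanlog = 3, base_sdlog = 0.3, seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(all(c("gene_id", "tissue", "effect") %in% names(dominant)),
            all(dominant$tissue %in% tissues), all(dominant$effect > 1))
  set.seed(seed)
  mat <- matrix(stats::rlnorm(nrow(dominant) * length(tissues),
                              base_meanlog, base_sdlog),
                nrow = nrow(dominant),
                dimnames = list(dominant$gene_id, tissues))
  for (i in seq_len(nrow(dominant)))
    mat[i, dominant$tissue[i]] <- mat[i, dominant$tissue[i]] * dominant$effect[i]
  list(mat = mat, truth = dominant)
}
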