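# Average (ExPASy-style) residue masses in daltons; free protein adds one
# water (18.0153 Da).
.RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

.WATER_MASS <- 18.0153

# Bjellqvist/ExPASy-style pKa set; overridable via the pka argument of
# isoelectric_point().
.PKA <- c(nterm = 9.69, cterm = 2.34, D = 3.65, E = 4.25, C = 8.3,
          Y = 10.07, H = 6.0, K = 10.53, R = 12.48)

.GENETIC_CODE <- Biostrings::GENETIC_CODE

#' Translate an open reading frame
#'
#' Standard genetic code; a terminal stop codon is dropped. An internal stop
#' or a codon containing an ambiguous base is an error reporting the codon
#' index.
#'
#' @param cds_seq nucleotide string, length divisible by 3.
#' @return amino-acid string.
#' @export
translate_orf <- function(cds_seq) {
  cds_seq <- toupper(gsub("U", "T", cds_seq, fixed = TRUE))
  n <- nchar(cds_seq)
  if (n == 0L || n %% 3L != 0L) stop("CDS length ", n, " not divisible by 3")
  codons <- substring(cds_seq, seq(1L, n, 3L), seq(3L, n, 3L))
  bad <- grep("[^ACGT]", codons)
  if (length(bad)) stop("ambiguous base in codon ", bad[1], " ('", codons[bad[1]], "')")
  aa <- unname(.GENETIC_CODE[codons])
  nc <- length(aa)
  stops <- which(aa == "*")
  if (length(stops) && any(stops < nc))
    stop("internal stop codon at codon index ", stops[stops < nc][1])
  if (length(stops)) aa <- aa[-nc]
  paste(aa, collapse = "")
}

#' Average molecular weight of a protein
#'
#' Sum of average residue masses plus one water (18.0153 Da). The empty
#' string returns the mass of water.
#'
#' @param aa_seq amino-acid string over the standard 20-letter alphabet.
#' @return mass in daltons.
#' @export
molecular_weight <- function(aa_seq) {
  if (nchar(aa_seq) == 0L) return(.WATER_MASS)
  ch <- strsplit(toupper(aa_seq), "")[[1]]
  bad <- which(!(ch %in% names(.RESIDUE_MASS)))
  if (length(bad)) stop("non-standard residue '", ch[bad[1]], "' at position ", bad[1])
  sum(.RESIDUE_MASS[ch]) + .WATER_MASS
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the two termini and the D, E, C, Y, H, K,
#' R side chains.
#'
#' @param aa_seq amino-acid string.
#' @param ph pH value.
#' @param pka named pKa vector (defaults to a Bjellqvist/ExPASy-style set).
#' @return net charge in elementary charge units.
#' @export
net_charge <- function(aa_seq, ph, pka = .PKA) {
  ch <- strsplit(toupper(aa_seq), "")[[1]]
  cnt <- table(factor(ch, levels = names(.RESIDUE_MASS)))
  pos_groups <- c(nterm = 1, K = unname(cnt["K"]), R = unname(cnt["R"]),
                  H = unname(cnt["H"]))
  neg_groups <- c(cterm = 1, D = unname(cnt["D"]), E = unname(cnt["E"]),
                  C = unname(cnt["C"]), Y = unname(cnt["Y"]))
  pos <- sum(pos_groups / (1 + 10^(ph - pka[names(pos_groups)])))
  neg <- sum(neg_groups / (1 + 10^(pka[names(neg_groups)] - ph)))
  pos - neg
}

#' Isoelectric point by bisection
#'
#' Finds the pH in \[0, 14\] where [net_charge()] crosses zero, to
#' `|charge| < 1e-4`.
#'
#' @inheritParams net_charge
#' @return pI in pH units.
#' @export
isoelectric_point <- function(aa_seq, pka = .PKA) {
  ch <- strsplit(toupper(aa_seq), "")[[1]]
  bad <- which(!(ch %in% names(.RESIDUE_MASS)))
  if (length(bad)) stop("non-standard residue '", ch[bad[1]], "' at position ", bad[1])
  lo <- 0; hi <- 14
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    q <- net_charge(aa_seq, mid, pka)
    if (abs(q) < 1e-4) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Build an ungapped log-odds domain profile (PSSM) from a seed alignment
#'
#' Column residue frequencies (gaps ignored) with a pseudocount are turned
#' into log2 odds against the background. Used as a lightweight stand-in
#' for a profile-HMM domain search: the scan surface, not the profile
#' machinery, is what downstream census logic consumes.
#'
#' @param aln named character vector of aligned protein sequences (equal
#'   lengths, `-` for gaps), e.g. from [read_fasta()].
#' @param background named amino-acid frequency vector summing to 1
#'   (default uniform).
#' @param pseudocount added per residue per column.
#' @param score_threshold bit-score threshold for [scan_domain()]; usually
#'   set by [calibrate_profile()].
#' @return object of class `domain_profile` with fields `matrix` (20 x
#'   length log-odds), `length`, `background`, `score_threshold`.
#' @export
build_domain_profile <- function(aln, background = NULL, pseudocount = 0.5,
                                 score_threshold = NA_real_) {
  lens <- nchar(aln)
  if (length(unique(lens)) != 1L) stop("seed alignment rows have unequal lengths")
  aas <- names(.RESIDUE_MASS)
  if (is.null(background)) background <- stats::setNames(rep(1 / 20, 20), aas)
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  m <- do.call(rbind, strsplit(toupper(aln), ""))
  L <- ncol(m)
  pssm <- matrix(NA_real_, nrow = 20, ncol = L, dimnames = list(aas, NULL))
  for (j in seq_len(L)) {
    col <- m[, j]
    col <- col[col %in% aas]
    cnt <- table(factor(col, levels = aas)) + pseudocount
    freq <- cnt / sum(cnt)
    pssm[, j] <- log2(freq / background[aas])
  }
  structure(list(matrix = pssm, length = L, background = background,
                 score_threshold = score_threshold),
            class = "domain_profile")
}

#' Consensus sequence of a domain profile
#' @param profile a `domain_profile`.
#' @return amino-acid string of per-column best residues.
#' @export
profile_consensus <- function(profile) {
  paste(rownames(profile$matrix)[apply(profile$matrix, 2, which.max)],
        collapse = "")
}

#' Calibrate a profile score threshold on a shuffled-sequence null
#'
#' Scores the best window of `n_shuffles` random sequences drawn from the
#' profile background and returns the `1 - fpr` quantile of the null
#' maxima, emulating a stringent E-value cutoff for [scan_domain()].
#'
#' @param profile a `domain_profile`.
#' @param seq_len length of each null sequence.
#' @param n_shuffles number of null draws.
#' @param fpr tolerated per-sequence false positive rate.
#' @param seed RNG seed.
#' @return the profile with `score_threshold` set.
#' @export
calibrate_profile <- function(profile, seq_len = 500L, n_shuffles = 1000L,
                              fpr = 0.001, seed = 1L) {
  set.seed(seed)
  aas <- rownames(profile$matrix)
  maxima <- vapply(seq_len(n_shuffles), function(i) {
    s <- paste(sample(aas, seq_len, replace = TRUE, prob = profile$background[aas]),
               collapse = "")
    h <- scan_domain(s, profile, threshold = -Inf, all_windows = TRUE)
    max(h$score)
  }, numeric(1))
  profile$score_threshold <- unname(stats::quantile(maxima, 1 - fpr, type = 7))
  profile
}

#' Scan a protein with a domain profile
#'
#' Slides the profile over the protein; windows scoring at or above the
#' threshold are reported, reduced to a non-overlapping set by greedy
#' best-score-first selection.
#'
#' @param aa_seq protein string.
#' @param profile a `domain_profile`.
#' @param threshold bit-score cutoff; defaults to the profile's.
#' @param all_windows if `TRUE`, return every window score (no greedy
#'   filtering); used for calibration.
#' @return data.frame with columns `start`, `end` (1-based inclusive
#'   residue coordinates) and `score`.
#' @export
scan_domain <- function(aa_seq, profile, threshold = profile$score_threshold,
                        all_windows = FALSE) {
  if (is.na(threshold)) stop("profile has no score threshold; run calibrate_profile()")
  ch <- strsplit(toupper(aa_seq), "")[[1]]
  L <- profile$length
  n <- length(ch)
  empty <- data.frame(start = integer(), end = integer(), score = numeric())
  if (n < L) return(empty)
  idx <- match(ch, rownames(profile$matrix))
  scores <- vapply(seq_len(n - L + 1L), function(s) {
    rows <- idx[s:(s + L - 1L)]
    if (anyNA(rows)) return(-Inf)
    sum(profile$matrix[cbind(rows, seq_len(L))])
  }, numeric(1))
  hits <- data.frame(start = seq_along(scores), end = seq_along(scores) + L - 1L,
                     score = scores)
  if (all_windows) return(hits)
  hits <- hits[hits$score >= threshold, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  hits <- hits[order(-hits$score, hits$start), , drop = FALSE]
  keep <- logical(nrow(hits))
  occupied <- rep(FALSE, n)
  for (i in seq_len(nrow(hits))) {
    span <- hits$start[i]:hits$end[i]
    if (!any(occupied[span])) {
      keep[i] <- TRUE
      occupied[span] <- TRUE
    }
  }
  out <- hits[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Family census from gene models and coding sequences
#'
#' Translates each CDS, computes protein length, molecular weight,
#' isoelectric point and exon count, optionally filters to domain-positive
#' genes with a profile scan, and summarizes the table.
#'
#' @param models list of `gene_model`s with attached `cds_seq`.
#' @param profile optional `domain_profile`; when given only genes whose
#'   protein has at least one scan hit are kept.
#' @return object of class `census_report`: `rows` data.frame (`gene_id`,
#'   `orf_len`, `aa_len`, `mw`, `pi`, `exon_count`, `domain_hits`) and
#'   `summary` (see [census_summary()]).
#' @export
census <- function(models, profile = NULL) {
  no_cds <- vapply(models, function(m) is.na(m$cds_seq), logical(1))
  if (any(no_cds))
    stop("gene model(s) without CDS: ",
         paste(vapply(models[no_cds], `[[`, "", "gene_id"), collapse = ", "))
  rows <- do.call(rbind, lapply(models, function(m) {
    aa <- translate_orf(m$cds_seq)
    nhit <- if (is.null(profile)) NA_integer_ else nrow(scan_domain(aa, profile))
    data.frame(gene_id = m$gene_id, orf_len = nchar(m$cds_seq),
               aa_len = nchar(aa), mw = round(molecular_weight(aa), 2),
               pi = round(isoelectric_point(aa), 3),
               exon_count = nrow(m$exons), domain_hits = nhit)
  }))
  rownames(rows) <- NULL
  if (!is.null(profile)) rows <- rows[rows$domain_hits > 0L, , drop = FALSE]
  structure(list(rows = rows, summary = census_summary(rows)),
            class = "census_report")
}

#' Summary statistics of a census table
#'
#' Means of ORF and protein length are truncated to integers (reporting
#' convention of the source tables this mirrors); mean molecular weight is
#' rounded to 2 decimals. Min/max carry the gene ids attaining them.
#'
#' @param rows data.frame with columns `gene_id`, `orf_len`, `aa_len`,
#'   `mw`, `pi` and `exon_count`.
#' @return list with per-column `min`/`max`/`mean` (named by attaining
#'   gene), `n_genes`, `intronless_count` and `intronless_fraction`.
#' @export
census_summary <- function(rows) {
  stat <- function(x) list(
    min = stats::setNames(min(x), rows$gene_id[which.min(x)]),
    max = stats::setNames(max(x), rows$gene_id[which.max(x)]),
    mean = mean(x))
  s <- list(orf_len = stat(rows$orf_len), aa_len = stat(rows$aa_len),
            mw = stat(rows$mw), pi = stat(rows$pi))
  s$orf_len$mean <- trunc(s$orf_len$mean)
  s$aa_len$mean <- trunc(s$aa_len$mean)
  s$mw$mean <- round(s$mw$mean, 2)
  s$pi$mean <- round(s$pi$mean, 3)
  s$n_genes <- nrow(rows)
  s$intronless_count <- sum(rows$exon_count == 1L)
  s$intronless_fraction <- round(s$intronless_count / nrow(rows), 4)
  s
}

#' @export
print.census_report <- function(x, ...) {
  cat("Family census:", x$summary$n_genes, "genes\n")
  cat(sprintf("  ORF length (bp): %d-%d, mean %d\n",
              x$summary$orf_len$min, x$summary$orf_len$max, x$summary$orf_len$mean))
  cat(sprintf("  Protein (aa):    %d-%d, mean %d\n",
              x$summary$aa_len$min, x$summary$aa_len$max, x$summary$aa_len$mean))
  cat(sprintf("  MW (Da):         mean %.2f\n", x$summary$mw$mean))
  cat(sprintf("  Intronless:      %d (%.1f%%)\n", x$summary$intronless_count,
              100 * x$summary$intronless_fraction))
  invisible(x)
}
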