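# ---- codon machinery for Nei-Gojobori (1986) counting --------------------

.BASES <- c("A", "C", "G", "T")

.codon_env <- new.env(parent = emptyenv())

# Per-codon synonymous site fraction at each position: among the three
# possible single-nucleotide changes, mutations creating a stop codon are
# excluded from the denominator (NG86 convention), so every position still
# contributes exactly one site split between synonymous and nonsynonymous.
.codon_sites <- function() {
  if (!is.null(.codon_env$sites)) return(.codon_env$sites)
  codons <- apply(expand.grid(.BASES, .BASES, .BASES, stringsAsFactors = FALSE)[, 3:1],
                  1, paste, collapse = "")
  syn <- stats::setNames(numeric(length(codons)), codons)
  for (cod in codons) {
    if (.GENETIC_CODE[cod] == "*") { syn[cod] <- NA_real_; next }
    s <- 0
    for (pos in 1:3) {
      nb <- 0L; ns <- 0L
      for (b in setdiff(.BASES, substr(cod, pos, pos))) {
        mut <- cod
        substr(mut, pos, pos) <- b
        if (.GENETIC_CODE[mut] == "*") next
        nb <- nb + 1L
        if (.GENETIC_CODE[mut] == .GENETIC_CODE[cod]) ns <- ns + 1L
      }
      s <- s + if (nb > 0L) ns / nb else 0
    }
    syn[cod] <- s
  }
  .codon_env$sites <- syn
  syn
}

# Average synonymous/nonsynonymous difference counts between two sense
# codons over all minimal substitution pathways; pathways passing through a
# stop codon are excluded. If every pathway is blocked, all pathways are
# used with steps into/out of stops counted as nonsynonymous.
.codon_path_diffs <- function(cod_a, cod_b) {
  key <- paste0(cod_a, cod_b)
  cached <- .codon_env$paths[[key]]
  if (!is.null(cached)) return(cached)
  pos <- which(strsplit(cod_a, "")[[1]] != strsplit(cod_b, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- switch(k,
                  list(pos),
                  list(pos, rev(pos)),
                  {p <- pos; list(p[c(1,2,3)], p[c(1,3,2)], p[c(2,1,3)],
                                  p[c(2,3,1)], p[c(3,1,2)], p[c(3,2,1)])})
  walk <- function(order, skip_stops) {
    cur <- cod_a
    sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cod_b, p, p)
      aa1 <- .GENETIC_CODE[cur]; aa2 <- .GENETIC_CODE[nxt]
      if (skip_stops && aa2 == "*" && nxt != cod_b) return(NULL)
      if (aa1 == aa2 && aa1 != "*") sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  counts <- Filter(Negate(is.null), lapply(perms, walk, skip_stops = TRUE))
  if (!length(counts)) counts <- lapply(perms, walk, skip_stops = FALSE)
  res <- colMeans(do.call(rbind, counts))
  if (is.null(.codon_env$paths)) .codon_env$paths <- new.env(parent = emptyenv())
  .codon_env$paths[[key]] <- res
  res
}

# ---- codon-aware alignment ------------------------------------------------

#' Codon-aware pairwise alignment of two coding sequences
#'
#' Both CDS are translated ([translate_orf()] rules apply), globally aligned
#' at the protein level (Needleman-Wunsch, BLOSUM62, gap open 10 / extend
#' 1), and each amino-acid column is expanded back to its source codon, so
#' gaps occur only as whole codons and the reading frame is preserved.
#'
#' @param cds_a,cds_b coding sequences (terminal stop allowed and dropped).
#' @param ids optional character vector of two sequence ids.
#' @return object of class `codon_alignment`: `id_a`, `id_b`, `codons_a`,
#'   `codons_b` (character vectors with `"---"` gap codons), `n_codons`.
#' @export
codon_align <- function(cds_a, cds_b, ids = c("a", "b")) {
  aa_a <- translate_orf(cds_a)
  aa_b <- translate_orf(cds_b)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(aa_a), Biostrings::AAString(aa_b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 1)
  ga <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  gb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  thread <- function(gapped_aa, cds) {
    n <- nchar(gsub("-", "", paste(gapped_aa, collapse = "")))
    codons <- substring(toupper(cds), seq(1L, 3L * n, 3L), seq(3L, 3L * n, 3L))
    out <- character(length(gapped_aa))
    k <- 0L
    for (i in seq_along(gapped_aa)) {
      if (gapped_aa[i] == "-") out[i] <- "---"
      else { k <- k + 1L; out[i] <- codons[k] }
    }
    out
  }
  structure(list(id_a = ids[1], id_b = ids[2],
                 codons_a = thread(ga, cds_a), codons_b = thread(gb, cds_b),
                 n_codons = length(ga)),
            class = "codon_alignment")
}

#' Codon alignment from already-aligned coding sequences
#'
#' Pairs codons positionally from two gapped (or gap-free, equal-length)
#' CDS strings — for sequences aligned elsewhere or simulated without
#' indels, where re-alignment is unnecessary.
#'
#' @param aligned_a,aligned_b aligned CDS strings of equal length, gaps as
#'   `-` in whole-codon units.
#' @param ids optional character vector of two sequence ids.
#' @return object of class `codon_alignment`.
#' @export
codon_alignment <- function(aligned_a, aligned_b, ids = c("a", "b")) {
  if (nchar(aligned_a) != nchar(aligned_b))
    stop("aligned sequences must have equal length")
  n <- nchar(aligned_a)
  if (n %% 3L != 0L) stop("aligned length not divisible by 3")
  ca <- substring(toupper(aligned_a), seq(1L, n, 3L), seq(3L, n, 3L))
  cb <- substring(toupper(aligned_b), seq(1L, n, 3L), seq(3L, n, 3L))
  part <- function(x) grepl("-", x) & x != "---"
  if (any(part(ca)) || any(part(cb)))
    stop("gaps must occur as whole codons")
  structure(list(id_a = ids[1], id_b = ids[2], codons_a = ca, codons_b = cb,
                 n_codons = length(ca)),
            class = "codon_alignment")
}

# ---- NG86 estimation ------------------------------------------------------

#' Nei-Gojobori (1986) Ka/Ks estimation with Jukes-Cantor correction
#'
#' Synonymous/nonsynonymous site fractions come from the standard genetic
#' code with stop-creating mutations excluded; observed differences are
#' averaged over all minimal substitution pathways, skipping pathways that
#' pass through stop codons. Proportions `pN = Nd/N` and `pS = Sd/S` are
#' corrected for multiple hits with `d = -3/4 log(1 - 4p/3)`; a proportion
#' at or above 3/4 saturates the corresponding rate.
#'
#' @param aln a `codon_alignment`; gap codons and codons with ambiguous
#'   bases are dropped pairwise.
#' @param lambda synonymous substitution rate per site per year used for
#'   the dating field.
#' @return object of class `kaks_result`: `ka`, `ks`, `ratio`, `t_my`,
#'   `selection_class`, `n_sites`, `s_sites`, `nd`, `sd`, `n_codons_used`,
#'   `saturated` (logical `c(ka, ks)`).
#' @export
kaks_ng86 <- function(aln, lambda = 6.5e-9) {
  stopifnot(inherits(aln, "codon_alignment"))
  ok <- aln$codons_a != "---" & aln$codons_b != "---" &
    !grepl("[^ACGT]", aln$codons_a) & !grepl("[^ACGT]", aln$codons_b)
  if (!any(ok)) stop("no ungapped codon columns in alignment")
  ca <- aln$codons_a[ok]
  cb <- aln$codons_b[ok]
  sites <- .codon_sites()
  s_a <- sum(sites[ca]); s_b <- sum(sites[cb])
  S <- (s_a + s_b) / 2
  N <- 3 * length(ca) - S
  diffs <- mapply(function(x, y) .codon_path_diffs(x, y), ca, cb)
  Sd <- sum(diffs["sd", ])
  Nd <- sum(diffs["nd", ])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 0.75) return(NA_real_)  # saturated
    d <- -0.75 * log(1 - 4 * p / 3)
    if (d == 0) 0 else d
  }
  ks <- jc(pS); ka <- jc(pN)
  saturated <- c(ka = !is.na(pN) && pN >= 0.75, ks = !is.na(pS) && pS >= 0.75)
  ratio <- if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_
  structure(list(ka = ka, ks = ks, ratio = ratio,
                 t_my = if (!is.na(ks)) divergence_time(ks, lambda) else NA_real_,
                 selection_class = classify_selection(ratio),
                 n_sites = N, s_sites = S, nd = Nd, sd = Sd,
                 n_codons_used = length(ca), saturated = saturated),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("Ka = %.5f  Ks = %.5f  Ka/Ks = %s  T = %s My  [%s]\n",
              x$ka, x$ks,
              if (is.na(x$ratio)) "NA" else sprintf("%.4f", x$ratio),
              if (is.na(x$t_my)) "NA" else sprintf("%.2f", x$t_my),
              x$selection_class))
  invisible(x)
}

#' Duplication/divergence date from a synonymous rate
#'
#' `T = Ks / (2 * lambda)` years, returned in million years. Linear in Ks;
#' reports conventionally round to 2 decimals.
#'
#' @param ks synonymous substitutions per synonymous site (finite, >= 0).
#' @param lambda synonymous substitution rate per site per year
#'   (default 6.5e-9).
#' @return time in million years (unrounded).
#' @export
divergence_time <- function(ks, lambda = 6.5e-9) {
  if (any(is.na(ks)) || any(ks < 0)) stop("Ks must be finite and non-negative")
  ks / (2 * lambda) / 1e6
}

#' Classify a Ka/Ks ratio into a selection regime
#'
#' @param ratio Ka/Ks value (may be `NA` for saturated/undefined pairs).
#' @return `"positive"` (ratio > 1), `"purifying"` (< 1), `"neutral"`
#'   (equal to 1 within 1e-9) or `"undefined"`.
#' @export
classify_selection <- function(ratio) {
  vapply(ratio, function(r) {
    if (is.na(r)) return("undefined")
    if (abs(r - 1) < 1e-9) return("neutral")
    if (r > 1) "positive" else "purifying"
  }, character(1))
}

#' Sliding-window Ka/Ks track along a codon alignment
#'
#' Windows of `window_bp` advanced by `step_bp` over the alignment's
#' ungapped codon columns, snapped to codon boundaries (both defaults are
#' divisible by 3). Each window is estimated with [kaks_ng86()]; windows
#' with a saturated proportion, no synonymous sites, or `Ks = 0` yield an
#' undefined ratio.
#'
#' @param aln a `codon_alignment`.
#' @param window_bp window size in base pairs (default 150).
#' @param step_bp step size in base pairs (default 9).
#' @return data.frame `window_start_bp`, `window_end_bp` (0-based half-open
#'   over the ungapped alignment), `ka`, `ks`, `ratio`.
#' @export
sliding_window_kaks <- function(aln, window_bp = 150L, step_bp = 9L) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (window_bp %% 3L != 0L || step_bp %% 3L != 0L)
    stop("window and step sizes must be codon multiples")
  ok <- which(aln$codons_a != "---" & aln$codons_b != "---" &
                !grepl("[^ACGT]", aln$codons_a) & !grepl("[^ACGT]", aln$codons_b))
  n_bp <- 3L * length(ok)
  wc <- window_bp %/% 3L
  sc <- step_bp %/% 3L
  if (n_bp < window_bp) {
    warning("alignment shorter than one window; returning a single whole-alignment window")
    starts <- 1L
    wc <- length(ok)
  } else {
    starts <- seq(1L, length(ok) - wc + 1L, by = sc)
  }
  rows <- lapply(starts, function(s) {
    idx <- ok[s:(s + wc - 1L)]
    sub <- structure(list(id_a = aln$id_a, id_b = aln$id_b,
                          codons_a = aln$codons_a[idx],
                          codons_b = aln$codons_b[idx],
                          n_codons = length(idx)),
                     class = "codon_alignment")
    kk <- kaks_ng86(sub)
    ratio <- if (is.na(kk$ka) || is.na(kk$ks) || kk$s_sites == 0 || kk$ks == 0)
      NA_real_ else kk$ka / kk$ks
    data.frame(window_start_bp = (s - 1L) * 3L,
               window_end_bp = (s - 1L) * 3L + 3L * wc,
               ka = kk$ka, ks = kk$ks, ratio = ratio)
  })
  do.call(rbind, rows)
}

#' Group Ks values into duplication-age bands
#'
#' Sorted Ks values are split at their `n_groups - 1` largest gaps
#' (equivalent to cutting a single-linkage tree at `n_groups` clusters).
#' Groups are numbered 1..k by decreasing mean Ks (1 = oldest band).
#'
#' @param ks numeric vector of Ks values.
#' @param n_groups number of bands (default 3).
#' @return integer group id per input element.
#' @export
group_ks <- function(ks, n_groups = 3L) {
  n <- length(ks)
  if (n_groups >= n) return(rank(-ks, ties.method = "first"))
  o <- order(ks)
  gaps <- diff(ks[o])
  cuts <- sort(order(gaps, decreasing = TRUE)[seq_len(n_groups - 1L)])
  band <- cumsum(c(1L, as.integer(seq_len(n - 1L) %in% cuts)))
  grp <- integer(n)
  grp[o] <- band
  means <- tapply(ks, grp, mean)
  relabel <- rank(-means, ties.method = "first")
  as.integer(relabel[as.character(grp)])
}

#' Selection and duplication-dating report for homolog pairs
#'
#' Per pair: Ka, Ks, their ratio (4 decimals), the dated duplication event
#' (2 decimals, `T = Ks/2*lambda`), the selection regime, and a Ks age band
#' from [group_ks()]. Group summaries give mean Ks and mean T per band;
#' counts report positive-selection pairs and pairs younger than a
#' species-divergence threshold.
#'
#' @param pairs data.frame with columns `pair_id`, `ka`, `ks` (e.g. raw
#'   estimates or published values).
#' @param lambda synonymous substitution rate per site per year.
#' @param n_groups number of Ks bands.
#' @param recent_my species-divergence threshold in My (default 12).
#' @return object of class `selection_report`: `rows`, `groups`,
#'   `n_positive`, `n_recent`.
#' @export
selection_report <- function(pairs, lambda = 6.5e-9, n_groups = 3L,
                             recent_my = 12) {
  stopifnot(all(c("pair_id", "ka", "ks") %in% names(pairs)), nrow(pairs) >= 1L)
  t_my <- divergence_time(pairs$ks, lambda)
  ratio <- pairs$ka / pairs$ks
  rows <- data.frame(pair_id = pairs$pair_id, ka = pairs$ka, ks = pairs$ks,
                     ratio = round(ratio, 4), t_my = round(t_my, 2),
                     selection_class = classify_selection(ratio),
                     group = group_ks(pairs$ks, n_groups))
  groups <- do.call(rbind, lapply(sort(unique(rows$group)), function(g) {
    sel <- rows$group == g
    data.frame(group = g, n_pairs = sum(sel),
               mean_ks = round(mean(pairs$ks[sel]), 2),
               mean_t_my = round(mean(t_my[sel]), 2))
  }))
  structure(list(rows = rows, groups = groups,
                 n_positive = sum(ratio > 1, na.rm = TRUE),
                 n_recent = sum(t_my < recent_my, na.rm = TRUE),
                 recent_my = recent_my),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Selection/dating report:", nrow(x$rows), "pairs\n")
  print(x$rows, row.names = FALSE)
  cat("\nKs age bands:\n")
  print(x$groups, row.names = FALSE)
  cat(sprintf("\nPositive selection (Ka/Ks > 1): %d pairs; dated < %g My: %d pairs\n",
              x$n_positive, x$recent_my, x$n_recent))
  invisible(x)
}
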