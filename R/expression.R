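#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged first; within each biological
#' replicate and condition, `dCt = Ct(target) - Ct(reference)`, then
#' `ddCt = dCt(condition) - dCt(calibrator)` paired within the biological
#' replicate, and `fold = 2^-ddCt`. Per-condition mean and standard error
#' are taken across biological replicates only, so the calibrator condition
#' is exactly 1 for every gene with zero standard error.
#'
#' @param ct data.frame with columns `gene_id`, `condition`, `bio_rep`,
#'   `tech_rep`, `ct` (cycles, > 0).
#' @param reference_gene internal-control gene id (must be measured in
#'   every condition and biological replicate).
#' @param calibrator calibrator condition id (fold set to 1).
#' @return data.frame `gene_id`, `condition`, `fold_change`, `se`,
#'   `n_bio_reps`.
#' @export
ddct <- function(ct, reference_gene, calibrator) {
  need <- c("gene_id", "condition", "bio_rep", "tech_rep", "ct")
  if (!all(need %in% names(ct)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  if (!reference_gene %in% ct$gene_id)
    stop("reference gene ", reference_gene, " absent from Ct table")
  if (!calibrator %in% ct$condition)
    stop("calibrator condition ", calibrator, " absent from Ct table")
  # average technical replicates
  m <- stats::aggregate(ct ~ gene_id + condition + bio_rep, ct, mean)
  ref <- m[m$gene_id == reference_gene, c("condition", "bio_rep", "ct")]
  names(ref)[3] <- "ref_ct"
  targets <- setdiff(unique(m$gene_id), reference_gene)
  out <- list()
  for (g in targets) {
    tg <- merge(m[m$gene_id == g, ], ref, by = c("condition", "bio_rep"))
    conds <- unique(m$condition[m$gene_id == g])
    missing_ref <- setdiff(conds, ref$condition)
    if (length(missing_ref))
      stop("reference gene missing in condition(s): ",
           paste(missing_ref, collapse = ", "), " for gene ", g)
    tg$dct <- tg$ct - tg$ref_ct
    cal <- tg[tg$condition == calibrator, c("bio_rep", "dct")]
    if (!nrow(cal)) stop("calibrator condition missing for gene ", g)
    names(cal)[2] <- "dct_cal"
    tg <- merge(tg, cal, by = "bio_rep")
    tg$fold <- 2^(-(tg$dct - tg$dct_cal))
    for (cond in unique(tg$condition)) {
      f <- tg$fold[tg$condition == cond]
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g, condition = cond, fold_change = mean(f),
        se = if (length(f) > 1L) stats::sd(f) / sqrt(length(f)) else 0,
        n_bio_reps = length(f))
    }
  }
  res <- do.call(rbind, out)
  res[order(res$gene_id, res$condition), ]
}

#' Normalize a tissue expression matrix and order genes by clustering
#'
#' Values are `log(x + pseudo)` transformed (base `log_base`) and each gene
#' row is z-scored; constant rows become zero rows and are flagged rather
#' than producing NaN. Genes are ordered by average-linkage hierarchical
#' clustering on Euclidean row distances (heatmap-ready ordering).
#'
#' @param mat numeric matrix, genes x tissues, finite non-negative.
#' @param log_base logarithm base (default 2).
#' @param pseudo pseudo-count added before the log (default 1).
#' @return list with `z` (normalized matrix, rows reordered), `order`
#'   (gene ids in display order), `constant` (flagged gene ids), `hclust`.
#' @export
tissue_profile <- function(mat, log_base = 2, pseudo = 1) {
  if (any(!is.finite(mat)) || any(mat < 0)) stop("matrix must be finite and non-negative")
  if (is.null(rownames(mat))) stop("matrix rows must be named by gene")
  lg <- log(mat + pseudo, base = log_base)
  sds <- apply(lg, 1, stats::sd)
  constant <- rownames(mat)[sds == 0]
  z <- lg
  for (i in seq_len(nrow(lg)))
    z[i, ] <- if (sds[i] == 0) 0 else (lg[i, ] - mean(lg[i, ])) / sds[i]
  hc <- stats::hclust(stats::dist(z, method = "euclidean"), method = "average")
  ord <- rownames(z)[hc$order]
  list(z = z[ord, , drop = FALSE], order = ord, constant = constant, hclust = hc)
}

#' Tissue-specificity index (tau) and top tissue per gene
#'
#' Computed on log-transformed values:
#' `tau = sum(1 - x_i / max(x)) / (n - 1)`; 0 means uniform expression, 1
#' expression in a single tissue. The top tissue is the argmax, ties broken
#' by column order and flagged.
#'
#' @param mat numeric matrix, genes x tissues (>= 2 tissues), non-negative.
#' @param log_base,pseudo transform parameters as in [tissue_profile()].
#' @return data.frame `gene_id`, `tau` (`NA` for all-zero genes, flagged in
#'   `status`), `top_tissue`, `tied`.
#' @export
tissue_specificity <- function(mat, log_base = 2, pseudo = 1) {
  if (ncol(mat) < 2L) stop("need at least 2 tissues")
  if (is.null(colnames(mat))) stop("matrix columns must be named by tissue")
  lg <- log(mat + pseudo, base = log_base)
  rows <- lapply(seq_len(nrow(mat)), function(i) {
    x <- lg[i, ]
    if (all(mat[i, ] == 0))
      return(data.frame(gene_id = rownames(mat)[i], tau = NA_real_,
                        top_tissue = NA_character_, tied = FALSE,
                        status = "all-zero"))
    tau <- sum(1 - x / max(x)) / (length(x) - 1)
    top <- which(x == max(x))
    data.frame(gene_id = rownames(mat)[i], tau = tau,
               top_tissue = colnames(mat)[top[1]], tied = length(top) > 1L,
               status = "ok")
  })
  do.call(rbind, rows)
}
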