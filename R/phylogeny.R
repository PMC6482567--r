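#' Poisson-corrected protein distance matrix
#'
#' For each sequence pair, the proportion of differing residues `p` over
#' shared non-gap columns (pairwise deletion) is corrected as
#' `d = -log(1 - p)`. Saturated pairs (`p >= 1 - exp(-cap)`) are capped at
#' `cap` and flagged. Set `correction = "p"` for raw p-distances.
#'
#' @param msa named character vector of aligned protein sequences (equal
#'   lengths, `-` gaps).
#' @param correction `"poisson"` (default) or `"p"`.
#' @param cap distance cap for saturated pairs (default 20).
#' @return symmetric numeric matrix with zero diagonal; attribute
#'   `saturated` is a logical matrix marking capped entries.
#' @export
protein_distance <- function(msa, correction = c("poisson", "p"), cap = 20) {
  correction <- match.arg(correction)
  lens <- nchar(msa)
  if (length(unique(lens)) != 1L) stop("MSA rows have unequal lengths")
  m <- do.call(rbind, strsplit(toupper(msa), ""))
  rownames(m) <- names(msa)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  sat <- matrix(FALSE, n, n, dimnames = dimnames(D))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(shared))
      stop("no shared non-gap columns between ", names(msa)[i], " and ", names(msa)[j])
    p <- mean(m[i, shared] != m[j, shared])
    if (correction == "p") d <- p
    else if (p >= 1 - exp(-cap)) { d <- cap; sat[i, j] <- sat[j, i] <- TRUE }
    else d <- -log(1 - p)
    D[i, j] <- D[j, i] <- d
  }
  attr(D, "saturated") <- sat
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via [ape::nj]); negative branch lengths are
#' clamped to zero.
#'
#' @param D symmetric distance matrix with labels (>= 3 taxa).
#' @return unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("need at least 3 taxa")
  if (is.null(rownames(D))) stop("distance matrix must be labelled")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  tr <- ape::nj(D)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

.msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(toupper(msa), ""))
  rownames(m) <- names(msa)
  m
}

.tree_from_matrix <- function(m, correction = "poisson") {
  msa <- stats::setNames(apply(m, 1, paste, collapse = ""), rownames(m))
  neighbor_joining(protein_distance(msa, correction))
}

#' Neighbor-joining tree with bootstrap support
#'
#' Alignment columns are resampled with replacement `n_reps` times; the
#' support of each internal edge of the point-estimate tree is the
#' percentage of replicate trees containing the same bipartition.
#'
#' @param msa named character vector of aligned protein sequences.
#' @param n_reps number of bootstrap replicates (analysis convention 1000;
#'   smaller values keep test runs fast).
#' @param seed RNG seed (mandatory: resampling must be reproducible).
#' @param correction distance model passed to [protein_distance()].
#' @return [ape::phylo] tree whose `node.label` holds integer support
#'   percentages for internal nodes (`NA` on the root).
#' @export
bootstrap_support <- function(msa, n_reps = 100L, seed, correction = "poisson") {
  if (missing(seed)) stop("a seed is required for bootstrap resampling")
  stopifnot(n_reps >= 1L)
  m <- .msa_matrix(msa)
  phy <- .tree_from_matrix(m, correction)
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    reps[[b]] <- .tree_from_matrix(m[, cols, drop = FALSE], correction)
  }
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(phy, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  phy$node.label <- as.character(round(100 * counts / n_reps))
  phy$node.label[1] <- ""  # root of the unrooted representation: no bipartition
  phy
}

#' Assign family members to subfamilies from anchored reference leaves
#'
#' Each unlabeled leaf takes the subfamily of the smallest clade that
#' contains it together with at least one anchor, provided all anchors in
#' that clade belong to one subfamily; mixed-anchor clades leave the gene
#' unassigned with a diagnostic. Unrooted trees are midpoint-rooted first.
#'
#' @param tree [ape::phylo] tree containing both query and anchor leaves.
#' @param anchors data.frame with columns `leaf_id`, `subfamily`; at least
#'   one anchor per subfamily present in the tree.
#' @return data.frame `gene_id`, `subfamily` (`NA` when unassigned),
#'   `status` (`"assigned"`, `"anchor"` or a conflict diagnostic).
#' @export
assign_subfamilies <- function(tree, anchors) {
  stopifnot(all(c("leaf_id", "subfamily") %in% names(anchors)))
  missing_anchors <- setdiff(anchors$leaf_id, tree$tip.label)
  if (length(missing_anchors))
    stop("anchor leaves not in tree: ", paste(missing_anchors, collapse = ", "))
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  ntip <- length(tree$tip.label)
  anchor_sub <- stats::setNames(anchors$subfamily, anchors$leaf_id)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  tips_below <- phangorn::Descendants(tree, (ntip + 1L):(ntip + tree$Nnode), "tips")
  rows <- lapply(seq_len(ntip), function(i) {
    id <- tree$tip.label[i]
    if (id %in% names(anchor_sub))
      return(data.frame(gene_id = id, subfamily = unname(anchor_sub[id]),
                        status = "anchor"))
    node <- parent[i]
    while (node != 0L) {
      tips <- tree$tip.label[tips_below[[node - ntip]]]
      hit <- intersect(tips, names(anchor_sub))
      if (length(hit)) {
        subs <- unique(unname(anchor_sub[hit]))
        if (length(subs) == 1L)
          return(data.frame(gene_id = id, subfamily = subs, status = "assigned"))
        return(data.frame(gene_id = id, subfamily = NA_character_,
                          status = paste0("conflict: smallest anchored clade mixes ",
                                          paste(sort(subs), collapse = "/"))))
      }
      node <- parent[node]
    }
    data.frame(gene_id = id, subfamily = NA_character_, status = "no anchored clade")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-species composition of each subfamily
#'
#' @param assignment data.frame from [assign_subfamilies()].
#' @param species named character vector mapping `gene_id` to a species
#'   tag.
#' @return data.frame `subfamily`, `species`, `n`, `percent`; percentages
#'   within each subfamily sum to 100 (up to rounding).
#' @export
subfamily_percentages <- function(assignment, species) {
  keep <- !is.na(assignment$subfamily)
  df <- assignment[keep, , drop = FALSE]
  df$species <- unname(species[df$gene_id])
  if (anyNA(df$species))
    stop("species tag missing for: ",
         paste(df$gene_id[is.na(df$species)], collapse = ", "))
  tab <- as.data.frame(table(subfamily = df$subfamily, species = df$species),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  totals <- tapply(tab$n, tab$subfamily, sum)
  tab$percent <- round(100 * tab$n / totals[tab$subfamily], 2)
  tab[order(tab$subfamily, tab$species), ]
}
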