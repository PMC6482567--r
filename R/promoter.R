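#' Load a cis-element dictionary
#'
#' TSV with columns `element`, `iupac`, `category`, `subcategory`. The
#' packaged default covers hormone-, stress-, development- and
#' light-responsive elements commonly reported by plant promoter scans;
#' consensus strings are editable stand-ins, not proprietary matrices.
#'
#' @param path TSV path; default the packaged dictionary.
#' @return data.frame dictionary, validated (unique names, IUPAC alphabet,
#'   every entry categorized).
#' @export
read_element_dictionary <- function(path = system.file("extdata", "cis_elements.tsv",
                                                       package = "famevol")) {
  dict <- utils::read.table(path, sep = "\t", header = TRUE,
                            comment.char = "#", stringsAsFactors = FALSE)
  need <- c("element", "iupac", "category", "subcategory")
  if (!all(need %in% names(dict)))
    stop("dictionary must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(dict$element)) stop("duplicate element names in dictionary")
  bad <- grepl("[^ACGTNRYSWKMBDHV]", toupper(dict$iupac))
  if (any(bad)) stop("non-IUPAC consensus for: ", paste(dict$element[bad], collapse = ", "))
  if (any(!nzchar(dict$category))) stop("uncategorized dictionary entries")
  dict$iupac <- toupper(dict$iupac)
  dict
}

#' Write a cis-element dictionary
#' @param dict dictionary data.frame.
#' @param path output TSV path.
#' @export
write_element_dictionary <- function(dict, path) write_report(dict, path)

#' Extract promoter windows upstream of gene models
#'
#' Takes `window` bp immediately upstream of the translation start on the
#' coding strand: for `+` genes the slice ends at the first exon start, for
#' `-` genes it begins at the last exon end and is reverse-complemented.
#' Genes too close to a contig edge yield truncated promoters and a
#' warning; the `truncated` attribute flags them.
#'
#' @param models list of `gene_model`s.
#' @param genome named character vector of contig sequences.
#' @param window promoter length in bp (default 2000).
#' @return named character vector of promoter sequences (5'->3' relative to
#'   the gene) with logical attribute `truncated`.
#' @export
extract_promoters <- function(models, genome, window = 2000L) {
  out <- character(length(models))
  trunc_flag <- logical(length(models))
  ids <- vapply(models, `[[`, "", "gene_id")
  for (k in seq_along(models)) {
    m <- models[[k]]
    contig <- genome[[m$chrom]]
    if (is.null(contig) || is.na(contig)) stop("contig not found: ", m$chrom)
    clen <- nchar(contig)
    if (m$strand == "+") {
      tss <- min(m$exons[, 1])  # 0-based
      from <- max(0L, tss - window)
      seq <- substr(contig, from + 1L, tss)
    } else {
      tss <- max(m$exons[, 2])
      to <- min(clen, tss + window)
      seq <- revcomp(substr(contig, tss + 1L, to))
    }
    if (nchar(seq) < window) {
      trunc_flag[k] <- TRUE
      warning("promoter of ", m$gene_id, " truncated to ", nchar(seq), " bp")
    }
    out[k] <- seq
  }
  names(out) <- ids
  names(trunc_flag) <- ids
  attr(out, "truncated") <- trunc_flag
  out
}

# All exact matches of an IUPAC consensus on one strand of a plain-ACGT
# subject; returns 0-based starts.
.iupac_matches <- function(consensus, subject) {
  if (nchar(subject) < nchar(consensus)) return(integer())
  hits <- Biostrings::matchPattern(Biostrings::DNAString(consensus),
                                   Biostrings::DNAString(subject),
                                   fixed = c(pattern = FALSE, subject = TRUE))
  Biostrings::start(hits) - 1L
}

#' Scan promoters for cis-acting elements
#'
#' Every exact IUPAC-consensus match on both strands is reported; matches
#' of distinct elements may overlap. A palindromic consensus matching the
#' same coordinates on both strands is counted once (forward strand kept).
#'
#' @param promoters named character vector of promoter sequences.
#' @param dict element dictionary (see [read_element_dictionary()]).
#' @return data.frame `gene_id`, `element`, `category`, `subcategory`,
#'   `start`, `end` (0-based half-open on the promoter), `strand`.
#' @export
scan_elements <- function(promoters, dict = read_element_dictionary()) {
  if (!length(promoters)) stop("no promoters to scan")
  rows <- list()
  for (g in names(promoters)) {
    subject <- toupper(promoters[[g]])
    for (r in seq_len(nrow(dict))) {
      cons <- dict$iupac[r]
      w <- nchar(cons)
      fwd <- .iupac_matches(cons, subject)
      rev <- .iupac_matches(revcomp(cons), subject)
      rev <- setdiff(rev, fwd[revcomp(cons) == cons])  # palindrome dedupe
      if (length(fwd) || length(rev))
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g, element = dict$element[r], category = dict$category[r],
          subcategory = dict$subcategory[r],
          start = c(fwd, rev), end = c(fwd, rev) + w,
          strand = rep(c("+", "-"), c(length(fwd), length(rev))))
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(), element = character(),
                      category = character(), subcategory = character(),
                      start = integer(), end = integer(), strand = character()))
  out <- do.call(rbind, rows)
  out[order(out$gene_id, out$start, out$element, out$strand), ]
}

#' Aggregate cis-element hits into counts and category shares
#'
#' @param hits data.frame from [scan_elements()] (may be empty).
#' @param dict dictionary, used to list zero-count elements.
#' @return list with `elements` (per-element counts and percentage share of
#'   the element's category, 2 decimals), `subcategories` (share of each
#'   subcategory within its category) and `categories` (total counts).
#' @export
summarize_elements <- function(hits, dict = read_element_dictionary()) {
  counts <- table(factor(hits$element, levels = dict$element))
  el <- data.frame(element = dict$element, category = dict$category,
                   subcategory = dict$subcategory, count = as.integer(counts))
  cat_tot <- tapply(el$count, el$category, sum)
  el$pct_of_category <- ifelse(cat_tot[el$category] > 0,
                               round(100 * el$count / cat_tot[el$category], 2), 0)
  sub <- stats::aggregate(count ~ category + subcategory, el, sum)
  sub$pct_of_category <- ifelse(cat_tot[sub$category] > 0,
                                round(100 * sub$count / cat_tot[sub$category], 2), 0)
  cats <- data.frame(category = names(cat_tot), count = as.integer(cat_tot))
  list(elements = el[order(el$category, -el$count), ],
       subcategories = sub[order(sub$category, -sub$count), ],
       categories = cats[order(cats$category), ])
}
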