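# Allowed residue characters per alphabet (after case folding and U->T).
.ALPHABETS <- list(
  dna = strsplit("ACGTNRYSWKMBDHV", "")[[1]],
  aa  = strsplit("ACDEFGHIKLMNPQRSTVWYX*", "")[[1]]
)

#' Read a FASTA file into a sequence set
#'
#' Sequences are upper-cased on read; for nucleotide sets `U` is mapped to
#' `T` so RNA input is stored in DNA space. Record order is preserved.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"dna"` or `"aa"`; characters outside the declared
#'   alphabet (IUPAC codes allowed for DNA, the 20 residues plus `X`/`*`
#'   for protein) raise an error naming the offending position.
#' @return named character vector of sequences with attribute `alphabet`.
#' @export
read_fasta <- function(path, alphabet = c("dna", "aa")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  if (alphabet == "dna") seqs <- gsub("U", "T", seqs, fixed = TRUE)
  names(seqs) <- ids
  .check_alphabet(seqs, alphabet)
  if (any(!nzchar(seqs))) stop("empty sequence for id(s): ",
                               paste(ids[!nzchar(seqs)], collapse = ", "))
  sequence_set(seqs, alphabet)
}

#' Construct a sequence set from a named character vector
#'
#' @param seqs named character vector, unique non-empty names.
#' @param alphabet `"dna"` or `"aa"`.
#' @return the validated vector with attribute `alphabet`.
#' @export
sequence_set <- function(seqs, alphabet = c("dna", "aa")) {
  alphabet <- match.arg(alphabet)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids")
  if (any(!nzchar(seqs))) stop("empty sequences are not allowed")
  .check_alphabet(seqs, alphabet)
  attr(seqs, "alphabet") <- alphabet
  seqs
}

.check_alphabet <- function(seqs, alphabet) {
  allowed <- .ALPHABETS[[alphabet]]
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "")[[1]]
    bad <- which(!(ch %in% c(allowed, "-")))
    if (length(bad))
      stop("illegal ", alphabet, " character '", ch[bad[1]], "' at position ",
           bad[1], " in sequence '", names(seqs)[i], "'")
  }
  invisible(TRUE)
}

#' Write a sequence set to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width in characters.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read gene models from a GFF-lite exon table
#'
#' The on-disk table is TSV with columns `gene_id, chrom, strand,
#' exon_start, exon_end`, one row per exon, coordinates 1-based inclusive.
#' Internally all coordinates are 0-based half-open; exons are sorted
#' 5'->3' on the coding strand and checked for overlap.
#'
#' @param path TSV path (lines starting with `#` ignored).
#' @param cds optional named character vector of CDS sequences; when given,
#'   each gene's summed exon length must equal its CDS length and the CDS
#'   length must be divisible by 3.
#' @return list of `gene_model` objects (fields `gene_id`, `chrom`,
#'   `strand`, `exons` 0-based half-open matrix, `cds_seq` or `NA`).
#' @export
read_gene_models <- function(path, cds = NULL) {
  if (!file.exists(path)) stop("gene model table not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "exon_start", "exon_end")
  if (!all(need %in% names(tab)))
    stop("gene model table must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(tab, tab$gene_id), function(g) {
    gene_model(gene_id = g$gene_id[1], chrom = g$chrom[1], strand = g$strand[1],
               exons = cbind(g$exon_start - 1L, g$exon_end),
               cds_seq = if (!is.null(cds)) unname(cds[g$gene_id[1]]) else NA_character_)
  })
  out[order(names(out))]
}

#' Construct and validate a gene model
#'
#' @param gene_id,chrom,strand scalar identifiers; strand `"+"` or `"-"`.
#' @param exons two-column matrix of 0-based half-open exon intervals in
#'   genomic coordinates (any row order; sorted internally).
#' @param cds_seq coding sequence or `NA`; when given its length must equal
#'   the summed exon length and be divisible by 3.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds_seq = NA_character_) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-' for ", gene_id)
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 2] <= exons[, 1]))
    stop("empty or inverted exon in gene ", gene_id)
  if (nrow(exons) > 1L && any(exons[-1L, 1] < exons[-nrow(exons), 2]))
    stop("overlapping exons in gene ", gene_id)
  # 5'->3' on the coding strand: genomic order for +, reversed for -
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  if (!is.na(cds_seq)) {
    if (sum(exons[, 2] - exons[, 1]) != nchar(cds_seq))
      stop("exon lengths do not sum to CDS length for gene ", gene_id)
    if (nchar(cds_seq) %% 3L != 0L)
      stop("CDS length not divisible by 3 for gene ", gene_id)
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, cds_seq = cds_seq),
            class = "gene_model")
}

#' Number of introns of a gene model
#' @param model a `gene_model`.
#' @return integer, `nrow(exons) - 1`.
#' @export
intron_count <- function(model) nrow(model$exons) - 1L

#' Write gene models back to the GFF-lite exon table format
#' @param models list of `gene_model`s.
#' @param path output TSV path (1-based inclusive coordinates on disk).
#' @export
write_gene_models <- function(models, path) {
  rows <- do.call(rbind, lapply(models, function(m) {
    ex <- m$exons[order(m$exons[, 1]), , drop = FALSE]
    data.frame(gene_id = m$gene_id, chrom = m$chrom, strand = m$strand,
               exon_start = ex[, 1] + 1L, exon_end = ex[, 2])
  }))
  write_report(rows, path)
}

#' Convert disk (1-based inclusive) to internal (0-based half-open) intervals
#' @param start,end integer vectors of 1-based inclusive coordinates.
#' @return two-column matrix of 0-based half-open intervals.
#' @export
coords_to_internal <- function(start, end) cbind(start = start - 1L, end = end)

#' Convert internal (0-based half-open) to disk (1-based inclusive) intervals
#' @param start,end integer vectors of 0-based half-open coordinates.
#' @return two-column matrix of 1-based inclusive intervals.
#' @export
coords_to_disk <- function(start, end) cbind(start = start + 1L, end = end)

#' Write a phylogenetic tree to Newick
#'
#' Integer bootstrap supports stored in `tree$node.label` are serialized as
#' internal-node labels. Leaf labels containing Newick metacharacters are
#' rejected.
#'
#' @param tree an [ape::phylo] object.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  bad <- grepl("[](),:;[]|\\s", tree$tip.label)
  if (any(bad))
    stop("tip label(s) contain Newick metacharacters: ",
         paste(tree$tip.label[bad], collapse = ", "))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths cannot be serialized")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Newick file path.
#' @return an [ape::phylo] object (node labels kept as bootstrap supports).
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write a TSV report with a schema header comment
#'
#' All pipeline reports share this format: a `# columns:` comment line, a
#' header row, then tab-separated values. [read_report()] round-trips it.
#'
#' @param df data.frame to serialize.
#' @param path output path.
#' @export
write_report <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# columns: ", paste(names(df), collapse = ", ")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV report written by [write_report()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_report <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Reverse complement of DNA strings
#' @param x character vector of DNA sequences (IUPAC codes allowed).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
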