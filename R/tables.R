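#' Packaged family census table (35 trihelix genes of Moso bamboo)
#'
#' Printed per-gene census values: ORF length, protein length, molecular
#' weight, isoelectric point and exon count, usable as input to
#' [census_summary()]. One molecular weight (PeTTF17) is retained exactly
#' as printed in the source despite being physically inconsistent with its
#' protein length.
#'
#' @return data.frame with columns `gene_id`, `locus_id`, `chrom`, `start`,
#'   `end`, `orf_len`, `aa_len`, `mw`, `pi`, `exon_count`.
#' @export
pettf_census_table <- function() {
  read_report(system.file("extdata", "pettf_table1.tsv", package = "famevol"))
}

#' Packaged Ka/Ks and duplication-dating table (12 paralog pairs)
#'
#' Printed Ka, Ks, Ka/Ks and dated duplication (My) per duplicated gene
#' pair; the `ka`/`ks` columns feed [selection_report()], the `ratio` and
#' `t_my` columns are the published reference values.
#'
#' @return data.frame with columns `pair_id`, `ka`, `ks`, `ratio`, `t_my`.
#' @export
pettf_kaks_table <- function() {
  read_report(system.file("extdata", "pettf_table3.tsv", package = "famevol"))
}

#' Packaged homolog pair list (12 paralog + 15 ortholog pairs)
#'
#' @return data.frame with columns `id_a`, `id_b`, `relation`.
#' @export
pettf_homolog_pairs <- function() {
  read_report(system.file("extdata", "pettf_pairs.tsv", package = "famevol"))
}
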