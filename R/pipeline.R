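#' Default pipeline configuration
#'
#' Thresholds default to the analysis conventions used throughout the
#' package: paralogy requires > 300 aligned bp and >= 40% identity,
#' orthology reciprocal best hits with > 300 aligned bp; sliding windows
#' are 150 bp advanced by 9 bp; dating uses lambda = 6.5e-9 synonymous
#' substitutions per site per year; bootstrap default 1000 replicates; a
#' duplication is "recent" below 12 My.
#'
#' @param seed RNG seed used by every stochastic stage.
#' @param outdir output directory.
#' @return nested config list (`inputs`, `thresholds`, `seed`, `outdir`).
#' @export
default_run_config <- function(seed = 1L, outdir = tempfile("famevol_run_")) {
  list(
    inputs = list(cds = NULL, models = NULL, profile_seed = NULL, msa = NULL,
                  anchors = NULL, promoters = NULL,
                  elements = system.file("extdata", "cis_elements.tsv",
                                         package = "famevol"),
                  ct = NULL, reference_gene = "TIP41", calibrator = "0h"),
    thresholds = list(aligned_bp = 300L, identity = 0.40, evalue = 1e-5,
                      window_bp = 150L, step_bp = 9L, lambda = 6.5e-9,
                      bootstrap = 1000L, species_divergence_my = 12),
    profile = list(n_shuffles = 200L, fpr = 1e-3),
    seed = seed,
    outdir = outdir)
}

.write_stage <- function(writer, path) {
  partial <- paste0(path, ".partial")
  writer(partial)
  file.rename(partial, path)
  path
}

#' Run the full family-evolution pipeline
#'
#' Orchestrates census, paralog detection, Ka/Ks estimation with dating and
#' sliding windows, NJ tree with bootstrap and subfamily assignment,
#' promoter element scanning, and qPCR quantification from one config.
#' Missing input files abort before any computation; a failing stage aborts
#' with the stage name and leaves its `.partial` output for inspection.
#'
#' @param config list from [default_run_config()] with `inputs` paths set.
#'   Stages whose inputs are `NULL` are skipped.
#' @return named character vector of output paths (invisibly), plus a
#'   `run_manifest.tsv` recording thresholds, seed and input checksums.
#' @export
run_pipeline <- function(config) {
  inp <- config$inputs
  th <- config$thresholds
  paths <- unlist(inp[vapply(inp, is.character, logical(1))])
  paths <- paths[!names(paths) %in% c("reference_gene", "calibrator")]
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ",
         paste(sprintf("%s (%s)", missing, names(missing)), collapse = ", "))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  op <- function(f) file.path(config$outdir, f)

  if (!is.null(inp$cds) && !is.null(inp$models)) {
    out["census"] <- stage("census", {
      cds <- read_fasta(inp$cds, "dna")
      models <- read_gene_models(inp$models, cds = cds)
      profile <- NULL
      if (!is.null(inp$profile_seed)) {
        seedaln <- read_fasta(inp$profile_seed, "aa")
        profile <- calibrate_profile(build_domain_profile(seedaln),
                                     n_shuffles = config$profile$n_shuffles,
                                     fpr = config$profile$fpr,
                                     seed = config$seed)
      }
      cen <- census(models, profile)
      .write_stage(function(p) {
        write_report(cen$rows, p)
        con <- file(p, "a")
        s <- cen$summary
        writeLines(c(
          sprintf("# summary: n_genes=%d", s$n_genes),
          sprintf("# summary: orf_len min=%d max=%d mean=%d",
                  s$orf_len$min, s$orf_len$max, s$orf_len$mean),
          sprintf("# summary: aa_len min=%d max=%d mean=%d",
                  s$aa_len$min, s$aa_len$max, s$aa_len$mean),
          sprintf("# summary: mw mean=%.2f", s$mw$mean),
          sprintf("# summary: intronless n=%d fraction=%.4f",
                  s$intronless_count, s$intronless_fraction)), con)
        close(con)
      }, op("census.tsv"))
    })
  }

  pairs <- NULL
  if (!is.null(inp$cds)) {
    pairs <- stage("homologs", {
      cds <- read_fasta(inp$cds, "dna")
      pp <- find_paralogs(cds, min_aligned = th$aligned_bp,
                          min_identity = th$identity)
      .write_stage(function(p) write_report(pp, p), op("pairs.tsv"))
      pp
    })
    out["pairs"] <- op("pairs.tsv")
    if (!is.null(pairs) && nrow(pairs) > 0L) {
      out["kaks"] <- stage("kaks", {
        cds <- read_fasta(inp$cds, "dna")
        res <- lapply(seq_len(nrow(pairs)), function(i) {
          aln <- codon_align(cds[[pairs$id_a[i]]], cds[[pairs$id_b[i]]],
                             ids = c(pairs$id_a[i], pairs$id_b[i]))
          list(aln = aln, kk = kaks_ng86(aln, lambda = th$lambda))
        })
        est <- data.frame(
          pair_id = paste(pairs$id_a, pairs$id_b, sep = "-"),
          ka = vapply(res, function(r) r$kk$ka, numeric(1)),
          ks = vapply(res, function(r) r$kk$ks, numeric(1)))
        rep <- selection_report(est, lambda = th$lambda,
                                recent_my = th$species_divergence_my)
        .write_stage(function(p) write_report(rep$rows, p), op("table3.tsv"))
        win <- do.call(rbind, lapply(seq_along(res), function(i) {
          w <- sliding_window_kaks(res[[i]]$aln, th$window_bp, th$step_bp)
          cbind(pair_id = est$pair_id[i], w)
        }))
        .write_stage(function(p) write_report(win, p), op("windows.tsv"))
        op("table3.tsv")
      })
      out["windows"] <- op("windows.tsv")
    }
  }

  if (!is.null(inp$msa)) {
    out["tree"] <- stage("tree", {
      msa <- read_fasta(inp$msa, "aa")
      tree <- bootstrap_support(msa, n_reps = th$bootstrap, seed = config$seed)
      .write_stage(function(p) write_newick(tree, p), op("tree.nwk"))
      if (!is.null(inp$anchors)) {
        anchors <- read_report(inp$anchors)
        assign <- assign_subfamilies(tree, anchors)
        .write_stage(function(p) write_report(assign, p), op("subfamilies.tsv"))
      }
      op("tree.nwk")
    })
  }

  if (!is.null(inp$promoters)) {
    out["cis_hits"] <- stage("cis", {
      prom <- read_fasta(inp$promoters, "dna")
      dict <- read_element_dictionary(inp$elements)
      hits <- scan_elements(prom, dict)
      .write_stage(function(p) write_report(hits, p), op("cis_hits.tsv"))
      summ <- summarize_elements(hits, dict)
      .write_stage(function(p) write_report(summ$elements, p), op("cis_summary.tsv"))
      op("cis_hits.tsv")
    })
    out["cis_summary"] <- op("cis_summary.tsv")
  }

  if (!is.null(inp$ct)) {
    out["folds"] <- stage("qpcr", {
      ct <- read_report(inp$ct)
      folds <- ddct(ct, inp$reference_gene, inp$calibrator)
      .write_stage(function(p) write_report(folds, p), op("folds.tsv"))
    })
  }

  out["manifest"] <- stage("manifest", {
    cfg_dump <- file.path(config$outdir, "config_dump.txt")
    writeLines(utils::capture.output(utils::str(config)), cfg_dump)
    manifest <- data.frame(
      key = c(paste0("threshold.", names(th)), "seed", "config_md5",
              paste0("input_md5.", names(paths))),
      value = c(vapply(th, format, character(1)), format(config$seed),
                unname(tools::md5sum(cfg_dump)),
                unname(tools::md5sum(paths))))
    .write_stage(function(p) write_report(manifest, p), op("run_manifest.tsv"))
  })
  invisible(out)
}

.encode_aa <- function(aa) {
  code <- Biostrings::GENETIC_CODE
  paste(vapply(strsplit(aa, "")[[1]],
               function(a) names(code)[code == a][1], character(1)),
        collapse = "")
}

#' Write a complete synthetic input bundle for the pipeline
#'
#' Generates, under one seed: a duplicated gene family carrying the
#' packaged synthetic domain (CDS FASTA + exon table), a protein MSA with
#' subfamily anchors, promoters with planted elements, and a qPCR Ct table
#' — every file the pipeline consumes, with known ground truth.
#'
#' @param dir output directory.
#' @param seed RNG seed.
#' @return named list of file paths plus the `truth` records.
#' @export
write_demo_inputs <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed_aln_path <- system.file("extdata", "trihelix_domain_seed_synthetic.fa",
                               package = "famevol")
  seed_aln <- read_fasta(seed_aln_path, "aa")
  consensus <- profile_consensus(build_domain_profile(seed_aln))
  pairs <- data.frame(pair_id = c("g1", "g2", "g3"),
                      ks = c(0.15, 0.4, 0.7), omega = c(0.2, 0.2, 0.3))
  fam <- simulate_family(pairs, codon_length = 150L, seed = seed)
  # splice the domain consensus (as codons) after the start codon
  dom <- .encode_aa(consensus)
  seqs <- vapply(fam$seqs, function(s)
    paste0(substr(s, 1, 3), dom, substr(s, 4 + nchar(dom), nchar(s))),
    character(1))
  cds_path <- file.path(dir, "cds.fa")
  write_fasta(seqs, cds_path)
  models <- data.frame(gene_id = names(seqs), chrom = paste0("ctg_", names(seqs)),
                       strand = "+", exon_start = 2001L,
                       exon_end = 2000L + nchar(seqs))
  models_path <- file.path(dir, "genes.tsv")
  write_report(models, models_path)
  aa <- vapply(seqs, translate_orf, character(1))
  msa_path <- file.path(dir, "msa.fa")
  write_fasta(aa, msa_path)
  anchors <- data.frame(leaf_id = paste0(pairs$pair_id, "a"),
                        subfamily = c("GT-1", "GT-2", "SIP1"))
  anchors_path <- file.path(dir, "anchors.tsv")
  write_report(anchors, anchors_path)
  plants <- data.frame(gene_id = rep(names(seqs), each = 2),
                       element = rep(c("CGTCA-motif", "MBS"), length(seqs)),
                       count = rep(c(3L, 2L), length(seqs)))
  prom <- simulate_promoters(plants, seed = seed + 1L)
  prom_path <- file.path(dir, "promoters.fa")
  write_fasta(prom$promoters, prom_path)
  folds <- expand.grid(gene_id = paste0(pairs$pair_id, "a"),
                       condition = c("0h", "1h", "6h"),
                       stringsAsFactors = FALSE)
  folds$fold <- ifelse(folds$condition == "0h", 1,
                       ifelse(folds$condition == "1h", 4, 0.5))
  ct <- simulate_ct(folds, calibrator = "0h", seed = seed + 2L)
  ct_path <- file.path(dir, "ct.tsv")
  write_report(ct$ct, ct_path)
  list(cds = cds_path, models = models_path, profile_seed = seed_aln_path,
       msa = msa_path, anchors = anchors_path, promoters = prom_path,
       ct = ct_path,
       truth = list(family = fam$truth, promoters = prom$truth,
                    folds = ct$truth))
}
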