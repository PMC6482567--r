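test_that("ORF translation follows the standard code and drops terminal stops", {
  expect_equal(translate_orf("ATGTAA"), "M")
  expect_equal(translate_orf("atggga"), "MG")
  expect_error(translate_orf("ATGTAAGGG"), "internal stop.*codon index 2")
  expect_error(translate_orf("ATGNNN"), "ambiguous.*codon 2")
  expect_error(translate_orf("ATGC"), "not divisible by 3")
  # stop-terminated ORF: protein length is ORF/3 - 1 (the 477 bp -> 158 aa
  # and 1935 bp -> 644 aa arithmetic of the census table)
  set.seed(2)
  orf <- paste0(random_cds(158), "TGA")
  expect_equal(nchar(orf), 477)
  expect_equal(nchar(translate_orf(orf)), 158)
  orf2 <- paste0(random_cds(644), "TAA")
  expect_equal(nchar(orf2), 1935)
  expect_equal(nchar(translate_orf(orf2)), 644)
})

test_that("molecular weight is an average-mass residue sum plus one water", {
  expect_equal(round(molecular_weight(""), 2), 18.02)
  expect_equal(round(molecular_weight("G"), 2), 75.07)
  expect_error(molecular_weight("GZ"), "non-standard residue 'Z' at position 2")
  # independent table-sum oracle on random 50-mers
  masses <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
              C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
              H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
              M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
              T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
  set.seed(31)
  for (i in 1:5) {
    aa <- sample(names(masses), 50, replace = TRUE)
    expect_equal(molecular_weight(paste(aa, collapse = "")),
                 sum(masses[aa]) + 18.0153)
  }
})

test_that("molecular weight is additive up to one water", {
  set.seed(8)
  aas <- names(famevol:::.RESIDUE_MASS)
  a <- paste(sample(aas, 20, TRUE), collapse = "")
  b <- paste(sample(aas, 35, TRUE), collapse = "")
  expect_equal(molecular_weight(paste0(a, b)),
               molecular_weight(a) + molecular_weight(b) - 18.0153)
})

test_that("isoelectric point solves the zero-charge equation", {
  # poly-glycine has only the two termini; with one positive group at pKa
  # 9.69 and one negative at 2.34 the zero crossing is their midpoint
  expect_equal(isoelectric_point("GGGGGG"), (9.69 + 2.34) / 2, tolerance = 1e-3)
  expect_gt(isoelectric_point("K"), 7)
  expect_lt(isoelectric_point("D"), 7)
  # self-consistency and composition-only invariance
  set.seed(12)
  for (i in 1:10) {
    aa <- sample(names(famevol:::.RESIDUE_MASS), 40, replace = TRUE)
    pi1 <- isoelectric_point(paste(aa, collapse = ""))
    expect_lt(abs(net_charge(paste(aa, collapse = ""), pi1)), 1e-4)
    pi2 <- isoelectric_point(paste(sample(aa), collapse = ""))
    expect_equal(pi1, pi2, tolerance = 1e-6)
  }
})

seed_aln <- read_fasta(system.file("extdata", "trihelix_domain_seed_synthetic.fa",
                                   package = "famevol"), "aa")
profile <- calibrate_profile(build_domain_profile(seed_aln),
                             seq_len = 300L, n_shuffles = 300L, seed = 5)

test_that("profile scan finds the consensus and rejects shuffled sequences", {
  cons <- profile_consensus(profile)
  hit <- scan_domain(cons, profile)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 1L)
  expect_equal(hit$end, profile$length)
  # planted consensus inside random flanks: start recovered exactly
  set.seed(9)
  aas <- rownames(profile$matrix)
  for (i in 1:5) {
    left <- paste(sample(aas, 80, TRUE), collapse = "")
    right <- paste(sample(aas, 60, TRUE), collapse = "")
    h <- scan_domain(paste0(left, cons, right), profile)
    expect_true(81 %in% h$start)
  }
  # shuffled-sequence null at the calibrated threshold: essentially no hits
  set.seed(10)
  n_hits <- sum(vapply(1:50, function(i) {
    nrow(scan_domain(paste(sample(aas, 300, TRUE), collapse = ""), profile))
  }, numeric(1)))
  expect_lte(n_hits, 1)
})

test_that("census reports rows for domain-positive genes with exact summaries", {
  cons <- profile_consensus(profile)
  set.seed(14)
  enc <- famevol:::.encode_aa
  mk <- function(id, n_extra) {
    cds <- paste0("ATG", enc(cons), random_cds(n_extra))
    gene_model(id, "c1", "+", cbind(0L, nchar(cds)), cds_seq = cds)
  }
  models <- list(mk("gA", 60), mk("gB", 100))
  rep2 <- census(models, profile)
  expect_equal(rep2$rows$gene_id, c("gA", "gB"))
  expect_equal(rep2$rows$aa_len, rep2$rows$orf_len / 3)
  # summary equals an independent pass over the rows
  expect_equal(rep2$summary$mw$mean, round(mean(rep2$rows$mw), 2))
  expect_equal(rep2$summary$orf_len$mean, trunc(mean(rep2$rows$orf_len)))
  expect_equal(rep2$summary$intronless_count, 2L)
  # single-gene census: summary equals that gene's row
  rep1 <- census(models[1], profile)
  expect_equal(unname(rep1$summary$mw$min), rep1$rows$mw[1])
  expect_equal(rep1$summary$orf_len$mean, rep1$rows$orf_len[1])
  # adding a domain-negative gene never changes the report
  neg <- gene_model("gNeg", "c1", "+", cbind(0L, 300L),
                    cds_seq = random_cds(100))
  rep3 <- census(c(models, list(neg)), profile)
  expect_equal(rep3$rows, rep2$rows)
  expect_equal(rep3$summary, rep2$summary)
})

test_that("census summary reproduces independently recomputed statistics", {
  tab <- pettf_census_table()
  s <- census_summary(tab)
  expect_equal(s$mw$mean, round(mean(tab$mw), 2))
  expect_equal(s$orf_len$mean, trunc(mean(tab$orf_len)))
  expect_equal(names(s$orf_len$min), tab$gene_id[which.min(tab$orf_len)])
  expect_equal(names(s$orf_len$max), tab$gene_id[which.max(tab$orf_len)])
  expect_equal(s$intronless_count, sum(tab$exon_count == 1))
})
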