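test_that("codon alignment threads protein gaps back onto whole codons", {
  set.seed(51)
  cds <- random_cds(60)
  aln <- codon_align(cds, cds)
  expect_false(any(aln$codons_a == "---" | aln$codons_b == "---"))
  expect_equal(paste(aln$codons_a, collapse = ""), cds)

  # deleting one internal codon yields exactly one gap codon, frame intact
  del <- paste0(substr(cds, 1, 90), substr(cds, 94, nchar(cds)))
  aln2 <- codon_align(cds, del)
  expect_equal(sum(aln2$codons_b == "---"), 1L)
  expect_equal(sum(aln2$codons_a == "---"), 0L)
  expect_equal(paste(aln2$codons_b[aln2$codons_b != "---"], collapse = ""), del)
})

test_that("NG86 handles identical and single-difference toy pairs", {
  set.seed(52)
  cds <- random_cds(50)
  kk <- kaks_ng86(codon_align(cds, cds))
  expect_equal(kk$ka, 0)
  expect_equal(kk$ks, 0)
  expect_equal(kk$n_sites + kk$s_sites, 3 * kk$n_codons_used)

  # GGG <-> GGA third position is synonymous on every pathway
  kk2 <- kaks_ng86(codon_align("GGGAAA", "GGAAAA"))
  expect_equal(kk2$sd, 1)
  expect_equal(kk2$nd, 0)
  expect_equal(kk2$ka, 0)
})

test_that("NG86 counts equal the brute-force pathway-enumeration oracle", {
  set.seed(53)
  for (rep in 1:10) {
    fam <- simulate_family(data.frame(pair_id = "p", ks = stats::runif(1, 0.05, 0.9),
                                      omega = stats::runif(1, 0.1, 1.5)),
                           codon_length = 80L, seed = 530 + rep)
    aln <- codon_alignment(fam$seqs[["pa"]], fam$seqs[["pb"]])
    kk <- kaks_ng86(aln)
    oc <- oracle_ng86_counts(fam$seqs[["pa"]], fam$seqs[["pb"]])
    expect_equal(kk$s_sites, oc$S, tolerance = 1e-12)
    expect_equal(kk$n_sites, oc$N, tolerance = 1e-12)
    expect_equal(kk$sd, oc$Sd, tolerance = 1e-12)
    expect_equal(kk$nd, oc$Nd, tolerance = 1e-12)
  }
})

test_that("NG86 is symmetric in its two sequences", {
  fam <- simulate_family(data.frame(pair_id = "p", ks = 0.4, omega = 0.3),
                         codon_length = 120L, seed = 54)
  k1 <- kaks_ng86(codon_align(fam$seqs[["pa"]], fam$seqs[["pb"]]))
  k2 <- kaks_ng86(codon_align(fam$seqs[["pb"]], fam$seqs[["pa"]]))
  expect_equal(k1$ka, k2$ka)
  expect_equal(k1$ks, k2$ks)
  expect_equal(k1$s_sites, k2$s_sites)
})

test_that("simulated divergence is recovered within stated tolerances", {
  rel_err_ks <- numeric(0)
  rel_err_w <- numeric(0)
  for (rep in 1:20) {
    fam <- simulate_family(data.frame(pair_id = "p", ks = 0.3, omega = 0.2),
                           codon_length = 500L, seed = 550 + rep)
    kk <- kaks_ng86(codon_align(fam$seqs[["pa"]], fam$seqs[["pb"]]))
    tr <- fam$truth
    rel_err_ks <- c(rel_err_ks, abs(kk$ks - tr$ks_true) / tr$ks_true)
    w_true <- tr$ka_true / tr$ks_true
    rel_err_w <- c(rel_err_w, abs(kk$ratio - w_true) / w_true)
  }
  expect_lt(mean(rel_err_ks), 0.15)
  expect_lt(mean(rel_err_w), 0.2)
})

test_that("divergence dating is linear and reproduces printed dates", {
  expect_equal(round(divergence_time(0.28456), 2), 21.89)
  expect_equal(round(divergence_time(1.33589), 2), 102.76)
  expect_equal(divergence_time(0), 0)
  set.seed(56)
  ks <- stats::runif(10, 0, 2)
  expect_equal(divergence_time(2 * ks), 2 * divergence_time(ks))
  expect_error(divergence_time(-0.1), "non-negative")
})

test_that("selection classes follow the ratio boundaries", {
  expect_equal(classify_selection(1.5346), "positive")
  expect_equal(classify_selection(0.2271), "purifying")
  expect_equal(classify_selection(1.0), "neutral")
  expect_equal(classify_selection(NA_real_), "undefined")
})

test_that("sliding windows count, localize, and bracket the global estimate", {
  fam <- simulate_family(data.frame(pair_id = "p", ks = 0.35, omega = 0.25),
                         codon_length = 200L, seed = 57)
  aln <- codon_align(fam$seqs[["pa"]], fam$seqs[["pb"]])
  win <- sliding_window_kaks(aln)
  aligned_bp <- 3 * sum(aln$codons_a != "---" & aln$codons_b != "---")
  expect_equal(nrow(win), floor((aligned_bp - 150) / 9) + 1)
  expect_equal(unique(diff(win$window_start_bp)), 9)

  # uniform divergence: the global ratio lies within the window range
  kk <- kaks_ng86(aln)
  defined <- win$ratio[!is.na(win$ratio)]
  expect_gte(kk$ratio, min(defined) - 1e-12)
  expect_lte(kk$ratio, max(defined) + 1e-12)

  # an engineered high-omega block pulls the track maximum into the block
  set.seed(58)
  anc1 <- random_cds(80); anc2 <- random_cds(60); anc3 <- random_cds(80)
  low1 <- evolve_cds(anc1, 0.3, 0.05)$seq
  hot <- evolve_cds(anc2, 0.3, 5)$seq
  low2 <- evolve_cds(anc3, 0.3, 0.05)$seq
  aln2 <- codon_align(paste0(anc1, anc2, anc3), paste0(low1, hot, low2))
  win2 <- sliding_window_kaks(aln2)
  peak <- win2[which.max(win2$ratio), ]
  expect_gte(peak$window_end_bp, 240)   # block spans bp 240-420
  expect_lte(peak$window_start_bp, 420)

  # short alignments degrade to a single whole-alignment window
  short <- codon_align(random_cds(30), random_cds(30))
  expect_warning(w1 <- sliding_window_kaks(short), "shorter than one window")
  expect_equal(nrow(w1), 1L)
})

test_that("Ks banding and the dating report reproduce the published grouping", {
  t3 <- pettf_kaks_table()
  grp <- group_ks(t3$ks)
  expect_equal(sort(as.vector(table(grp))), c(2L, 3L, 7L))
  # oldest band holds the two most diverged pairs
  expect_setequal(t3$pair_id[grp == 1], c("PeTTF7-16", "PeTTF19-25"))
  expect_setequal(t3$pair_id[grp == 2],
                  c("PeTTF3-23", "PeTTF15-26", "PeTTF33-35"))
  rep <- selection_report(t3)
  expect_equal(rep$groups$mean_t_my[rep$groups$group == 2], 48.12)
  expect_equal(rep$groups$mean_t_my[rep$groups$group == 3], 16.28)
  expect_equal(rep$n_positive, 4L)
  expect_equal(rep$n_recent, 3L)
})
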