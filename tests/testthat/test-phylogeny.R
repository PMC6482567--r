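aa_alphabet <- names(famevol:::.RESIDUE_MASS)
random_protein <- function(n) paste(sample(aa_alphabet, n, TRUE), collapse = "")

test_that("Poisson distances follow the closed form and flag saturation", {
  set.seed(61)
  a <- random_protein(100)
  msa <- c(s1 = a, s2 = a)
  expect_equal(unname(protein_distance(msa)["s1", "s2"]), 0)

  b <- mutate_protein(a, 10)  # p = 0.1 (mutate_protein never resamples a site)
  d <- protein_distance(c(s1 = a, s2 = b))["s1", "s2"]
  expect_equal(unname(d), -log(0.9), tolerance = 1e-3)

  # a pair with no identical residues saturates and is capped
  x <- strrep("A", 50); y <- strrep("W", 50)
  D <- protein_distance(c(s1 = x, s2 = y), cap = 20)
  expect_equal(unname(D["s1", "s2"]), 20)
  expect_true(attr(D, "saturated")["s1", "s2"])

  # pairwise deletion: gap columns are excluded per pair
  Dp <- protein_distance(c(s1 = "AAAA", s2 = "AA--"), correction = "p")
  expect_equal(unname(Dp["s1", "s2"]), 0)
})

test_that("three-taxon NJ solves the three-point formulas exactly", {
  D <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["A"]), (5 + 9 - 10) / 2)
  expect_equal(unname(bl["B"]), (5 + 10 - 9) / 2)
  expect_equal(unname(bl["C"]), (9 + 10 - 5) / 2)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
  Dbad <- D; Dbad[1, 2] <- 7
  expect_error(neighbor_joining(Dbad), "symmetric")
})

test_that("NJ recovers additive tree metrics exactly", {
  set.seed(62)
  for (rep in 1:50) {
    gen <- random_additive_matrix(sample(4:12, 1))
    tr <- neighbor_joining(gen$D)
    expect_equal(ape::dist.topo(tr, gen$tree), 0, ignore_attr = TRUE)
    # branch lengths are recovered too: path distances match the input
    expect_equal(ape::cophenetic.phylo(tr)[rownames(gen$D), colnames(gen$D)],
                 gen$D, tolerance = 1e-8)
  }
})

test_that("NJ output is invariant under label permutation of the matrix", {
  set.seed(63)
  gen <- random_additive_matrix(8)
  tr1 <- neighbor_joining(gen$D)
  perm <- sample(rownames(gen$D))
  tr2 <- neighbor_joining(gen$D[perm, perm])
  expect_equal(ape::dist.topo(tr1, tr2), 0, ignore_attr = TRUE)
  expect_equal(sum(tr1$edge.length), sum(tr2$edge.length), tolerance = 1e-8)
})

test_that("a zero-distance pair joins as a cherry", {
  set.seed(64)
  gen <- random_additive_matrix(6)
  D <- gen$D
  dup <- D["t1", , drop = TRUE]
  D <- rbind(cbind(D, t1_copy = dup), t1_copy = c(dup, 0))
  D["t1", "t1_copy"] <- D["t1_copy", "t1"] <- 0
  tr <- neighbor_joining(D)
  # t1 and its copy must be sisters
  mrca <- ape::getMRCA(tr, c("t1", "t1_copy"))
  tips <- ape::extract.clade(tr, mrca)$tip.label
  expect_setequal(tips, c("t1", "t1_copy"))
})

test_that("bootstrap supports separate simulated clades and ignore leaf order", {
  # two clades of diverged proteins: the inter-clade split is near-certain
  set.seed(65)
  anc1 <- random_protein(200)
  anc2 <- mutate_protein(anc1, 120)
  msa <- c(
    stats::setNames(vapply(1:4, function(i) mutate_protein(anc1, 8), ""),
                    paste0("a", 1:4)),
    stats::setNames(vapply(1:4, function(i) mutate_protein(anc2, 8), ""),
                    paste0("b", 1:4)))
  clade_support <- function(tr, tips) {
    sup <- suppressWarnings(as.numeric(tr$node.label))
    pp <- ape::prop.part(tr)
    sets <- lapply(pp, function(idx) sort(tr$tip.label[idx]))
    all_tips <- sort(tr$tip.label)
    target <- sort(tips)
    comp <- setdiff(all_tips, target)
    idx <- which(vapply(sets, function(s)
      identical(s, target) || identical(s, comp), logical(1)))
    sup[idx]
  }
  tr <- bootstrap_support(msa, n_reps = 100, seed = 66)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup >= 0 & sup <= 100, na.rm = TRUE))
  # the a-clade bipartition carries high support
  s_a <- clade_support(tr, paste0("a", 1:4))
  expect_gte(max(s_a, na.rm = TRUE), 95)

  tr2 <- bootstrap_support(msa[sample(names(msa))], n_reps = 100, seed = 66)
  expect_equal(max(clade_support(tr2, paste0("a", 1:4)), na.rm = TRUE),
               max(s_a, na.rm = TRUE))
})

test_that("anchored clades assign subfamilies and expose conflicts", {
  # five clean clades, three anchors and four queries each
  set.seed(67)
  subfams <- c("GT-1", "GT-2", "GT-gamma", "SIP1", "SH4")
  msa <- character(0)
  anchors <- list()
  truth <- list()
  base <- random_protein(240)
  for (k in seq_along(subfams)) {
    anc <- mutate_protein(base, 110)
    ids <- paste0("clade", k, "_", 1:7)
    for (id in ids) msa[id] <- mutate_protein(anc, 6)
    anchors[[k]] <- data.frame(leaf_id = ids[1:3], subfamily = subfams[k])
    truth[[k]] <- data.frame(gene_id = ids[4:7], subfamily = subfams[k])
  }
  anchors <- do.call(rbind, anchors)
  truth <- do.call(rbind, truth)
  tree <- neighbor_joining(protein_distance(msa))
  res <- assign_subfamilies(tree, anchors)
  got <- res[match(truth$gene_id, res$gene_id), ]
  expect_equal(got$subfamily, truth$subfamily)
  expect_true(all(got$status == "assigned"))

  # a query whose smallest anchored clade mixes two subfamilies is left
  # unassigned with a diagnostic
  tr <- ape::read.tree(text = "((q:1,(s1:1,s2:1):1):1,(o1:1,o2:1):1);")
  mixed <- data.frame(leaf_id = c("s1", "s2", "o1"),
                      subfamily = c("SIP1", "SH4", "GT-1"))
  res2 <- assign_subfamilies(tr, mixed)
  q <- res2[res2$gene_id == "q", ]
  expect_true(is.na(q$subfamily))
  expect_match(q$status, "conflict.*SH4/SIP1")

  # a leaf sister to a single anchor takes that anchor's subfamily
  single <- assign_subfamilies(tr, data.frame(leaf_id = c("s1", "o1"),
                                              subfamily = c("GT-gamma", "SH4")))
  expect_equal(single$subfamily[single$gene_id == "s2"], "GT-gamma")

  expect_error(assign_subfamilies(tr, data.frame(leaf_id = "nope",
                                                 subfamily = "GT-1")),
               "not in tree")
})

test_that("subfamily percentages sum to 100 within each subfamily", {
  assignment <- data.frame(
    gene_id = c("p1", "p2", "o1", "a1", "p3", "o2"),
    subfamily = c("GT-1", "GT-1", "GT-1", "SIP1", "SIP1", "SIP1"),
    status = "assigned")
  species <- c(p1 = "Pe", p2 = "Pe", p3 = "Pe", o1 = "Os", o2 = "Os", a1 = "At")
  pct <- subfamily_percentages(assignment, species)
  sums <- tapply(pct$percent, pct$subfamily, sum)
  expect_true(all(abs(sums - 100) <= 0.5))
  expect_equal(pct$percent[pct$subfamily == "GT-1" & pct$species == "Pe"], 66.67)
})
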