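test_that("three-taxon NJ solves the three-point system exactly", {
  D <- matrix(c(0, 0.3, 0.4,
                0.3, 0, 0.5,
                0.4, 0.5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  P <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(P, D, tolerance = 1e-9)
})

test_that("NJ recovers additive matrices exactly (topology and lengths)", {
  set.seed(5)
  for (trial in 1:10) {
    true <- ape::rtree(sample(4:8, 1))
    true$edge.length <- true$edge.length / 4
    D <- ape::cophenetic.phylo(true)
    D <- D[sort(rownames(D)), sort(rownames(D))]
    tr <- neighbor_joining(D)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
                 tolerance = 1e-9)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(true)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("our NJ agrees with ape::nj on random noisy matrices", {
  set.seed(6)
  for (trial in 1:10) {
    n <- sample(5:10, 1)
    M <- matrix(runif(n * n, 0.05, 0.4), n, n)
    D <- (M + t(M)) / 2; diag(D) <- 0
    dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
    expect_equal(ape::dist.topo(ape::unroot(neighbor_joining(D)),
                                ape::unroot(ape::nj(D))), 0,
                 ignore_attr = TRUE)
  }
})

test_that("NJ refuses matrices with NaN entries", {
  D <- matrix(c(0, NaN, 0.1, NaN, 0, 0.1, 0.1, 0.1, 0), 3, 3)
  dimnames(D) <- list(letters[1:3], letters[1:3])
  expect_error(neighbor_joining(D), "re-estimate")
})

test_that("NJ on the printed study matrix reproduces the text's groupings", {
  D <- dendrobium_table3()
  tr <- neighbor_joining(D)
  expect_true(are_sisters(tr, "Dendrobium_williamsonii", "Dendrobium_cariniferum"))
  expect_true(are_sisters(tr, "Dendrobium_jenkinsii", "Dendrobium_lindleyi"))
  expect_true(are_sisters(tr, "Dendrobium_thyrsiflorum", "Dendrobium_densiflorum"))
  rooted <- root_on_outgroup(tr, "Pholidota_yunnanensis")
  kids <- ape::prop.part(rooted)
  labs <- rooted$tip.label
  clades <- lapply(kids, function(k) sort(labs[k]))
  expect_true(list(sort(setdiff(labs, "Pholidota_yunnanensis"))) %in% clades)
})

test_that("Fitch scoring matches forced small cases and phangorn", {
  inv <- its_alignment(matrix("A", 4, 6,
                              dimnames = list(paste0("t", 1:4), NULL)))
  tr <- read_newick("((t1,t2),(t3,t4));")
  expect_equal(fitch_score(tr, inv), 0L)
  one <- its_alignment(matrix(c("A", "A", "G", "G"), 4, 1,
                              dimnames = list(paste0("t", 1:4), NULL)))
  expect_equal(fitch_score(tr, one), 1L)
  ## against phangorn on random alignments and trees
  set.seed(8)
  for (trial in 1:10) {
    n <- sample(4:9, 1)
    m <- matrix(sample(c("A", "C", "G", "T"), n * 40, TRUE), n, 40,
                dimnames = list(paste0("t", 1:n), NULL))
    aln <- its_alignment(m)
    tr <- ape::rtree(n, tip.label = paste0("t", 1:n))
    expect_equal(fitch_score(tr, aln),
                 as.integer(phangorn::fitch(tr, phangorn::phyDat(m, type = "DNA"))))
  }
})

test_that("gaps are missing data for parsimony", {
  m <- rbind(t1 = c("A", "-"), t2 = c("A", "-"), t3 = c("G", "A"),
             t4 = c("G", "G"))
  tr <- read_newick("((t1,t2),(t3,t4));")
  expect_equal(fitch_score(tr, its_alignment(m)), 2L)  # 1 + 1 (A vs G below)
})

test_that("MP search attains the exhaustive 5-taxon minimum and never
           worsens its start", {
  set.seed(9)
  for (trial in 1:5) {
    base <- sample(c("A", "C", "G", "T"), 30, TRUE)
    m <- do.call(rbind, lapply(1:5, function(i) {
      mut <- sample(30, 8)
      out <- base
      out[mut] <- sample(c("A", "C", "G", "T"), 8, TRUE)
      out
    }))
    rownames(m) <- paste0("t", 1:5)
    aln <- its_alignment(m)
    res <- mp_search(aln)
    oracle <- brute_min_parsimony(aln)
    expect_equal(attr(res, "score"), oracle$score)
    start <- neighbor_joining(suppressWarnings(k2p_distance_matrix(aln)))
    expect_lte(attr(res, "score"), fitch_score(start, aln))
  }
  ## saturated data still searches (p-distance start fallback)
  msat <- matrix(sample(c("A", "C", "G", "T"), 5 * 30, TRUE), 5, 30,
                 dimnames = list(paste0("t", 1:5), NULL))
  alnsat <- its_alignment(msat)
  expect_equal(attr(mp_search(alnsat), "score"),
               brute_min_parsimony(alnsat)$score)
})

test_that("MP search returns the start topology for invariant alignments", {
  inv <- its_alignment(matrix("C", 5, 10,
                              dimnames = list(paste0("t", 1:5), NULL)))
  start <- read_newick("((t1,t2),(t3,t4),t5);")
  res <- mp_search(inv, start = start)
  expect_equal(attr(res, "score"), 0L)
  expect_equal(ape::dist.topo(ape::unroot(res), ape::unroot(start)), 0,
               ignore_attr = TRUE)
})

test_that("MP recovers a strongly supported generating topology", {
  tree <- "((a:0.02,b:0.02):0.03,((c:0.02,d:0.02):0.03,(e:0.02,f:0.02):0.03):0.03);"
  sim <- simulate_alignment(sim_config(tree = tree, seed = 90,
                                       region_sites = c(300, 300, 300),
                                       region_rates = c(1, 1, 1)))
  res <- mp_search(sim$alignment)
  expect_equal(ape::dist.topo(ape::unroot(res),
                              ape::unroot(read_newick(tree))), 0,
               ignore_attr = TRUE)
})

test_that("bootstrap supports are percentages of replicate bipartitions", {
  ## perfectly congruent signal: every column supports the same tree
  pat <- function(on) ifelse(paste0("t", 1:6) %in% on, "A", "G")
  m <- cbind(matrix(rep(pat(c("t1", "t2")), 8), 6),
             matrix(rep(pat(c("t3", "t4")), 8), 6),
             matrix(rep(pat(c("t5", "t6")), 8), 6),
             matrix("C", 6, 60))
  rownames(m) <- paste0("t", 1:6)
  aln <- its_alignment(m)
  tr <- bootstrap_tree(aln, "nj", B = 60, seed = 4)
  sup <- attr(tr, "supports")
  expect_true(all(sup$support == 100))
  ## B = 1: supports can only be 0 or 100
  tr1 <- bootstrap_tree(aln, "mp", B = 1, seed = 4)
  expect_true(all(attr(tr1, "supports")$support %in% c(0, 100)))
  expect_true(all(attr(tr, "supports")$support >= 0 &
                  attr(tr, "supports")$support <= 100))
})

test_that("bootstrap resampling is reproducible given the seed", {
  sim <- simulate_alignment(sim_config(n_taxa = 6, seed = 12,
                                       region_sites = c(80, 100, 80),
                                       total_depth = 0.08))
  t1 <- bootstrap_tree(sim$alignment, "nj", B = 30, seed = 99)
  t2 <- bootstrap_tree(sim$alignment, "nj", B = 30, seed = 99)
  expect_identical(attr(t1, "supports"), attr(t2, "supports"))
})

test_that("Newick round-trips preserve bipartitions and lengths", {
  set.seed(10)
  tr <- ape::rtree(20)
  nwk <- write_newick(tr)
  back <- read_newick(nwk)
  expect_setequal(tree_bipartitions(back), tree_bipartitions(tr))
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-6)
  ## file round-trip
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  expect_setequal(tree_bipartitions(read_newick(f)), tree_bipartitions(tr))
})

test_that("rooting on a leaf yields a two-child root and validates labels", {
  tr <- read_newick("(a:1,b:1,c:1);")
  rooted <- root_on_outgroup(tr, "c")
  expect_true(ape::is.rooted(rooted))
  root_children <- rooted$edge[rooted$edge[, 1] == length(rooted$tip.label) + 1L, 2]
  expect_length(root_children, 2L)
  expect_error(root_on_outgroup(tr, "zz"), "not in tree")
})
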