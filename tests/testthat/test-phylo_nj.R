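rf_dist <- function(t1, t2) ape::dist.topo(ape::unroot(t1), ape::unroot(t2))

test_that("distance models match closed forms and an independent oracle", {
  pair0 <- aln_from_strings(c("ACGTACGTAC", "ACGTACGTAC"))
  for (m in c("p", "K2P", "TN93", "composite"))
    expect_equal(unname(distance_matrix(pair0, m)[1, 2]), 0)

  # p-distance: 3 mismatches over 100 retained sites
  s <- paste(rep("ACGT", 25), collapse = "")
  s2 <- s; substr(s2, 1, 3) <- "TTT"
  expect_equal(unname(distance_matrix(aln_from_strings(c(s, s2)), "p")[1, 2]),
               0.03)

  # K2P closed form: 2 transitions (A<->G, C<->T), 1 transversion / 100
  x <- strsplit(s, "")[[1]]; y <- x
  y[1] <- "G"   # A->G transition
  y[2] <- "T"   # C->T transition
  y[3] <- "C"   # G->C transversion
  aK <- aln_from_strings(c(paste(x, collapse = ""), paste(y, collapse = "")))
  P <- 0.02; Q <- 0.01
  expect_equal(unname(distance_matrix(aK, "K2P")[1, 2]),
               -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q))
  # and against the ape implementation on a non-saturated alignment
  a <- related_aln(8, 200, nmut = 12, seed = 13)
  ours <- distance_matrix(a, "K2P")
  theirs <- as.matrix(ape::dist.dna(ape::as.DNAbin(a$seqs), model = "K80"))
  expect_equal(unname(ours[1:8, 1:8]), unname(theirs), tolerance = 1e-12)

  # symmetry / zero diagonal across models
  for (m in c("p", "K2P", "TN93", "composite")) {
    d <- distance_matrix(a, m)
    expect_true(isSymmetric(matrix(d, nrow(d))))
    expect_true(all(diag(d) == 0))
    expect_true(all(is.finite(d)))
  }

  # saturated pair hits the ceiling and is flagged
  sat <- aln_from_strings(c(strrep("A", 40), strrep("G", 40)))
  dsat <- distance_matrix(sat, "K2P", ceiling = 7)
  expect_equal(unname(dsat[1, 2]), 7)
  expect_true(attr(dsat, "saturated")[1, 2])
})

test_that("NJ is exact on additive matrices and matches the ape oracle", {
  # additive 4-taxon matrix from a known tree: exact recovery
  tr <- ape::read.tree(text = "((a:2,b:3):4,(c:1,d:5):2);")
  D <- ape::cophenetic.phylo(tr)
  est <- nj_tree(D)
  expect_equal(as.numeric(rf_dist(est, tr)), 0)
  expect_equal(ape::cophenetic.phylo(est)[rownames(D), colnames(D)], D,
               tolerance = 1e-10)

  # property: exact on random additive matrices, 4-8 taxa
  set.seed(14)
  for (k in 4:8) {
    tru <- ape::rtree(k)
    tru$edge.length <- runif(length(tru$edge.length), 0.5, 3)
    D <- ape::cophenetic.phylo(tru)
    expect_equal(as.numeric(rf_dist(nj_tree(D), tru)), 0)
  }

  # random (non-additive) matrices: same topology as the ape NJ oracle
  for (rep in 1:5) {
    M <- matrix(runif(36, 1, 10), 6, 6); M <- (M + t(M)) / 2; diag(M) <- 0
    rownames(M) <- colnames(M) <- letters[1:6]
    expect_equal(as.numeric(rf_dist(nj_tree(M), ape::nj(M))), 0)
  }

  # star-like equidistant taxa: tie-broken deterministically
  S <- matrix(2, 4, 4); diag(S) <- 0
  rownames(S) <- colnames(S) <- c("d", "b", "a", "c")
  expect_equal(ape::write.tree(nj_tree(S)), ape::write.tree(nj_tree(S)))

  expect_error(nj_tree(matrix(0, 2, 2)), ">= 3 taxa")
})

test_that("bootstrap support saturates on clean splits and is reproducible", {
  # two clades separated by 30 fixed differences, light noise within
  set.seed(15)
  block <- function(ch, n, L) matrix(ch, n, L)
  left <- cbind(block("A", 3, 30), block("C", 3, 30))
  right <- cbind(block("T", 3, 30), block("C", 3, 30))
  m <- rbind(left, right)
  for (i in 1:6) m[i, 30 + i] <- "G"   # unique mutations
  rownames(m) <- paste0("t", 1:6)
  a <- mt_alignment(m, data.frame(sample_id = rownames(m), breed = "b",
                                  region = "", metapopulation = ""))
  tr <- bootstrap_support(a, model = "p", B = 100, seed = 3)
  supp <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(any(supp[!is.na(supp)] == 100))

  tr1 <- bootstrap_support(a, model = "p", B = 50, seed = 9)
  tr2 <- bootstrap_support(a, model = "p", B = 50, seed = 9)
  expect_identical(tr1$node.label, tr2$node.label)   # bit-identical

  trB1 <- bootstrap_support(a, model = "p", B = 1, seed = 2)
  s1 <- suppressWarnings(as.numeric(trB1$node.label))
  expect_true(all(s1[!is.na(s1)] %in% c(0, 100)))

  expect_error(bootstrap_support(a, B = 0), "positive")
})

test_that("lineage assignment recovers reference labels and mixtures", {
  refs <- generate_reference_fixture()
  # a reference sequence is assigned its own label by both methods
  self_md <- assign_lineage(refs, refs, method = "min_distance")
  expect_equal(unname(self_md$assignment), refs$labels$breed)
  self_nj <- assign_lineage(refs, refs, method = "nj_clade")
  expect_equal(unname(self_nj$assignment), refs$labels$breed)

  # 1 mutation from ref A, 20 from everything else -> A
  qry <- refs$seqs["ref_A", , drop = FALSE]
  qry[1, 600] <- setdiff(c("A", "C", "G", "T"), qry[1, 600])[1]
  rownames(qry) <- "q1"
  aq <- mt_alignment(qry, data.frame(sample_id = "q1", breed = "", region = "",
                                     metapopulation = ""))
  expect_equal(unname(assign_lineage(aq, refs)$assignment), "A")

  # equidistant sample -> flagged ambiguous, not silently assigned
  half <- refs$seqs["ref_A", ]
  bsites <- which(refs$seqs["ref_A", ] != refs$seqs["ref_B", ])
  half[bsites[1:(length(bsites) / 2)]] <- refs$seqs["ref_B", bsites[1:(length(bsites) / 2)]]
  mhalf <- matrix(half, 1, dimnames = list("amb", NULL))
  aamb <- mt_alignment(mhalf, data.frame(sample_id = "amb", breed = "",
                                         region = "", metapopulation = ""))
  expect_true(is.na(assign_lineage(aamb, refs)$assignment))

  # synthetic 92:8-style mixture: recovered proportions = generating ones
  w <- matrix(c(0.95, 0.05), 10, 2, byrow = TRUE)
  w[6, ] <- c(0.21, 0.79)
  cfg <- generator_config(n_breeds = 10, samples_per_breed = 12,
                          n_lineages = 2, weights = w, seed = 17)
  gen <- generate_breeds(cfg)
  la <- assign_lineage(gen$alignment, gen$truth$founders)
  expect_equal(unname(la$assignment),
               unname(gen$truth$lineage[names(la$assignment)]))
  # both methods agree when the margin is clear
  lc <- assign_lineage(gen$alignment, gen$truth$founders, method = "nj_clade")
  expect_equal(la$assignment, lc$assignment)
})
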