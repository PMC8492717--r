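test_that("haplotype diversity reproduces published values and the formula", {
  d <- haplotype_diversity(rep(1, 6))
  expect_equal(d$h, 1)
  expect_equal(sprintf("%.4f", d$se_h), "0.0962")   # Katchaikatty Black row
  d0 <- haplotype_diversity(30)
  expect_equal(d0$h, 0)                              # Ramnad White CYTB row
  expect_equal(d0$se_h, 0)
  expect_equal(haplotype_diversity(c(2, 1, 1))$h, 4 / 3 * (1 - 6 / 16))

  expect_error(haplotype_diversity(1), "at least 2")

  # independent implementation on random count vectors (plug-in parity)
  nei_oracle <- function(cnt) {
    n <- sum(cnt); p <- cnt / n
    h <- n / (n - 1) * (1 - sum(p^2))
    v <- 2 / (n * (n - 1)) *
      (2 * (n - 2) * (sum(p^3) - sum(p^2)^2) + sum(p^2) - sum(p^2)^2)
    c(h, sqrt(max(v, 0)))
  }
  set.seed(3)
  for (i in 1:1000) {
    cnt <- rmultinom(1, sample(2:80, 1), prob = runif(sample(1:6, 1)))[, 1]
    cnt <- cnt[cnt > 0]
    if (sum(cnt) < 2) next
    d <- haplotype_diversity(cnt)
    expect_equal(c(d$h, d$se_h), nei_oracle(cnt), tolerance = 1e-12)
  }
})

test_that("pairwise differences and mismatch distributions match oracles", {
  ident <- aln_from_strings(rep("ACGTACGT", 4))
  expect_equal(mean_pairwise_differences(ident, "pop1"), 0)
  two <- aln_from_strings(c("AAAAAA", "AATTTA"))
  expect_equal(mean_pairwise_differences(two, "pop1"), 3)
  expect_error(mean_pairwise_differences(aln_from_strings("ACGT"), "pop1"),
               ">= 2")

  a <- random_aln(10, 50, seed = 11)
  d <- 0; n <- 0
  for (i in 1:9) for (j in (i + 1):10) {
    d <- d + oracle_pairdiff(a$seqs, i, j); n <- n + 1
  }
  expect_equal(mean_pairwise_differences(a, "pop1"), d / n)

  # between-population variant: all cross pairs, uncorrected
  ab <- random_aln(8, 30, seed = 12, breed = rep(c("p1", "p2"), each = 4))
  dd <- mean(sapply(1:4, function(i)
    sapply(5:8, function(j) oracle_pairdiff(ab$seqs, i, j))))
  expect_equal(mean_pairwise_differences(ab, c("p1", "p2")), dd)

  expect_equal(mismatch_distribution(aln_from_strings(rep("ACGT", 3))),
               c("0" = 3L))
  expect_equal(mismatch_distribution(aln_from_strings(c("AAAA", "AAAT", "AATT"))),
               c("1" = 2L, "2" = 1L))
  mm <- mismatch_distribution(a)
  expect_equal(sum(mm), 10 * 9 / 2)
})

test_that("AMOVA components equal an explicit sums-of-squares oracle", {
  # 3 populations x 6 samples, one-level decomposition
  a <- random_aln(18, 40, seed = 21,
                  breed = rep(c("p1", "p2", "p3"), each = 6))
  res <- amova(a)

  # independent oracle: build the 18x18 distance matrix by loops and
  # apply the variance-component formulas from scratch
  D <- matrix(0, 18, 18)
  for (i in 1:17) for (j in (i + 1):18)
    D[i, j] <- D[j, i] <- oracle_pairdiff(a$seqs, i, j)
  pops <- rep(1:3, each = 6)
  N <- 18; P <- 3
  ss_tot <- sum(D[upper.tri(D)]) / N
  ss_w <- sum(sapply(1:3, function(p) {
    idx <- which(pops == p); sub <- D[idx, idx]
    sum(sub[upper.tri(sub)]) / length(idx)
  }))
  ss_a <- ss_tot - ss_w
  ms_w <- ss_w / (N - P); ms_a <- ss_a / (P - 1)
  nc <- (N - sum(rep(6, 3)^2) / N) / (P - 1)
  sig_a <- (ms_a - ms_w) / nc
  expect_equal(res$components$SS, c(ss_a, ss_w, ss_tot))
  expect_equal(res$components$df, c(2L, 15L, 17L))
  expect_equal(res$components$sigma2[1:2], c(sig_a, ms_w))
  expect_equal(res$phi[["Phi_ST"]],
               max(sig_a, 0) / (max(sig_a, 0) + ms_w))
  # percentages sum to 100; partition SSDs sum to the total
  expect_equal(sum(res$components$pct[1:2]), 100, tolerance = 1e-6)
  expect_equal(ss_a + ss_w, ss_tot)

  # two identical populations -> among-population percentage 0
  base <- c("AAAA", "AATT", "ATTT", "AAAA")
  dup <- aln_from_strings(c(base, base),
                          breed = rep(c("p1", "p2"), each = 4))
  expect_equal(amova(dup)$components$pct[1], 0)

  # two populations fixed for haplotypes d sites apart -> Phi_ST = 1
  fixed <- aln_from_strings(c(rep("AAAAAA", 5), rep("TTTAAA", 5)),
                            breed = rep(c("p1", "p2"), each = 5))
  rf <- amova(fixed)
  expect_equal(rf$phi[["Phi_ST"]], 1)
  expect_equal(rf$components$pct[1], 100)

  expect_error(amova(random_aln(6, 10, 1)), ">= 2 populations")

  # Phi invariant to sample order
  set.seed(4)
  expect_equal(amova(a[sample(18)])$phi, res$phi)
})

test_that("two-level AMOVA percentages sum to 100 and dfs to n-1", {
  set.seed(31)
  a <- random_aln(24, 30, seed = 31, breed = rep(paste0("p", 1:4), each = 6))
  a$labels$region <- rep(c("g1", "g2"), each = 12)
  res <- amova(a, pop_level = "breed", group_level = "region")
  expect_equal(sum(res$components$df[1:3]), 23L)
  expect_equal(sum(res$components$pct[1:3]), 100, tolerance = 1e-6)
  expect_equal(sum(res$components$SS[1:3]), res$components$SS[4])
  expect_named(res$phi, c("Phi_ST", "Phi_CT", "Phi_SC"))
})

test_that("pairwise Phi_ST is a table of two-population AMOVAs", {
  a <- random_aln(24, 25, seed = 41, breed = rep(paste0("p", 1:4), each = 6))
  f <- pairwise_fst(a)
  expect_true(isSymmetric(f$fst))
  expect_true(all(diag(f$fst) == 0))
  # each cell equals a fresh 2-population amova() call
  for (i in 1:3) for (j in (i + 1):4) {
    keep <- a$labels$breed %in% paste0("p", c(i, j))
    phi <- amova(a[keep])$phi[["Phi_ST"]]
    expect_equal(f$fst[i, j], phi)
  }
  # duplicated population -> 0 off-diagonal; fixed divergent pair -> 1
  base <- c("AAAAAA", "AATTAA", "ATTTAA")
  dup <- aln_from_strings(c(base, base, rep("GGGGGG", 3), rep("CCCCCC", 3)),
                          breed = rep(c("p1", "p2", "p3", "p4"), each = 3))
  fd <- pairwise_fst(dup)
  expect_equal(fd$fst["p1", "p2"], 0)
  expect_equal(fd$fst["p3", "p4"], 1)   # both fixed, divergent

  # no differentiation: random labels -> mean Phi_ST near 0
  set.seed(5)
  phis <- replicate(20, {
    b <- random_aln(20, 60, seed = sample.int(1e6, 1),
                    breed = sample(rep(c("x", "y"), each = 10)))
    pairwise_fst(b)$fst[1, 2]
  })
  expect_lt(abs(mean(phis)), 0.05)
})
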