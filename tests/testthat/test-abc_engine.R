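# shared small scenario machinery for this file
panmictic <- scenario("pan", "P", c(P = "N"),
                      data.frame(derived = character(0),
                                 source = character(0),
                                 time = character(0)))
two_pop <- scenario("split", c("X", "Y"), c(X = "NX", Y = "NY"),
                    data.frame(derived = "Y", source = "X", time = "t1"))

test_that("simulate_dataset respects sample structure and constraints", {
  pars <- list(N = 5000, mu = 5e-8, kappa = 5)
  set.seed(1)
  one <- simulate_dataset(panmictic, pars, c(P = 1L), L = 500)
  expect_equal(length(one$sample_ids), 1L)
  expect_length(polymorphic_sites(one), 0L)

  set.seed(2)
  a <- simulate_dataset(panmictic, pars, c(P = 10L), L = 500)
  expect_equal(a$L, 500L)
  expect_equal(unique(a$labels$metapopulation), "P")

  # identical seeds give identical datasets
  set.seed(7); s1 <- simulate_dataset(panmictic, pars, c(P = 8L), L = 300)
  set.seed(7); s2 <- simulate_dataset(panmictic, pars, c(P = 8L), L = 300)
  expect_identical(s1$seqs, s2$seqs)

  # constraint violations are rejected before simulation
  con <- scenario("c", c("X", "Y"), c(X = "NX", Y = "NY"),
                  data.frame(derived = "Y", source = "X", time = "t1"),
                  list(c("t1", ">", "t2")))
  expect_error(simulate_dataset(con, list(NX = 100, NY = 100, t1 = 5,
                                          t2 = 10, mu = 1e-7, kappa = 5),
                                c(X = 2L, Y = 2L)),
               "constraint")
  expect_error(simulate_dataset(panmictic, pars, c(P = 0L)), "zero sample")
})

test_that("coalescent expectations: pi and S at small scale", {
  # E[pi] = 2 Ne mu L and Watterson E[S] = a_n theta (light version;
  # the full 2000-replicate calibration runs in the acceptance suite)
  Ne <- 4000; mu <- 5e-8; L <- 500; n <- 20
  theta <- 2 * Ne * mu * L
  pars <- list(N = Ne, mu = mu, kappa = 5)
  set.seed(11)
  reps <- 400
  pis <- numeric(reps); Ss <- numeric(reps)
  for (i in seq_len(reps)) {
    sim <- simulate_dataset(panmictic, pars, c(P = n), L, as_alignment = FALSE)
    ss <- summary_stats(sim, pops = "P")
    pis[i] <- ss[["pi.P"]]
    X <- sim$seqs
    Ss[i] <- if (ncol(X)) sum(apply(X, 2, function(v) length(unique(v)) > 1))
             else 0
  }
  expect_lt(abs(mean(pis) - theta), 3 * sd(pis) / sqrt(reps))
  a_n <- sum(1 / seq_len(n - 1))
  expect_lt(abs(mean(Ss) - a_n * theta), 3 * sd(Ss) / sqrt(reps))
})

test_that("divergence time drives Phi_ST towards 1", {
  mu <- 5e-8; L <- 600
  set.seed(13)
  mean_fst <- vapply(c(200, 2000, 20000, 2e5), function(t1) {
    mean(replicate(60, {
      sim <- simulate_dataset(two_pop,
                              list(NX = 2000, NY = 2000, t1 = t1,
                                   mu = mu, kappa = 5),
                              c(X = 10L, Y = 10L), L, as_alignment = FALSE)
      summary_stats(sim, pops = c("X", "Y"))[["fst.X.Y"]]
    }))
  }, numeric(1))
  expect_true(all(diff(mean_fst) > 0))
  expect_gt(mean_fst[4], 0.9)
})

test_that("summary statistics match hand counts and a brute-force oracle", {
  # monomorphic population: zeros, flagged
  mono <- aln_from_strings(rep("ACGT", 4), metapopulation = "P")
  sm <- summary_stats(mono, pops = "P")
  expect_equal(as.numeric(sm), c(0, 0, 0))
  expect_equal(attr(sm, "flags"), "P")

  # {AAAA x3, AAAT}: one segregating site, rarest count 1
  h <- aln_from_strings(c("AAAA", "AAAA", "AAAA", "AAAT"),
                        metapopulation = "P")
  sh <- summary_stats(h, pops = "P")
  expect_equal(unname(sh[c("mean_rare.P", "var_rare.P")]), c(1, 0))
  expect_equal(unname(sh[["pi.P"]]), mean(c(0, 0, 1, 0, 1, 1)))

  expect_error(summary_stats(h, pops = c("P", "Q")), "absent")

  # random two-population alignment vs an independent per-site tally
  a <- random_aln(14, 30, seed = 17,
                  breed = rep(c("p1", "p2"), times = c(6, 8)))
  a$labels$metapopulation <- a$labels$breed
  v <- summary_stats(a, pops = c("p1", "p2"))
  oracle_pop <- function(seqs) {
    n <- nrow(seqs)
    pi <- mean(apply(combn(n, 2), 2, function(ij)
      oracle_pairdiff(seqs, ij[1], ij[2])))
    rare <- c()
    for (j in seq_len(ncol(seqs))) {
      tab <- table(seqs[, j])
      if (length(tab) >= 2) rare <- c(rare, min(tab))
    }
    c(pi, mean(rare), var(rare))
  }
  o1 <- oracle_pop(a$seqs[1:6, ]); o2 <- oracle_pop(a$seqs[7:14, ])
  expect_equal(unname(v[1:3]), o1)
  expect_equal(unname(v[4:6]), o2)
  piB <- mean(sapply(1:6, function(i)
    sapply(7:14, function(j) oracle_pairdiff(a$seqs, i, j))))
  expect_equal(unname(v[["piB.p1.p2"]]), piB)
  # Phi_ST agrees with the AMOVA module (floored convention)
  expect_equal(unname(v[["fst.p1.p2"]]),
               unname(amova(a, pop_level = "breed")$phi[["Phi_ST"]]))
})

test_that("reference tables are reproducible and honour priors", {
  pri <- prior_spec(NX = list(dist = "unif", min = 500, max = 5000),
                    NY = list(dist = "unif", min = 500, max = 5000),
                    t1 = list(dist = "unif", min = 100, max = 5000))
  scns <- list(two_pop,
               scenario("split2", c("X", "Y"), c(X = "NX", Y = "NY"),
                        data.frame(derived = "X", source = "Y",
                                   time = "t1")))
  samples <- c(X = 8L, Y = 8L)
  rt <- build_reference_table(scns, pri, 10L, samples, 300L, seed = 5)
  expect_equal(nrow(rt$stats), 20L)
  expect_equal(as.integer(table(rt$scenario)), c(10L, 10L))
  expect_false(anyNA(rt$stats))
  rt2 <- build_reference_table(scns, pri, 10L, samples, 300L, seed = 5)
  expect_identical(rt$stats, rt2$stats)     # bit-identical
  expect_identical(rt$params, rt2$params)

  # point-mass priors: parameters constant, stats vary by coalescent noise
  pri0 <- prior_spec(NX = list(dist = "unif", min = 1000, max = 1000),
                     NY = list(dist = "unif", min = 1000, max = 1000),
                     t1 = list(dist = "unif", min = 800, max = 800),
                     mu = list(dist = "unif", min = 5e-8, max = 5e-8),
                     kappa = list(dist = "unif", min = 5, max = 5))
  rt0 <- build_reference_table(scns[1], pri0, 8L, samples, 300L, seed = 6)
  expect_equal(nrow(unique(rt0$params)), 1L)
  expect_gt(nrow(unique(as.data.frame(rt0$stats))), 1L)

  # unreachable constraint region errors with the constraint named
  bad <- scenario("bad", c("X", "Y"), c(X = "NX", Y = "NY"),
                  data.frame(derived = "Y", source = "X", time = "t1"),
                  list(c("t1", ">", "NX")))
  pri_bad <- prior_spec(NX = list(dist = "unif", min = 1e6, max = 2e6),
                        t1 = list(dist = "unif", min = 1, max = 2))
  expect_error(draw_params(bad, pri_bad, max_tries = 20),
               "unreachable")
})

test_that("model choice: symmetry, frequency fallback, normalization", {
  pri <- prior_spec(NX = list(dist = "unif", min = 500, max = 5000),
                    NY = list(dist = "unif", min = 500, max = 5000),
                    t1 = list(dist = "unif", min = 100, max = 5000))
  # two scenarios defined identically -> posteriors ~ 0.5/0.5
  twins <- list(two_pop,
                scenario("twin", c("X", "Y"), c(X = "NX", Y = "NY"),
                         data.frame(derived = "Y", source = "X",
                                    time = "t1")))
  samples <- c(X = 10L, Y = 10L)
  rt <- build_reference_table(twins, pri, 600L, samples, 400L, seed = 8)
  set.seed(9)
  obs <- summary_stats(
    simulate_dataset(twins[[1]], draw_params(twins[[1]], pri), samples, 400L,
                     as_alignment = FALSE), pops = rt$pops)
  mc <- model_choice(rt, obs, tolerance = 0.2)
  expect_equal(sum(mc$table$posterior), 1, tolerance = 1e-6)
  expect_true(mc$table$ci_low[1] <= 0.5 && mc$table$ci_high[1] >= 0.5 ||
                abs(mc$table$posterior[1] - 0.5) < 0.15)

  # tolerance = 1 with the frequency estimator = per-scenario fractions
  pri_s <- prior_spec()
  st <- matrix(rnorm(200 * 4), 200, 4,
               dimnames = list(NULL, paste0("s", 1:4)))
  rtm <- manual_reftable(rep(c("A", "B"), times = c(60, 140)),
                         data.frame(N = runif(200)), st, pri_s)
  mcf <- model_choice(rtm, st[1, ], tolerance = 1, estimator = "frequency")
  expect_equal(mcf$table$posterior, c(0.3, 0.7))

  # probabilities invariant to affine rescaling of any statistic
  st2 <- st; st2[, 2] <- st2[, 2] * 1000 + 5
  rtm2 <- manual_reftable(rep(c("A", "B"), times = c(60, 140)),
                          data.frame(N = runif(200)), st2, pri_s)
  obs1 <- st[7, ]; obs2 <- st2[7, ]
  m1 <- model_choice(rtm, obs1, tolerance = 0.25)
  m2 <- model_choice(rtm2, obs2, tolerance = 0.25)
  expect_equal(m1$table$posterior, m2$table$posterior, tolerance = 1e-6)
  # and to statistic ordering
  perm <- c(3, 1, 4, 2)
  rtm3 <- manual_reftable(rep(c("A", "B"), times = c(60, 140)),
                          data.frame(N = runif(200)), st[, perm], pri_s)
  m3 <- model_choice(rtm3, obs1[perm], tolerance = 0.25)
  expect_equal(m3$table$posterior, m1$table$posterior, tolerance = 1e-6)

  # a scenario absent from the retained set -> probability ~0, warning
  stA <- rbind(matrix(rnorm(150 * 2), 150, 2),
               matrix(rnorm(50 * 2, mean = 50), 50, 2))
  rtA <- manual_reftable(rep(c("near", "far"), times = c(150, 50)),
                         data.frame(N = runif(200)), stA, pri_s)
  expect_warning(mA <- model_choice(rtA, c(0, 0), tolerance = 0.1),
                 "absent")
  expect_equal(mA$table$posterior[2], 0)
})

test_that("PCA pre-evaluation flags displaced observations", {
  pri_s <- prior_spec()
  st <- matrix(rnorm(300 * 5), 300, 5)
  colnames(st) <- paste0("s", 1:5)
  rtm <- manual_reftable(rep("A", 300), data.frame(N = runif(300)), st, pri_s)
  inside <- preevaluate_pca(rtm, st[3, ])
  expect_false(inside$flag)
  displaced <- preevaluate_pca(rtm, st[3, ] + 10 * apply(st, 2, sd))
  expect_true(displaced$flag)
  # zero-variance statistics dropped with a warning
  st0 <- cbind(st, s6 = 1)
  rt0 <- manual_reftable(rep("A", 300), data.frame(N = runif(300)), st0, pri_s)
  expect_warning(p0 <- preevaluate_pca(rt0, st0[3, ]), "zero-variance")
  expect_equal(p0$dropped, "s6")
})

test_that("local linear adjustment estimates parameters within prior bounds", {
  # white-box reference table with a planted linear parameter-SS map
  set.seed(19)
  n <- 2000
  a_b <- c(100, 10000)
  theta <- runif(n, a_b[1], a_b[2])
  ss <- cbind(s1 = theta / 1000 + rnorm(n, 0, 0.3),
              s2 = rnorm(n))
  pri <- prior_spec(N1 = list(dist = "unif", min = a_b[1], max = a_b[2]))
  scn1 <- scenario("s1", "P", c(P = "N1"),
                   data.frame(derived = character(0), source = character(0),
                              time = character(0)))
  rtm <- manual_reftable(rep("s1", n), data.frame(N1 = theta,
                                                  mu = runif(n, 1e-8, 1e-7),
                                                  kappa = runif(n, 2, 20)),
                         ss, pri, scenarios = list(scn1), pops = "P",
                         samples = c(P = 20L))
  theta_true <- 4000
  obs <- c(s1 = theta_true / 1000, s2 = 0)
  post <- estimate_parameters(rtm, "s1", obs, tolerance = 0.05)
  # never outside prior bounds
  expect_true(all(post$sample[, "N1"] >= a_b[1] &
                    post$sample[, "N1"] <= a_b[2]))
  # the planted relationship is recovered: adjusted median close to truth
  med <- post$summary$median[post$summary$parameter == "N1"]
  expect_lt(abs(med - theta_true) / theta_true, 0.15)
  # regression beats rejection-only across repeated observations
  rej_med <- function(obs) {
    d <- mtphylogeo:::.abc_distances(rtm$stats,
                                     obs, mtphylogeo:::.stat_scales(rtm$stats))
    idx <- order(d)[1:100]
    median(theta[idx])
  }
  errs <- t(vapply(seq(1000, 9000, by = 800), function(tt) {
    ob <- c(s1 = tt / 1000, s2 = 0)
    p <- estimate_parameters(rtm, "s1", ob, tolerance = 0.05)
    c(adj = abs(p$summary$median[p$summary$parameter == "N1"] - tt),
      rej = abs(rej_med(ob) - tt))
  }, numeric(2)))
  expect_lt(mean(errs[, "adj"]), mean(errs[, "rej"]))

  # observed at the cloud centroid: adjustment is small
  obs_c <- c(s1 = mean(ss[, 1]), s2 = mean(ss[, 2]))
  p_c <- estimate_parameters(rtm, "s1", obs_c, tolerance = 0.05)
  d <- mtphylogeo:::.abc_distances(rtm$stats, obs_c,
                                   mtphylogeo:::.stat_scales(rtm$stats))
  idx <- order(d)[seq_len(p_c$n_retained)]
  expect_lt(abs(p_c$summary$median[p_c$summary$parameter == "N1"] -
                  median(theta[idx])) / median(theta[idx]), 0.2)
})

test_that("scenario choice error and goodness of fit behave correctly", {
  pri <- prior_spec(NX = list(dist = "unif", min = 500, max = 5000),
                    NY = list(dist = "unif", min = 500, max = 5000),
                    t1 = list(dist = "unif", min = 100, max = 5000))
  twins <- list(two_pop,
                scenario("twin", c("X", "Y"), c(X = "NX", Y = "NY"),
                         data.frame(derived = "Y", source = "X",
                                    time = "t1")))
  samples <- c(X = 8L, Y = 8L)
  rt <- build_reference_table(twins, pri, 400L, samples, 300L, seed = 21)
  # indistinguishable scenarios: error ~ 1 - 1/k = 0.5
  e1 <- scenario_choice_error(rt, n_test = 60L, tolerance = 0.1, seed = 31)
  expect_gt(e1$error, 0.3); expect_lt(e1$error, 0.7)
  e2 <- scenario_choice_error(rt, n_test = 60L, tolerance = 0.1, seed = 31)
  expect_identical(e1$error, e2$error)      # fixed seed -> identical
  expect_error(scenario_choice_error(rt, n_test = 0L), "positive")

  # goodness of fit: self-consistent observation is not rejected,
  # a grossly displaced one is
  set.seed(33)
  obs <- summary_stats(
    simulate_dataset(two_pop, draw_params(two_pop, pri), samples, 300L,
                     as_alignment = FALSE), pops = rt$pops)
  post <- suppressWarnings(estimate_parameters(rt, "split", obs,
                                               tolerance = 0.2))
  gof <- goodness_of_fit(rt, post, obs, n_ppc = 80L, seed = 35)
  expect_true(all(gof$tail_prob >= 0 & gof$tail_prob <= 1))
  expect_gt(median(gof$tail_prob), 0.05)
  gof_bad <- goodness_of_fit(rt, post, obs + 40, n_ppc = 250L, seed = 35)
  expect_true(any(gof_bad$tail_prob < 0.01))
  expect_error(goodness_of_fit(rt, post, obs, n_ppc = 0L), "positive")
})

test_that("RMAE machinery validates against injected estimators", {
  pri <- prior_spec(NX = list(dist = "unif", min = 500, max = 5000),
                    NY = list(dist = "unif", min = 500, max = 5000),
                    t1 = list(dist = "unif", min = 100, max = 5000))
  samples <- c(X = 6L, Y = 6L)
  rt <- build_reference_table(list(two_pop), pri, 60L, samples, 300L,
                              seed = 41)
  # perfect estimator -> RMAE exactly 0
  perfect <- function(rt, winner, obs, tol, truth) truth
  r0 <- parameter_rmae(rt, "split", n_pods = 20L, seed = 43,
                       estimator = perfect)
  expect_equal(r0$rmae, rep(0, nrow(r0)))
  expect_false(any(r0$flagged))
})
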