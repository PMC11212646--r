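test_that("RCBD decomposition has the Method 1 df layout and additive SS", {
  d <- simulate_diallel(sim_truth(p = 8, r = 3, seed = 2))
  rb <- rcbd_anova(d, "trait")
  expect_equal(rb$table$df, c(2, 63, 126))

  # SS_total equals brute-force sum of squared deviations and the parts add
  y <- d$plots$trait
  ss_total <- sum((y - mean(y))^2)
  expect_equal(sum(rb$table$SS), ss_total)
  expect_gt(rb$ms_residual, 0)

  # zero-variance data -> all SS zero
  d0 <- d
  d0$plots$trait <- 3.3
  rb0 <- rcbd_anova(d0, "trait")
  expect_equal(rb0$table$SS, rep(0, 3))

  # r = 1 leaves no residual df
  d1 <- as_diallel_data(toy_plots(p = 4, r = 1, traits = "y"))
  expect_error(rcbd_anova(d1, "y"), "at least 2 replications")
})

test_that("Griffing effects satisfy the closed-form special cases", {
  p <- 5
  # constant table: everything zero, mu = c
  mc <- new_cross_means(matrix(4.2, p, p))
  gc <- griffing_effects(mc)
  expect_equal(gc$mu, 4.2)
  expect_equal(unname(gc$g), rep(0, p))
  expect_true(all(abs(gc$s) < 1e-12) && all(abs(gc$rec) < 1e-12))

  # purely additive table x_ij = a_i + a_j with sum(a) = 0
  set.seed(31)
  a <- rnorm(p)
  a <- a - mean(a)
  ga <- griffing_effects(new_cross_means(outer(a, a, "+") + 10))
  expect_equal(unname(ga$g), a)
  expect_true(all(abs(ga$s) < 1e-12) && all(abs(ga$rec) < 1e-12))

  # antisymmetric perturbation moves only the reciprocal effects
  mn <- random_means(p, seed = 7)
  set.seed(8)
  dlt <- matrix(rnorm(p * p), p, p)
  dlt <- (dlt - t(dlt)) / 2
  g1 <- griffing_effects(mn)
  g2 <- griffing_effects(new_cross_means(mn$x + dlt))
  expect_equal(g2$g, g1$g)
  expect_equal(g2$s, g1$s)
  expect_equal(unname(g2$rec - g1$rec), unname(dlt))
})

test_that("Griffing GCA agrees with a least-squares projection oracle", {
  mn <- random_means(4, seed = 13)
  oracle <- lsq_additive_fit(mn$x)
  ge <- griffing_effects(mn)
  expect_equal(unname(ge$g), unname(oracle$g))
  expect_equal(ge$mu, oracle$mu)
})

test_that("effects reconstruct every entry mean and obey the constraints", {
  for (seed in 1:5) {
    mn <- random_means(sample(4:8, 1), seed = seed)
    ge <- griffing_effects(mn)
    recon <- ge$mu + outer(ge$g, ge$g, "+") + ge$s + ge$rec
    expect_equal(unname(recon), unname(mn$x))
    expect_lt(abs(sum(ge$g)), 1e-10)
    expect_equal(ge$s, t(ge$s))
    expect_equal(ge$rec, -t(ge$rec))
    expect_equal(unname(diag(ge$rec)), rep(0, mn$n_parents))
  }
})

test_that("combining-ability ANOVA partitions SS and df exactly", {
  # p = 8 reproduces the Method 1 df layout
  mn8 <- random_means(8, seed = 3)
  ca8 <- combining_ability_anova(mn8, ms_residual = 2, df_residual = 126, r = 3)
  df8 <- ca8$table$df[match(c("GCA", "SCA", "Reciprocal", "Maternal",
                              "Non-Maternal"), ca8$table$source)]
  expect_equal(df8, c(7, 28, 28, 7, 21))

  # symmetric table has no reciprocal variation at all
  ms <- random_means(6, seed = 4, symmetric = TRUE)
  cas <- combining_ability_anova(ms, 1, 50, 2)$table
  expect_equal(cas$SS_mean[cas$source %in%
                 c("Reciprocal", "Maternal", "Non-Maternal")], rep(0, 3))

  # SS additivity against a brute-force oracle on random instances
  for (seed in 1:8) {
    mn <- random_means(4, seed = 100 + seed)
    tab <- combining_ability_anova(mn, 1.5, 30, 2)$table
    ss <- function(src) tab$SS_mean[tab$source == src]
    brute_treat <- sum((mn$x - mean(mn$x))^2)
    expect_equal(ss("Treatments"), brute_treat)
    expect_equal(ss("GCA") + ss("SCA") + ss("Reciprocal"), brute_treat)
    expect_equal(ss("Maternal") + ss("Non-Maternal"), ss("Reciprocal"))
    brute_rec <- 0
    for (i in 1:3) for (j in (i + 1):4)
      brute_rec <- brute_rec + (mn$x[i, j] - mn$x[j, i])^2 / 2
    expect_equal(ss("Reciprocal"), brute_rec)
    expect_true(all(tab$SS_mean >= -1e-10))
    dfs <- tab$df[tab$source != "Residual"]
    expect_equal(sum(dfs[-1]) - dfs[tab$source == "Maternal"] -
                   dfs[tab$source == "Non-Maternal"], dfs[1])
  }
  expect_error(combining_ability_anova(mn8, 0, 10, 3), "positive")
})

test_that("standard errors scale correctly and match Monte Carlo", {
  p <- 4; r <- 3
  se0 <- effect_standard_errors(0, r, p)
  expect_true(all(se0 == 0))
  se1 <- effect_standard_errors(1.3, r, p)
  se2 <- effect_standard_errors(2.6, r, p)
  expect_equal(as.numeric(se2), as.numeric(sqrt(2) * se1), tolerance = 1e-12)

  # empirical sd of g_1 and m_1 over error-only diallels (variance of an
  # entry mean = sigma2 / r); vectorized, 10k draws
  sigma2 <- 1.3
  n_mc <- 10000
  set.seed(77)
  g1 <- m1 <- s12 <- r12 <- numeric(n_mc)
  for (k in seq_len(n_mc)) {
    e <- matrix(rnorm(p * p, 0, sqrt(sigma2 / r)), p, p)
    rt <- rowSums(e); ct <- colSums(e); gt <- sum(e)
    g1[k] <- (rt[1] + ct[1]) / (2 * p) - gt / p^2
    m1[k] <- (rt[1] - ct[1]) / (2 * p)
    s12[k] <- (e[1, 2] + e[2, 1]) / 2 -
      (rt[1] + ct[1] + rt[2] + ct[2]) / (2 * p) + gt / p^2
    r12[k] <- (e[1, 2] - e[2, 1]) / 2
  }
  se <- effect_standard_errors(sigma2, r, p)
  expect_equal(sd(g1), unname(se["gca"]), tolerance = 0.03)
  expect_equal(sd(m1), unname(se["maternal"]), tolerance = 0.03)
  expect_equal(sd(s12), unname(se["sca"]), tolerance = 0.03)
  expect_equal(sd(r12), unname(se["reciprocal"]), tolerance = 0.03)
})
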