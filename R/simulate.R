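#' Define the generating truth of a synthetic full diallel
#'
#' Builds the fixed (Model I) truth for a p-parent, r-replicate diallel:
#' grand mean, centred block effects, general combining abilities with a
#' maternal component (female-side effect g + m, male-side g - m), a
#' symmetric SCA matrix and an antisymmetric non-maternal reciprocal
#' matrix, plus the residual standard deviation. Supplied effects are
#' projected into the estimation constraint space (g, m, blocks centred;
#' SCA symmetric with zero row sums; non-maternal antisymmetric with zero
#' row sums and zero diagonal) so that with `sigma_e = 0` every estimator
#' in the pipeline recovers its generating value exactly. Unsupplied
#' effects are drawn from centred normal distributions with the given
#' spreads.
#'
#' The default scenario mimics a maize grain-yield diallel at the scale
#' of a p = 8, r = 3 field trial: grand mean about 70 q/ha, plot residual
#' variance about 47, parental GCA spread of a few q/ha, maternal and
#' SCA spreads large enough that reciprocal differences matter.
#'
#' @param p Number of parents (>= 3).
#' @param r Number of replications (>= 1).
#' @param mu Grand mean.
#' @param g,m Optional length-p vectors of GCA and maternal effects.
#' @param s Optional p x p symmetric SCA matrix.
#' @param nm Optional p x p antisymmetric non-maternal reciprocal matrix.
#' @param block Optional length-r vector of block effects.
#' @param sd_g,sd_m,sd_s,sd_nm,sd_block Spreads used to draw any effect
#'   not supplied explicitly (standard deviations before projection).
#' @param sigma_e Plot residual standard deviation.
#' @param self_depression Offset added to every selfed (diagonal) entry,
#'   e.g. a negative value for inbreeding depression. Nonzero values
#'   shift the estimands of the diagonal-bearing effects; recovery
#'   studies then use the noiseless-analysis values as truth.
#' @param seed Integer seed for drawing the effects and, by default, the
#'   plot errors.
#' @param trait,parents Labels carried through to the simulated data.
#' @return Object of class `sim_truth`.
#' @seealso [simulate_diallel()], [recovery_experiment()]
#' @export
sim_truth <- function(p = 8, r = 3, mu = 70,
                      g = NULL, m = NULL, s = NULL, nm = NULL, block = NULL,
                      sd_g = 3.5, sd_m = 5.5, sd_s = 12, sd_nm = 6,
                      sd_block = 1.5, sigma_e = 6.9,
                      self_depression = 0, seed = 1L,
                      trait = "trait", parents = paste0("P", seq_len(p))) {
  p <- as.integer(p); r <- as.integer(r)
  if (p < 3L) stop("'p' must be >= 3")
  if (r < 1L) stop("'r' must be >= 1")
  if (sigma_e < 0) stop("'sigma_e' must be non-negative")
  if (length(parents) != p || anyDuplicated(parents))
    stop("'parents' must be p unique labels")
  set.seed(as.integer(seed))

  center <- function(v) v - mean(v)
  if (is.null(g)) g <- stats::rnorm(p, 0, sd_g)
  if (is.null(m)) m <- stats::rnorm(p, 0, sd_m)
  if (is.null(block)) block <- if (r > 1) stats::rnorm(r, 0, sd_block) else 0
  g <- as.numeric(g); m <- as.numeric(m); block <- as.numeric(block)
  if (length(g) != p || length(m) != p) stop("'g' and 'm' must have length p")
  if (length(block) != r) stop("'block' must have length r")
  g <- center(g); m <- center(m); block <- center(block)

  if (is.null(s)) s <- matrix(stats::rnorm(p * p, 0, sd_s), p, p)
  s <- as.matrix(s)
  if (!all(dim(s) == p)) stop("'s' must be p x p")
  s <- (s + t(s)) / 2
  u <- rowSums(s)
  a <- (u - sum(u) / (2 * p)) / p
  s <- s - outer(a, a, "+") # symmetric, all row/col sums now zero

  if (is.null(nm)) nm <- matrix(stats::rnorm(p * p, 0, sd_nm), p, p)
  nm <- as.matrix(nm)
  if (!all(dim(nm) == p)) stop("'nm' must be p x p")
  nm <- (nm - t(nm)) / 2
  b <- rowSums(nm) / p
  nm <- nm - outer(b, rep(1, p)) + outer(rep(1, p), b) # zero row sums
  diag(nm) <- 0

  names(g) <- names(m) <- parents
  dimnames(s) <- dimnames(nm) <- list(parents, parents)
  structure(
    list(p = p, r = r, mu = mu, g = g, m = m,
         g_f = g + m, g_m = g - m, s = s, nm = nm, block = block,
         sigma_e = sigma_e, self_depression = self_depression,
         seed = as.integer(seed), trait = trait, parents = parents),
    class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "Diallel simulation truth: p = %d, r = %d, mu = %.4g, sigma_e = %.4g\n",
    x$p, x$r, x$mu, x$sigma_e))
  cat(sprintf("effect spreads (sd): g %.3g, m %.3g, s %.3g, nm %.3g\n",
              stats::sd(x$g), stats::sd(x$m), stats::sd(x$s[upper.tri(x$s)]),
              stats::sd(x$nm[upper.tri(x$nm)])))
  invisible(x)
}

#' Noiseless entry-mean table implied by a simulation truth
#'
#' @param truth A `sim_truth` object.
#' @return A `cross_means` object with cell (i, j) equal to
#'   mu + g_fi + g_mj + s_ij + nm_ij (+ self_depression on the diagonal).
#' @export
noiseless_means <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  x <- truth$mu + outer(truth$g_f, truth$g_m, "+") + truth$s + truth$nm
  diag(x) <- diag(x) + truth$self_depression
  dimnames(x) <- list(truth$parents, truth$parents)
  new_cross_means(x, truth$trait, truth$r)
}

#' Simulate plot-level data from a diallel truth
#'
#' Plot value for (female i, male j, replication k) is
#' mu + block_k + g_fi + g_mj + s_ij + nm_ij (+ self_depression if i = j)
#' + Normal(0, sigma_e). The same seed always reproduces identical data.
#'
#' @param truth A `sim_truth` object.
#' @param seed Seed for the residual draws; defaults to `truth$seed` so
#'   repeated calls are reproducible.
#' @return A validated `diallel_data` object with p^2 * r records.
#' @export
simulate_diallel <- function(truth, seed = truth$seed) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(as.integer(seed))
  p <- truth$p; r <- truth$r
  grid <- expand.grid(rep = seq_len(r), male = seq_len(p),
                      female = seq_len(p))
  base <- truth$mu + truth$block[grid$rep] +
    truth$g_f[grid$female] + truth$g_m[grid$male] +
    truth$s[cbind(grid$female, grid$male)] +
    truth$nm[cbind(grid$female, grid$male)] +
    ifelse(grid$female == grid$male, truth$self_depression, 0)
  y <- base + stats::rnorm(nrow(grid), 0, truth$sigma_e)
  df <- data.frame(female = truth$parents[grid$female],
                   male = truth$parents[grid$male],
                   rep = grid$rep, stringsAsFactors = FALSE)
  df[[truth$trait]] <- y
  design <- diallel_design(truth$parents, r, truth$trait)
  as_diallel_data(df, design)
}

#' Monte-Carlo parameter-recovery study
#'
#' Repeatedly simulates a diallel from a fixed truth, runs the full
#' estimation pipeline on each draw, and summarizes how well effects and
#' variance components are recovered. The estimand of every quantity is
#' its value in the noiseless limit (the analysis of [noiseless_means()]),
#' which coincides with the generating effects whenever
#' `self_depression = 0`; variance-component truths are the corresponding
#' quadratic forms of the noiseless table plus `sigma_e^2` for the error.
#'
#' @param truth A `sim_truth` object (needs r >= 2 for a residual term).
#' @param n_sims Number of simulated trials (>= 1).
#' @param seed Seed governing the whole experiment.
#' @param alpha Significance level for the maternal / reciprocal F-test
#'   rejection rates.
#' @return Object of class `recovery_report`: list with `components`
#'   (data.frame: truth, mean estimate, bias, relative bias, RMSE per
#'   variance component), `effects` (data.frame: mean bias and RMSE per
#'   effect class), `reject` (named rejection rates of the Maternal,
#'   Non-Maternal and Reciprocal F-tests), `n_sims`, `alpha`.
#' @export
recovery_experiment <- function(truth, n_sims, seed = truth$seed,
                                alpha = 0.05) {
  stopifnot(inherits(truth, "sim_truth"), n_sims >= 1)
  if (truth$r < 2L) stop("recovery needs r >= 2 for a residual mean square")
  p <- truth$p; r <- truth$r
  tm <- noiseless_means(truth)
  true_ca <- combining_ability_anova(tm, ms_residual = 1, df_residual = 1,
                                     r = r)$table
  ms_of <- function(tab, src) tab$MS_mean[tab$source == src]
  true_comp <- c(
    var_gca = ms_of(true_ca, "GCA") / (2 * p),
    var_sca = ms_of(true_ca, "SCA"),
    var_rca = ms_of(true_ca, "Reciprocal") / 2,
    var_err = truth$sigma_e^2 / r)
  true_eff <- list(
    g = griffing_effects(tm)$g,
    g_f = partition_gca(tm)$g_f, g_m = partition_gca(tm)$g_m,
    m = maternal_from_margins(tm),
    s_adj = partition_sca(tm)$s_adj, rec = griffing_effects(tm)$rec)

  set.seed(as.integer(seed))
  sim_seeds <- sample.int(.Machine$integer.max, n_sims)
  comp_est <- matrix(NA_real_, n_sims, 4,
                     dimnames = list(NULL, names(true_comp)))
  eff_err <- lapply(true_eff, function(e) matrix(NA_real_, n_sims, length(e)))
  rej <- matrix(FALSE, n_sims, 3,
                dimnames = list(NULL, c("Maternal", "Non-Maternal", "Reciprocal")))
  for (i in seq_len(n_sims)) {
    d <- simulate_diallel(truth, seed = sim_seeds[i])
    mn <- entry_means(d, truth$trait)
    rb <- rcbd_anova(d, truth$trait)
    ca <- combining_ability_anova(mn, rb$ms_residual, rb$df_residual, r)
    comp_est[i, ] <- suppressWarnings(variance_components(ca, p, r))
    eff <- list(g = griffing_effects(mn)$g,
                g_f = partition_gca(mn)$g_f, g_m = partition_gca(mn)$g_m,
                m = maternal_from_margins(mn),
                s_adj = partition_sca(mn)$s_adj,
                rec = griffing_effects(mn)$rec)
    for (nm_ in names(true_eff))
      eff_err[[nm_]][i, ] <- as.numeric(eff[[nm_]]) - as.numeric(true_eff[[nm_]])
    pvals <- ca$table$p[match(colnames(rej), ca$table$source)]
    rej[i, ] <- pvals < alpha
  }
  est_mean <- colMeans(comp_est)
  components <- data.frame(
    component = names(true_comp),
    truth = unname(true_comp), estimate = unname(est_mean),
    bias = unname(est_mean - true_comp),
    rel_bias = unname(ifelse(true_comp > 0,
                             (est_mean - true_comp) / true_comp, NA)),
    rmse = unname(sqrt(colMeans(sweep(comp_est, 2, true_comp)^2))),
    stringsAsFactors = FALSE)
  effects <- data.frame(
    class = names(eff_err),
    bias = vapply(eff_err, function(e) mean(colMeans(e)), numeric(1)),
    rmse = vapply(eff_err, function(e) sqrt(mean(e^2)), numeric(1)),
    stringsAsFactors = FALSE)
  structure(
    list(components = components, effects = effects,
         reject = colMeans(rej), n_sims = n_sims, alpha = alpha,
         truth = truth),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, digits = 4, ...) {
  cat(sprintf("Recovery experiment: %d simulations, p = %d, r = %d\n",
              x$n_sims, x$truth$p, x$truth$r))
  cat("Variance components:\n")
  print(cbind(x$components[1], round(x$components[-1], digits)))
  cat("Effect classes (bias, RMSE):\n")
  print(cbind(x$effects[1], round(x$effects[-1], digits)))
  cat(sprintf("F-test rejection rates at alpha = %.3g:\n", x$alpha))
  print(round(x$reject, digits))
  invisible(x)
}
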