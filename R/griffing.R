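#' Randomized complete block ANOVA of diallel plot data
#'
#' Two-way decomposition of the plot observations of one trait into
#' replications (blocks, r - 1 df), treatments (the p^2 diallel entries,
#' p^2 - 1 df) and residual ((p^2 - 1)(r - 1) df). The residual mean
#' square is the error term for every downstream combining-ability test
#' (Model I, fixed effects).
#'
#' @param data A `diallel_data` object.
#' @param trait Trait name.
#' @return List of class `rcbd_anova` with `table` (data.frame: source,
#'   df, SS, MS, F, p), `ms_residual`, `df_residual`, `grand_mean`, `cv`
#'   (coefficient of variation, percent) and `sem` (standard error of an
#'   entry mean).
#' @export
rcbd_anova <- function(data, trait) {
  stopifnot(inherits(data, "diallel_data"))
  des <- data$design
  if (!trait %in% des$traits) stop("unknown trait '", trait, "'")
  r <- des$n_reps
  if (r < 2L)
    stop("RCBD residual needs at least 2 replications; got r = ", r)
  p2 <- des$n_parents^2
  y <- data$plots[[trait]]
  entry <- paste(data$plots$female, data$plots$male, sep = "\r")
  block <- data$plots$rep
  gm <- mean(y)

  ss_total <- sum((y - gm)^2)
  rep_means <- tapply(y, block, mean)
  ss_rep <- p2 * sum((rep_means - gm)^2)
  ent_means <- tapply(y, entry, mean)
  ss_treat <- r * sum((ent_means - gm)^2)
  ss_resid <- ss_total - ss_rep - ss_treat

  df_rep <- r - 1L
  df_treat <- p2 - 1L
  df_resid <- df_rep * df_treat
  ms <- c(ss_rep / df_rep, ss_treat / df_treat, ss_resid / df_resid)
  f <- c(ms[1] / ms[3], ms[2] / ms[3], NA)
  pv <- c(stats::pf(f[1], df_rep, df_resid, lower.tail = FALSE),
          stats::pf(f[2], df_treat, df_resid, lower.tail = FALSE), NA)
  tab <- data.frame(
    source = c("Replications", "Treatments", "Residual"),
    df = c(df_rep, df_treat, df_resid),
    SS = c(ss_rep, ss_treat, ss_resid),
    MS = ms, F = f, p = pv,
    stringsAsFactors = FALSE)
  structure(
    list(trait = trait, table = tab,
         ms_residual = ms[3], df_residual = df_resid, grand_mean = gm,
         cv = 100 * sqrt(ms[3]) / gm, sem = sqrt(ms[3] / r)),
    class = "rcbd_anova")
}

#' Griffing Method 1 combining-ability effects
#'
#' Closed-form Model I estimates from the p x p entry-mean table (n = p
#' parents; totals over entry means):
#' \deqn{\hat g_i = \frac{1}{2n}(x_{i.} + x_{.i}) - \frac{1}{n^2} x_{..}}
#' \deqn{\hat s_{ij} = \tfrac12 (x_{ij} + x_{ji})
#'   - \frac{1}{2n}(x_{i.} + x_{.i} + x_{j.} + x_{.j}) + \frac{1}{n^2} x_{..}}
#' \deqn{\hat r_{ij} = \tfrac12 (x_{ij} - x_{ji})}
#' with \eqn{\hat\mu = x_{..}/n^2}. The GCA effects sum to zero, the SCA
#' matrix is symmetric (diagonal = parental SCA of the selfs) and the
#' reciprocal matrix is antisymmetric with zero diagonal, so
#' \eqn{\hat\mu + \hat g_i + \hat g_j + \hat s_{ij} + \hat r_{ij}}
#' reconstructs every cell \eqn{x_{ij}} exactly.
#'
#' @param means A `cross_means` object.
#' @param ms_residual Optional plot-basis residual mean square from
#'   [rcbd_anova()]; when supplied, standard errors and two-sided
#'   normal-deviate significance stars are attached.
#' @param r Replications behind each entry mean; defaults to
#'   `means$n_reps`.
#' @param alpha Two significance levels for the stars.
#' @return Object of class `griffing_effects`: list with `mu`, `g`
#'   (length-p named vector), `s` (p x p symmetric), `rec` (p x p
#'   antisymmetric), and when `ms_residual` is given `se` (per-class
#'   standard errors) plus `sig` (star labels for g, s, rec).
#' @export
griffing_effects <- function(means, ms_residual = NULL, r = NULL,
                             alpha = c(0.05, 0.01)) {
  stopifnot(inherits(means, "cross_means"))
  p <- means$n_parents
  x <- means$x
  rt <- means$row_totals
  ct <- means$col_totals
  gt <- means$grand_total

  mu <- gt / p^2
  g <- (rt + ct) / (2 * p) - gt / p^2
  marg <- outer(rt + ct, rt + ct, "+") # (x_i. + x_.i) + (x_j. + x_.j)
  s <- (x + t(x)) / 2 - marg / (2 * p) + gt / p^2
  rec <- (x - t(x)) / 2
  names(g) <- means$parents
  dimnames(s) <- dimnames(rec) <- dimnames(x)

  out <- list(trait = means$trait, mu = mu, g = g, s = s, rec = rec,
              n_parents = p, parents = means$parents)
  if (!is.null(ms_residual)) {
    if (is.null(r)) r <- means$n_reps
    se <- effect_standard_errors(ms_residual, r, p)
    out$se <- se
    out$sig <- list(
      g = stars_for(g / se["gca"], alpha),
      s = matrix(stars_for(ifelse(row(s) == col(s), s / se["sca_self"],
                                  s / se["sca"]), alpha), p, p,
                 dimnames = dimnames(s)),
      rec = matrix(stars_for(rec / se["reciprocal"], alpha), p, p,
                   dimnames = dimnames(rec)))
    out$sig$rec[row(out$sig$rec) == col(out$sig$rec)] <- ""
  }
  structure(out, class = "griffing_effects")
}

#' @export
print.griffing_effects <- function(x, digits = 3, ...) {
  cat(sprintf("Griffing Method 1 effects for trait '%s' (mu = %.4g)\n",
              x$trait, x$mu))
  cat("GCA effects g_i:\n")
  print(round(x$g, digits))
  cat("SCA effects s_ij (symmetric; diagonal = selfs):\n")
  print(round(x$s, digits))
  cat("Reciprocal effects r_ij (antisymmetric):\n")
  print(round(x$rec, digits))
  invisible(x)
}

#' Combining-ability analysis of variance
#'
#' Partitions the variation among the p^2 entry means into general
#' combining ability (GCA), specific combining ability (SCA) and
#' reciprocal differences, with the reciprocal sum of squares further
#' split into a maternal component (marginal female-vs-male differences
#' of each parent) and a non-maternal remainder:
#' \deqn{SS_{GCA} = \frac{1}{2p}\sum_i (x_{i.}+x_{.i})^2 - \frac{2}{p^2}x_{..}^2}
#' \deqn{SS_{Rec} = \tfrac12 \sum_{i<j} (x_{ij}-x_{ji})^2, \quad
#'       SS_{Mat} = \frac{1}{2p}\sum_i (x_{i.}-x_{.i})^2}
#' \deqn{SS_{SCA} = SS_{Treat} - SS_{GCA} - SS_{Rec}, \quad
#'       SS_{NonMat} = SS_{Rec} - SS_{Mat}}
#' These are orthogonal projections of the entry-mean table, so both the
#' SS and the df add up to the treatment line. Every mean square is
#' F-tested against the plot residual divided by r (Model I, single error
#' term). Sums of squares and mean squares are reported on the entry-mean
#' basis and, multiplied by r, on the plot basis.
#'
#' @param means A `cross_means` object.
#' @param ms_residual Plot-basis residual mean square (must be > 0).
#' @param df_residual Residual degrees of freedom for the F p-values.
#' @param r Replications behind each entry mean; defaults to
#'   `means$n_reps`.
#' @return Object of class `ca_anova`: data.frame with columns source,
#'   df, SS_mean, MS_mean, SS_plot, MS_plot, F, p; rows Treatments, GCA,
#'   SCA, Reciprocal, Maternal, Non-Maternal, Residual.
#' @export
combining_ability_anova <- function(means, ms_residual, df_residual,
                                    r = NULL) {
  stopifnot(inherits(means, "cross_means"))
  if (!is.numeric(ms_residual) || length(ms_residual) != 1L || ms_residual <= 0)
    stop("'ms_residual' must be a single positive number")
  if (is.null(r)) r <- means$n_reps
  p <- means$n_parents
  x <- means$x
  rt <- means$row_totals
  ct <- means$col_totals
  gt <- means$grand_total

  ss_treat <- sum(x^2) - gt^2 / p^2
  ss_gca <- sum((rt + ct)^2) / (2 * p) - 2 * gt^2 / p^2
  d <- x - t(x)
  ss_rec <- sum(d^2) / 4 # == (1/2) * sum_{i<j} (x_ij - x_ji)^2
  ss_mat <- sum((rt - ct)^2) / (2 * p)
  ss_sca <- ss_treat - ss_gca - ss_rec
  ss_nonmat <- ss_rec - ss_mat

  df <- c(Treatments = p^2 - 1L, GCA = p - 1L,
          SCA = p * (p + 1L) / 2 - p, Reciprocal = p * (p - 1L) / 2,
          Maternal = p - 1L,
          `Non-Maternal` = p * (p - 1L) / 2 - (p - 1L))
  ss <- c(ss_treat, ss_gca, ss_sca, ss_rec, ss_mat, ss_nonmat)
  ms <- ss / df
  err_mean <- ms_residual / r
  f <- ms / err_mean
  pv <- stats::pf(f, df, df_residual, lower.tail = FALSE)
  tab <- data.frame(
    source = c(names(df), "Residual"),
    df = c(df, df_residual),
    SS_mean = c(ss, err_mean * df_residual),
    MS_mean = c(ms, err_mean),
    SS_plot = c(ss * r, ms_residual * df_residual),
    MS_plot = c(ms * r, ms_residual),
    F = c(f, NA), p = c(pv, NA),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(trait = means$trait, table = tab, n_parents = p, r = r),
            class = "ca_anova")
}

#' @export
print.ca_anova <- function(x, digits = 4, ...) {
  cat(sprintf("Combining-ability ANOVA for trait '%s' (p = %d, r = %d)\n",
              x$trait, x$n_parents, x$r))
  tab <- x$table
  sig <- ifelse(is.na(tab$p), "",
                ifelse(tab$p < 0.01, "**", ifelse(tab$p < 0.05, "*", "")))
  print(cbind(tab[1], round(tab[2:8], digits), sig = sig))
  invisible(x)
}

#' Standard errors of Griffing Method 1 effects
#'
#' Every combining-ability effect is a fixed linear functional of the p^2
#' independent entry means, each with variance MS_residual / r. The
#' standard error of an effect class is therefore the Euclidean norm of
#' its coefficient pattern times the entry-mean standard deviation; the
#' coefficient patterns are built explicitly, which reproduces Griffing's
#' (1956) Method 1 variance formulas without transcribing them.
#'
#' @param ms_residual Plot-basis residual mean square (>= 0).
#' @param r Number of replications.
#' @param p Number of parents.
#' @return Named numeric vector of standard errors for classes `mu`,
#'   `gca` (g_i), `gca_part` (g_fi or g_mi), `maternal` (m_i), `sca`
#'   (Griffing s_ij, i != j), `sca_self` (s_ii), `sca_adj` (directional
#'   adjusted s_ij) and `reciprocal` (r_ij), plus attribute
#'   `"var_entry_mean"`.
#' @export
effect_standard_errors <- function(ms_residual, r, p) {
  if (ms_residual < 0) stop("'ms_residual' must be non-negative")
  if (p < 3) stop("'p' must be >= 3")
  var_mean <- ms_residual / r
  J <- matrix(1 / p^2, p, p)
  rowm <- function(i) {m <- matrix(0, p, p); m[i, ] <- 1; m}
  colm <- function(j) {m <- matrix(0, p, p); m[, j] <- 1; m}
  cell <- function(i, j) {m <- matrix(0, p, p); m[i, j] <- 1; m}

  coefs <- list(
    mu = J,
    gca = (rowm(1) + colm(1)) / (2 * p) - J,
    gca_part = rowm(1) / p - J,
    maternal = (rowm(1) - colm(1)) / (2 * p),
    sca = (cell(1, 2) + cell(2, 1)) / 2 -
      (rowm(1) + colm(1) + rowm(2) + colm(2)) / (2 * p) + J,
    sca_self = cell(1, 1) - (rowm(1) + colm(1)) / p + J,
    sca_adj = cell(1, 2) -
      (rowm(1) + colm(1) + rowm(2) + colm(2)) / (2 * p) + J,
    reciprocal = (cell(1, 2) - cell(2, 1)) / 2)
  se <- vapply(coefs, function(C) sqrt(var_mean * sum(C^2)), numeric(1))
  attr(se, "var_entry_mean") <- var_mean
  se
}

# Two-sided normal-deviate stars: "**" at alpha[2], "*" at alpha[1].
# z may contain NA (no error estimate) -> "".
stars_for <- function(z, alpha = c(0.05, 0.01)) {
  pv <- 2 * stats::pnorm(-abs(z))
  out <- ifelse(is.na(pv), "",
                ifelse(pv < min(alpha), "**",
                       ifelse(pv < max(alpha), "*", "")))
  if (is.matrix(z)) dim(out) <- dim(z)
  out
}
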