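#' Partition GCA into female-side and male-side components
#'
#' Griffing's single GCA effect per parent averages its behaviour as
#' female and as male. The modified partition estimates the two roles
#' separately from the row and column margins of the entry-mean table
#' (n = p parents):
#' \deqn{\hat g_{fi} = \frac{1}{n} x_{i.} - \frac{1}{n^2} x_{..}, \qquad
#'       \hat g_{mi} = \frac{1}{n} x_{.i} - \frac{1}{n^2} x_{..}}
#' Their average recovers Griffing's \eqn{\hat g_i} and half their
#' difference is the parent's maternal effect \eqn{\hat m_i}; all four
#' vectors sum to zero over parents.
#'
#' @param means A `cross_means` object.
#' @return List with named length-p vectors `g_f`, `g_m`, `g`, `m`.
#' @seealso [maternal_from_margins()], [partition_sca()],
#'   [partitioned_effects()]
#' @export
partition_gca <- function(means) {
  stopifnot(inherits(means, "cross_means"))
  p <- means$n_parents
  g_f <- means$row_totals / p - means$grand_total / p^2
  g_m <- means$col_totals / p - means$grand_total / p^2
  names(g_f) <- names(g_m) <- means$parents
  list(g_f = g_f, g_m = g_m,
       g = gca_from_partition(g_f, g_m),
       m = maternal_from_partition(g_f, g_m))
}

#' Partition SCA into straight and reciprocal cross components
#'
#' The adjusted SCA of the ordered cross (female i, male j) keeps the
#' straight and reciprocal cells apart instead of averaging them:
#' \deqn{\hat s_{ij} = x_{ij}
#'   - \frac{1}{2p}(x_{i.} + x_{.i} + x_{j.} + x_{.j}) + \frac{1}{p^2} x_{..}}
#' so that \eqn{(\hat s_{ij} + \hat s_{ji})/2} equals Griffing's SCA of
#' the pair and \eqn{r_{ij} = (\hat s_{ij} - \hat s_{ji})/2 =
#' (x_{ij} - x_{ji})/2} is the directional reciprocal effect
#' (\eqn{r_{ji} = -r_{ij}}). Diagonal cells carry the parental SCA of the
#' selfs, which have no reciprocal (`r_adj` diagonal is 0).
#'
#' @param means A `cross_means` object.
#' @return List with p x p matrices `s_adj` (directional adjusted SCA)
#'   and `r_adj` (antisymmetric reciprocal effects).
#' @export
partition_sca <- function(means) {
  stopifnot(inherits(means, "cross_means"))
  p <- means$n_parents
  marg <- outer(means$row_totals + means$col_totals,
                means$row_totals + means$col_totals, "+")
  s_adj <- means$x - marg / (2 * p) + means$grand_total / p^2
  r_adj <- (s_adj - t(s_adj)) / 2
  dimnames(s_adj) <- dimnames(r_adj) <- dimnames(means$x)
  list(s_adj = s_adj, r_adj = r_adj)
}

#' Maternal effects straight from the entry-mean margins
#'
#' Equivalent closed form \eqn{\hat m_i = (x_{i.} - x_{.i}) / (2n)}:
#' the marginal female-vs-male contrast of each parent. Algebraically
#' identical to `(g_fi - g_mi) / 2` from [partition_gca()]; both are
#' provided so the equivalence can be verified on data.
#'
#' @param means A `cross_means` object.
#' @return Named length-p vector of maternal effects (sums to zero).
#' @export
maternal_from_margins <- function(means) {
  stopifnot(inherits(means, "cross_means"))
  m <- (means$row_totals - means$col_totals) / (2 * means$n_parents)
  names(m) <- means$parents
  m
}

#' Recombine partitioned GCA components
#'
#' The identities linking the partitioned female/male GCA components to
#' Griffing's GCA and to the maternal effect:
#' `gca_from_partition()` returns \eqn{\hat g_i = (\hat g_{fi} + \hat
#' g_{mi})/2}; `maternal_from_partition()` returns \eqn{\hat m_i = (\hat
#' g_{fi} - \hat g_{mi})/2}. Vectorized; useful for recomputing one
#' quantity from a published table of the other two.
#'
#' @param g_f Female-side GCA component(s) g_fi.
#' @param g_m Male-side GCA component(s) g_mi.
#' @return Numeric vector of the same length.
#' @export
gca_from_partition <- function(g_f, g_m) (g_f + g_m) / 2

#' @rdname gca_from_partition
#' @export
maternal_from_partition <- function(g_f, g_m) (g_f - g_m) / 2

#' Recombine partitioned SCA components
#'
#' `sca_from_partition()` averages the adjusted straight and reciprocal
#' SCA of a cross back into Griffing's single SCA,
#' \eqn{(\hat s_{ij} + \hat s_{ji})/2}; `reciprocal_from_partition()`
#' returns the directional reciprocal effect
#' \eqn{r_{ij} = (\hat s_{ij} - \hat s_{ji})/2}. Vectorized.
#'
#' @param s_ij Adjusted SCA of the straight cross (female i, male j).
#' @param s_ji Adjusted SCA of the reciprocal cross (female j, male i).
#' @return Numeric vector of the same length.
#' @export
sca_from_partition <- function(s_ij, s_ji) (s_ij + s_ji) / 2

#' @rdname sca_from_partition
#' @export
reciprocal_from_partition <- function(s_ij, s_ji) (s_ij - s_ji) / 2

#' Full modified-partition effect set with standard errors
#'
#' Runs [partition_gca()], [partition_sca()] and
#' [maternal_from_margins()] on one entry-mean table and, when the
#' residual mean square is supplied, attaches per-class standard errors
#' and two-sided normal-deviate significance stars.
#'
#' @inheritParams griffing_effects
#' @return Object of class `partitioned_effects`: list with `g_f`, `g_m`,
#'   `g`, `m` (length-p vectors), `s_adj`, `r_adj` (p x p matrices), and
#'   optionally `se` and `sig`.
#' @export
partitioned_effects <- function(means, ms_residual = NULL, r = NULL,
                                alpha = c(0.05, 0.01)) {
  stopifnot(inherits(means, "cross_means"))
  gp <- partition_gca(means)
  sp <- partition_sca(means)
  out <- c(list(trait = means$trait, n_parents = means$n_parents,
                parents = means$parents, mu = means$grand_total / means$n_parents^2),
           gp, sp)
  if (!is.null(ms_residual)) {
    if (is.null(r)) r <- means$n_reps
    se <- effect_standard_errors(ms_residual, r, means$n_parents)
    out$se <- se
    p <- means$n_parents
    sig_sadj <- matrix(stars_for(ifelse(row(sp$s_adj) == col(sp$s_adj),
                                        sp$s_adj / se["sca_self"],
                                        sp$s_adj / se["sca_adj"]), alpha),
                       p, p, dimnames = dimnames(sp$s_adj))
    sig_radj <- matrix(stars_for(sp$r_adj / se["reciprocal"], alpha),
                       p, p, dimnames = dimnames(sp$r_adj))
    diag(sig_radj) <- ""
    out$sig <- list(
      g_f = stars_for(gp$g_f / se["gca_part"], alpha),
      g_m = stars_for(gp$g_m / se["gca_part"], alpha),
      g = stars_for(gp$g / se["gca"], alpha),
      m = stars_for(gp$m / se["maternal"], alpha),
      s_adj = sig_sadj, r_adj = sig_radj)
  }
  structure(out, class = "partitioned_effects")
}

#' @export
print.partitioned_effects <- function(x, digits = 3, ...) {
  cat(sprintf("Partitioned combining-ability effects for trait '%s'\n", x$trait))
  tab <- rbind(g_mi = x$g_m, g_fi = x$g_f, g_i = x$g, m_i = x$m)
  print(round(tab, digits))
  cat("Adjusted SCA s_ij (rows = female, cols = male; diagonal = selfs):\n")
  print(round(x$s_adj, digits))
  cat("Reciprocal effects r_ij = (s_ij - s_ji)/2:\n")
  print(round(x$r_adj, digits))
  invisible(x)
}
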