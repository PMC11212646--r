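#' Mid-parent and better-parent heterosis
#'
#' For every ordered hybrid (female i, male j, i != j) with F1 entry mean
#' x_ij and parental self means x_ii, x_jj:
#' \deqn{MPH = 100\,\frac{x_{ij} - MP}{MP}, \quad MP = (x_{ii}+x_{jj})/2}
#' \deqn{BPH = 100\,\frac{x_{ij} - BP}{BP}}
#' where BP is the parental mean favoured by the trait's direction: the
#' larger self mean when larger values are better (`direction = "max"`,
#' e.g. yield), the smaller when smaller values are better
#' (`direction = "min"`, e.g. days to flowering). Crosses whose MP or BP
#' is zero get `NA` heterosis and are flagged.
#'
#' @param means A `cross_means` object (diagonal = parental selfs).
#' @param direction `"max"` (larger is better) or `"min"`.
#' @return Object of class `heterosis_table`: data.frame with one row per
#'   ordered hybrid: female, male, f1, mp, bp, mph, bph, undefined.
#' @export
heterosis <- function(means, direction = c("max", "min")) {
  stopifnot(inherits(means, "cross_means"))
  direction <- match.arg(direction)
  p <- means$n_parents
  x <- means$x
  selfs <- diag(x)
  idx <- which(row(x) != col(x), arr.ind = TRUE)
  f1 <- x[idx]
  pi <- selfs[idx[, 1]]
  pj <- selfs[idx[, 2]]
  mp <- (pi + pj) / 2
  bp <- if (direction == "max") pmax(pi, pj) else pmin(pi, pj)
  mph <- ifelse(mp == 0, NA_real_, 100 * (f1 - mp) / mp)
  bph <- ifelse(bp == 0, NA_real_, 100 * (f1 - bp) / bp)
  out <- data.frame(
    female = means$parents[idx[, 1]], male = means$parents[idx[, 2]],
    f1 = f1, mp = mp, bp = bp, mph = mph, bph = bph,
    undefined = mp == 0 | bp == 0, stringsAsFactors = FALSE)
  ord <- order(idx[, 1], idx[, 2])
  out <- out[ord, ]
  rownames(out) <- NULL
  structure(out, class = c("heterosis_table", "data.frame"),
            trait = means$trait, direction = direction)
}

#' Correlations between combining-ability effects, hybrid performance and
#' heterosis
#'
#' Pearson correlations, over the ordered off-diagonal hybrids, between
#' each response series (F1 entry mean, mid-parent heterosis, better-
#' parent heterosis) and each predictor series derived from the
#' combining-ability analysis: Griffing's SCA \eqn{\hat s_{ij}}, the
#' adjusted (directional) SCA, Griffing's SGCA \eqn{\hat g_i + \hat g_j},
#' and the adjusted SGCA \eqn{\hat g_{fi} + \hat g_{mj}} (female component
#' of the female parent plus male component of the male parent — the only
#' pairing that uses the partition's directional information).
#' Significance stars come from the two-sided t-test of each coefficient.
#'
#' @param griffing A `griffing_effects` object.
#' @param partitioned A `partitioned_effects` object for the same trait.
#' @param het A `heterosis_table` from [heterosis()].
#' @param crosses `"ordered"` correlates over all p(p-1) ordered hybrids
#'   (straight and reciprocal as separate observations); `"straight"`
#'   restricts to the p(p-1)/2 crosses with female index < male index.
#' @param alpha Two significance levels for the stars.
#' @return Object of class `effect_correlations`: data.frame with columns
#'   response, predictor, r, n, p_value, sig.
#' @export
effect_performance_correlations <- function(griffing, partitioned, het,
                                            crosses = c("ordered", "straight"),
                                            alpha = c(0.05, 0.01)) {
  stopifnot(inherits(griffing, "griffing_effects"),
            inherits(partitioned, "partitioned_effects"),
            inherits(het, "heterosis_table"))
  crosses <- match.arg(crosses)
  parents <- griffing$parents
  fi <- match(het$female, parents)
  mi <- match(het$male, parents)
  keep <- rep(TRUE, nrow(het))
  if (crosses == "straight") keep <- fi < mi
  fi <- fi[keep]; mi <- mi[keep]; hh <- het[keep, ]

  pred <- list(
    griffing_sca = griffing$s[cbind(fi, mi)],
    adjusted_sca = partitioned$s_adj[cbind(fi, mi)],
    griffing_sgca = griffing$g[fi] + griffing$g[mi],
    adjusted_sgca = partitioned$g_f[fi] + partitioned$g_m[mi])
  resp <- list(mean = hh$f1, mph = hh$mph, bph = hh$bph)

  rows <- list()
  for (rn in names(resp)) for (pn in names(pred)) {
    xx <- resp[[rn]]; yy <- pred[[pn]]
    ok <- stats::complete.cases(xx, yy)
    n <- sum(ok)
    if (n < 3 || stats::sd(xx[ok]) == 0 || stats::sd(yy[ok]) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        response = rn, predictor = pn, r = NA_real_, n = n,
        p_value = NA_real_, sig = "", stringsAsFactors = FALSE)
      next
    }
    ct <- stats::cor.test(xx[ok], yy[ok], method = "pearson")
    pv <- ct$p.value
    rows[[length(rows) + 1L]] <- data.frame(
      response = rn, predictor = pn, r = unname(ct$estimate), n = n,
      p_value = pv,
      sig = if (is.na(pv)) "" else if (pv < min(alpha)) "**"
            else if (pv < max(alpha)) "*" else "",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("effect_correlations", "data.frame"),
            trait = griffing$trait, crosses = crosses)
}
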