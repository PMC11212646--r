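#' Method-of-moments variance components from the combining-ability ANOVA
#'
#' Equates the entry-mean-basis mean squares to their expectations under
#' the Method 1 model and solves:
#' \deqn{\hat\sigma^2_e = MS_{resid}/r, \quad
#'       \hat\sigma^2_{rca} = (MS_{rec} - \hat\sigma^2_e)/2, \quad
#'       \hat\sigma^2_{gca} = (MS_{gca} - \hat\sigma^2_e)/(2p), \quad
#'       \hat\sigma^2_{sca} = MS_{sca} - \hat\sigma^2_e}
#' where all mean squares are on the entry-mean basis (plot-basis MS
#' divided by r). Negative estimates are truncated to zero and flagged.
#' The reciprocal estimator is equivalently
#' \eqn{(MS_{rec}^{plot} - MS_{resid}^{plot}) / (2r)}.
#'
#' @param anova A `ca_anova` object from [combining_ability_anova()], or a
#'   data.frame with columns `source` and `MS_mean` containing rows GCA,
#'   SCA, Reciprocal and Residual.
#' @param p Number of parents.
#' @param r Number of replications.
#' @return Named numeric vector `c(var_gca, var_sca, var_rca, var_err)`
#'   with logical attribute `"truncated"` marking components clipped at 0.
#' @export
variance_components <- function(anova, p, r) {
  tab <- if (inherits(anova, "ca_anova")) anova$table else as.data.frame(anova)
  need <- c("GCA", "SCA", "Reciprocal", "Residual")
  idx <- match(need, tab$source)
  if (anyNA(idx))
    stop("ANOVA table lacks row(s): ", paste(need[is.na(idx)], collapse = ", "))
  ms <- tab$MS_mean[idx]
  names(ms) <- need
  s2e <- ms["Residual"] # already on the entry-mean basis (MS_resid / r)
  raw <- c(var_gca = unname((ms["GCA"] - s2e) / (2 * p)),
           var_sca = unname(ms["SCA"] - s2e),
           var_rca = unname((ms["Reciprocal"] - s2e) / 2),
           var_err = unname(s2e))
  truncated <- raw < 0
  if (any(truncated))
    warning("negative variance component(s) truncated to 0: ",
            paste(names(raw)[truncated], collapse = ", "))
  out <- pmax(raw, 0)
  attr(out, "truncated") <- truncated
  out
}

#' Genetic parameters derived from variance components
#'
#' Applies the fixed definitions linking the combining-ability components
#' to quantitative-genetic quantities:
#' \deqn{\sigma^2_A = 2\sigma^2_{gca}, \quad \sigma^2_D = \sigma^2_{sca},
#'       \quad \sigma^2_P = \sigma^2_A + \sigma^2_D + \sigma^2_{rca} +
#'       \sigma^2_e / r}
#' \deqn{H^2_{bs} = 100\,(\sigma^2_A+\sigma^2_D)/\sigma^2_P, \quad
#'       h^2_{ns} = 100\,\sigma^2_A/\sigma^2_P, \quad
#'       \text{Baker} = \frac{2\sigma^2_{gca}}{2\sigma^2_{gca}+\sigma^2_{sca}}}
#' Heritabilities are percentages. With all genetic components zero,
#' Baker's ratio is reported as 0; with `var_P` zero both heritabilities
#' are `NA`.
#'
#' @param components Named numeric vector or list with elements `var_gca`,
#'   `var_sca`, `var_rca`, `var_err` (as from [variance_components()]).
#' @param r Number of replications behind the entry means.
#' @return Object of class `genetic_params`: named list with the four
#'   input components plus `var_A`, `var_D`, `var_P`, `ratio_AD`, `H2`,
#'   `h2`, `baker`, `n_reps`.
#' @export
derived_genetics <- function(components, r) {
  components <- as.list(components)
  need <- c("var_gca", "var_sca", "var_rca", "var_err")
  if (!all(need %in% names(components)))
    stop("'components' needs elements ", paste(need, collapse = ", "))
  v <- lapply(components[need], as.numeric)
  if (any(unlist(v) < 0)) stop("variance components must be non-negative")
  var_A <- 2 * v$var_gca
  var_D <- v$var_sca
  var_P <- var_A + var_D + v$var_rca + v$var_err / r
  H2 <- if (var_P > 0) 100 * (var_A + var_D) / var_P else NA_real_
  h2 <- if (var_P > 0) 100 * var_A / var_P else NA_real_
  denom <- 2 * v$var_gca + v$var_sca
  baker <- if (denom > 0) 2 * v$var_gca / denom else 0
  ratio_AD <- if (var_D > 0) var_A / var_D else NA_real_
  structure(
    c(v, list(var_A = var_A, var_D = var_D, var_P = var_P,
              ratio_AD = ratio_AD, H2 = H2, h2 = h2, baker = baker,
              n_reps = r)),
    class = "genetic_params")
}

#' @export
print.genetic_params <- function(x, digits = 4, ...) {
  v <- unlist(x[c("var_gca", "var_sca", "var_rca", "var_P", "var_err",
                  "var_A", "var_D", "ratio_AD", "H2", "h2", "baker")])
  print(round(v, digits))
  invisible(x)
}

#' @rdname genetic_params_df
#' @keywords internal
#' @noRd
genetics_as_row <- function(gp, trait) {
  data.frame(trait = trait,
             var_gca = gp$var_gca, var_sca = gp$var_sca, var_rca = gp$var_rca,
             var_P = gp$var_P, var_err = gp$var_err, var_A = gp$var_A,
             var_D = gp$var_D, ratio_AD = gp$ratio_AD, H2 = gp$H2,
             h2 = gp$h2, baker = gp$baker, stringsAsFactors = FALSE)
}
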