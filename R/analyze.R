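#' Run the full combining-ability pipeline on every trait
#'
#' For each trait: entry means -> RCBD ANOVA -> combining-ability ANOVA
#' (with the maternal / non-maternal split) -> Griffing effects ->
#' partitioned effects -> variance components and derived genetic
#' parameters -> heterosis -> effect/performance correlations.
#'
#' @param data A `diallel_data` object.
#' @param directions Optional named character vector mapping trait names
#'   to `"max"` (larger is better, the default) or `"min"` (smaller is
#'   better, e.g. days to flowering); used by the better-parent rule.
#' @param alpha Two significance levels for all stars.
#' @param crosses Passed to [effect_performance_correlations()].
#' @return Object of class `diallel_analysis`: list with `design`,
#'   `directions`, `alpha` and `traits`, a named list holding per trait:
#'   `means`, `rcbd`, `anova`, `griffing`, `partitioned`, `components`,
#'   `genetics`, `heterosis`, `correlations`.
#' @examples
#' d <- simulate_diallel(sim_truth(p = 4, r = 2, seed = 7))
#' fit <- diallel_analyze(d)
#' fit$traits$trait$genetics
#' @export
diallel_analyze <- function(data, directions = NULL,
                            alpha = c(0.05, 0.01),
                            crosses = c("ordered", "straight")) {
  stopifnot(inherits(data, "diallel_data"))
  crosses <- match.arg(crosses)
  if (any(alpha <= 0 | alpha >= 1)) stop("'alpha' levels must lie in (0, 1)")
  des <- data$design
  bad_dir <- setdiff(names(directions), des$traits)
  if (length(bad_dir))
    stop("directions given for unknown trait(s): ",
         paste(bad_dir, collapse = ", "))
  res <- list()
  for (tr in des$traits) {
    mn <- entry_means(data, tr)
    rb <- rcbd_anova(data, tr)
    ca <- combining_ability_anova(mn, rb$ms_residual, rb$df_residual,
                                  des$n_reps)
    gr <- griffing_effects(mn, rb$ms_residual, des$n_reps, alpha)
    pe <- partitioned_effects(mn, rb$ms_residual, des$n_reps, alpha)
    comp <- suppressWarnings(variance_components(ca, des$n_parents,
                                                 des$n_reps))
    gen <- derived_genetics(comp, des$n_reps)
    dir <- if (!is.null(directions) && tr %in% names(directions))
      directions[[tr]] else "max"
    het <- heterosis(mn, dir)
    corr <- effect_performance_correlations(gr, pe, het, crosses, alpha)
    res[[tr]] <- list(means = mn, rcbd = rb, anova = ca, griffing = gr,
                      partitioned = pe, components = comp, genetics = gen,
                      heterosis = het, correlations = corr)
  }
  structure(list(design = des, directions = directions, alpha = alpha,
                 crosses = crosses, traits = res),
            class = "diallel_analysis")
}

#' @export
print.diallel_analysis <- function(x, ...) {
  cat(sprintf("Diallel combining-ability analysis: %d parents, %d reps, %d trait(s)\n",
              x$design$n_parents, x$design$n_reps, length(x$traits)))
  for (tr in names(x$traits)) {
    g <- x$traits[[tr]]$genetics
    cat(sprintf(" %s: H2 = %.2f%%, h2 = %.2f%%, Baker = %.2f\n",
                tr, g$H2, g$h2, g$baker))
  }
  invisible(x)
}

round_df <- function(df, digits = 2) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Write the analysis report tables
#'
#' Serializes a [diallel_analyze()] result as one CSV per report table
#' (values rounded to 2 decimals, mirroring how such tables are usually
#' published) plus a machine-readable JSON companion at full precision
#' and a metadata JSON. Tables: `anova.csv` (RCBD + combining-ability
#' lines per trait, both bases), `gca_partition.csv` (three-row
#' g_mi/g_fi/g_i block plus maternal row per trait, parents in columns),
#' `maternal.csv` (parents x traits), `sca_pairs.csv` (per unordered
#' cross: Griffing SCA, adjusted straight/reciprocal SCA), `reciprocal.csv`
#' (r_ij for i < j), `genetic_params.csv`, `heterosis.csv`,
#' `correlations.csv`, `standard_errors.csv`, `report_values.json`,
#' `metadata.json`.
#'
#' @param analysis A `diallel_analysis` object.
#' @param out_dir Output directory (created if absent).
#' @param digits Rounding for the human-readable CSVs.
#' @return Invisibly, the character vector of files written.
#' @export
write_report <- function(analysis, out_dir, digits = 2) {
  stopifnot(inherits(analysis, "diallel_analysis"))
  if (!length(analysis$traits)) stop("analysis contains no traits")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  des <- analysis$design
  parents <- des$parents
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(round_df(df, digits), path, row.names = FALSE)
    files <<- c(files, path)
  }

  anova_rows <- list(); gca_rows <- list(); mat <- list(); sca_rows <- list()
  rec_rows <- list(); gen_rows <- list(); het_rows <- list(); cor_rows <- list()
  se_rows <- list()
  for (tr in names(analysis$traits)) {
    a <- analysis$traits[[tr]]
    rt <- a$rcbd$table
    rcbd_part <- data.frame(trait = tr, source = rt$source, df = rt$df,
                            SS_mean = rt$SS / des$n_reps,
                            MS_mean = rt$MS / des$n_reps,
                            SS_plot = rt$SS, MS_plot = rt$MS,
                            F = rt$F, p = rt$p, stringsAsFactors = FALSE)
    ca <- cbind(trait = tr, a$anova$table)
    keep <- ca$source != "Residual"
    anova_rows[[tr]] <- rbind(
      rcbd_part[rcbd_part$source == "Replications", ],
      ca[keep, ],
      rcbd_part[rcbd_part$source == "Residual", ])

    pe <- a$partitioned
    blk <- rbind(g_mi = pe$g_m, g_fi = pe$g_f, g_i = pe$g, m_i = pe$m)
    gca_rows[[tr]] <- data.frame(trait = tr, effect = rownames(blk),
                                 blk, check.names = FALSE,
                                 stringsAsFactors = FALSE)
    mat[[tr]] <- pe$m

    ij <- which(upper.tri(pe$s_adj), arr.ind = TRUE)
    sca_rows[[tr]] <- data.frame(
      trait = tr, female = parents[ij[, 1]], male = parents[ij[, 2]],
      griffing_s = a$griffing$s[ij], adj_s_ij = pe$s_adj[ij],
      adj_s_ji = t(pe$s_adj)[ij], stringsAsFactors = FALSE)
    rec_rows[[tr]] <- data.frame(
      trait = tr, female = parents[ij[, 1]], male = parents[ij[, 2]],
      r_ij = pe$r_adj[ij],
      sig = pe$sig$r_adj[ij], stringsAsFactors = FALSE)

    gen_rows[[tr]] <- genetics_as_row(a$genetics, tr)
    het_rows[[tr]] <- cbind(trait = tr, as.data.frame(a$heterosis))
    cor_rows[[tr]] <- cbind(trait = tr, as.data.frame(a$correlations))
    se_rows[[tr]] <- data.frame(trait = tr, class = names(a$griffing$se),
                                se = as.numeric(a$griffing$se),
                                stringsAsFactors = FALSE)
  }
  put(do.call(rbind, anova_rows), "anova.csv")
  put(do.call(rbind, gca_rows), "gca_partition.csv")
  mat_df <- data.frame(parent = parents, do.call(cbind, mat),
                       check.names = FALSE, stringsAsFactors = FALSE)
  put(mat_df, "maternal.csv")
  put(do.call(rbind, sca_rows), "sca_pairs.csv")
  put(do.call(rbind, rec_rows), "reciprocal.csv")
  put(do.call(rbind, gen_rows), "genetic_params.csv")
  put(do.call(rbind, het_rows), "heterosis.csv")
  put(do.call(rbind, cor_rows), "correlations.csv")
  put(do.call(rbind, se_rows), "standard_errors.csv")

  machine <- lapply(analysis$traits, function(a) list(
    entry_means = a$means$x,
    rcbd_anova = a$rcbd$table,
    ca_anova = a$anova$table,
    mu = a$griffing$mu,
    g = a$griffing$g, s = a$griffing$s, rec = a$griffing$rec,
    g_f = a$partitioned$g_f, g_m = a$partitioned$g_m, m = a$partitioned$m,
    s_adj = a$partitioned$s_adj, r_adj = a$partitioned$r_adj,
    se = as.list(a$griffing$se),
    components = as.list(a$components),
    genetics = unclass(a$genetics),
    heterosis = as.data.frame(a$heterosis),
    correlations = as.data.frame(a$correlations)))
  vp <- file.path(out_dir, "report_values.json")
  jsonlite::write_json(machine, vp, digits = I(17), auto_unbox = TRUE,
                       dataframe = "columns", pretty = TRUE)
  files <- c(files, vp)

  meta <- list(
    package = "diallelpart",
    version = as.character(utils::packageVersion("diallelpart")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_parents = des$n_parents, n_reps = des$n_reps,
    parents = des$parents, traits = des$traits,
    alpha = analysis$alpha, crosses = analysis$crosses,
    directions = as.list(analysis$directions))
  mp <- file.path(out_dir, "metadata.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, mp)
  invisible(files)
}

#' Reload the machine-readable report values
#'
#' Reads `report_values.json` written by [write_report()]; numbers are
#' serialized at full precision, so reloaded values equal the in-memory
#' analysis bit for bit.
#'
#' @param path Path to `report_values.json` (or the report directory).
#' @return Nested list keyed by trait.
#' @export
read_report_values <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "report_values.json")
  jsonlite::read_json(path, simplifyVector = TRUE)
}
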