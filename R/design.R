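#' Describe a full diallel mating design
#'
#' A full (Method 1) diallel crosses p parents in all p^2 ordered
#' combinations: p selfs, p(p-1)/2 straight crosses and their reciprocals,
#' every entry replicated r times.
#'
#' @param parents Character vector of unique parent labels (p >= 3).
#' @param n_reps Number of replications r (>= 1); replications are treated
#'   as complete blocks.
#' @param traits Character vector of unique trait (response) names.
#' @return An object of class `diallel_design`: a list with elements
#'   `parents`, `n_parents`, `n_reps`, `traits`.
#' @examples
#' diallel_design(paste0("P", 1:8), 3, c("GY", "DTT"))
#' @export
diallel_design <- function(parents, n_reps, traits) {
  parents <- as.character(parents)
  traits <- as.character(traits)
  if (length(parents) < 3L)
    stop("a diallel needs at least 3 parents, got ", length(parents))
  if (anyDuplicated(parents))
    stop("parent labels must be unique")
  n_reps <- as.integer(n_reps)
  if (length(n_reps) != 1L || is.na(n_reps) || n_reps < 1L)
    stop("'n_reps' must be a single integer >= 1")
  if (length(traits) < 1L)
    stop("at least one trait is required")
  if (anyDuplicated(traits))
    stop("trait names must be unique")
  if (any(traits %in% c("female", "male", "rep")))
    stop("trait names may not clash with the key columns female/male/rep")
  structure(
    list(parents = parents, n_parents = length(parents),
         n_reps = n_reps, traits = traits),
    class = "diallel_design")
}

#' @export
print.diallel_design <- function(x, ...) {
  cat(sprintf("Full diallel design: %d parents x %d parents, %d replication(s)\n",
              x$n_parents, x$n_parents, x$n_reps))
  cat("Parents:", paste(x$parents, collapse = ", "), "\n")
  cat("Traits: ", paste(x$traits, collapse = ", "), "\n")
  invisible(x)
}

#' Validate plot-level diallel phenotypes
#'
#' Checks a long-format table of plot observations against a full-diallel
#' design: one row per (female, male, rep) triple, all p^2 * r triples
#' present (selfs included), parents drawn from the declared set, and every
#' trait value numeric and non-missing. Entries whose parents are outside
#' the declared parent set (e.g. commercial checks grown alongside the
#' diallel) are a validation error, not silently dropped.
#'
#' @param df A data.frame with columns `female`, `male`, `rep`, then one
#'   numeric column per trait.
#' @param design Optional [diallel_design()]. When omitted, the parent set
#'   (union of female and male labels, in order of first appearance), the
#'   replication count and the trait list are inferred from the table.
#' @return A validated object of class `diallel_data`: list with elements
#'   `design` and `plots` (the data.frame, keys normalized and sorted).
#' @export
as_diallel_data <- function(df, design = NULL) {
  df <- as.data.frame(df)
  key <- c("female", "male", "rep")
  if (!all(key %in% names(df)))
    stop("input must have columns 'female', 'male' and 'rep'")
  df$female <- as.character(df$female)
  df$male <- as.character(df$male)
  rep_num <- suppressWarnings(as.numeric(df$rep))
  if (anyNA(rep_num) || any(rep_num != round(rep_num)))
    stop("'rep' must be integer replication indices")
  df$rep <- as.integer(rep_num)

  if (is.null(design)) {
    parents <- unique(c(df$female, df$male))
    traits <- setdiff(names(df), key)
    design <- diallel_design(parents, max(df$rep), traits)
  }
  stopifnot(inherits(design, "diallel_design"))

  bad <- !(df$female %in% design$parents) | !(df$male %in% design$parents)
  if (any(bad))
    stop("records outside the declared parent set: ",
         paste(unique(paste0(df$female[bad], "/", df$male[bad])), collapse = ", "))
  missing_traits <- setdiff(design$traits, names(df))
  if (length(missing_traits))
    stop("trait column(s) missing from input: ",
         paste(missing_traits, collapse = ", "))

  for (tr in design$traits) {
    v <- df[[tr]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad_rows <- which(is.na(vn) & !is.na(v))
      if (length(bad_rows))
        stop("non-numeric value for trait '", tr, "' at row(s) ",
             paste(utils::head(bad_rows, 5L), collapse = ", "))
      v <- vn
    }
    if (anyNA(v))
      stop("missing value for trait '", tr, "' at row(s) ",
           paste(utils::head(which(is.na(v)), 5L), collapse = ", "),
           " (missing data are not supported; the design must be balanced)")
    df[[tr]] <- v
  }

  got <- paste(df$female, df$male, df$rep, sep = "\r")
  dup <- duplicated(got)
  if (any(dup))
    stop("duplicated (female, male, rep) triple(s): ",
         paste(unique(gsub("\r", "/", got[dup])), collapse = ", "))
  want <- expand.grid(rep = seq_len(design$n_reps), male = design$parents,
                      female = design$parents, stringsAsFactors = FALSE)
  want_key <- paste(want$female, want$male, want$rep, sep = "\r")
  absent <- setdiff(want_key, got)
  if (length(absent))
    stop("incomplete diallel; missing (female, male, rep) combination(s): ",
         paste(utils::head(gsub("\r", "/", absent), 10L), collapse = ", "),
         if (length(absent) > 10L) sprintf(" ... and %d more", length(absent) - 10L))
  extra <- setdiff(got, want_key)
  if (length(extra))
    stop("records beyond the declared design (rep > n_reps?): ",
         paste(utils::head(gsub("\r", "/", extra), 10L), collapse = ", "))

  ord <- order(match(df$female, design$parents), match(df$male, design$parents),
               df$rep)
  df <- df[ord, c(key, design$traits), drop = FALSE]
  rownames(df) <- NULL
  structure(list(design = design, plots = df), class = "diallel_data")
}

#' @export
print.diallel_data <- function(x, ...) {
  print(x$design)
  cat(sprintf("%d plot records (%d entries x %d reps)\n",
              nrow(x$plots), x$design$n_parents^2, x$design$n_reps))
  invisible(x)
}

#' Read plot-level diallel phenotypes from CSV
#'
#' Expects a comma-separated, UTF-8, headered long format:
#' `female,male,rep,<trait1>,<trait2>,...` with `rep` a 1-based integer and
#' one row per plot. The file must contain the complete p^2 x r set of
#' records (selfs on the diagonal; reciprocals as separate rows).
#'
#' @param path Path to the CSV file.
#' @param design Optional [diallel_design()] the file must conform to;
#'   inferred from the file when omitted.
#' @return A validated `diallel_data` object.
#' @seealso [write_diallel_csv()], [as_diallel_data()]
#' @export
read_diallel_csv <- function(path, design = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  as_diallel_data(df, design = design)
}

#' Write plot-level diallel phenotypes to CSV
#'
#' Inverse of [read_diallel_csv()]: values are written at full precision
#' (up to 17 significant digits) so a round trip reproduces the data
#' exactly.
#'
#' @param data A `diallel_data` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_diallel_csv <- function(data, path) {
  stopifnot(inherits(data, "diallel_data"))
  df <- data$plots
  for (tr in data$design$traits)
    df[[tr]] <- format(df[[tr]], digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
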