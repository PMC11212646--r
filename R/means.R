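#' Entry-mean table of a diallel trait
#'
#' Averages the r replicate plots of every (female, male) entry into the
#' p x p table of entry means x_ij (female i in rows, male j in columns;
#' diagonal = selfed parents), together with the marginal quantities used
#' throughout the combining-ability closed forms: row totals
#' x_i. = sum_j x_ij (parent i over all males), column totals
#' x_.j = sum_i x_ij (parent j over all females) and the grand total x_..
#'
#' @param data A `diallel_data` object.
#' @param trait Trait name (one of `data$design$traits`).
#' @return Object of class `cross_means`: list with `trait`, `x` (p x p
#'   matrix with parent dimnames), `row_totals`, `col_totals`,
#'   `grand_total`, `n_parents`, `n_reps`, `parents`.
#' @examples
#' td <- sim_truth(p = 4, r = 2, seed = 1)
#' d <- simulate_diallel(td)
#' entry_means(d, "trait")
#' @export
entry_means <- function(data, trait) {
  stopifnot(inherits(data, "diallel_data"))
  des <- data$design
  if (!trait %in% des$traits)
    stop("unknown trait '", trait, "'; available: ",
         paste(des$traits, collapse = ", "))
  p <- des$n_parents
  fi <- match(data$plots$female, des$parents)
  mi <- match(data$plots$male, des$parents)
  sums <- matrix(0, p, p, dimnames = list(des$parents, des$parents))
  v <- data$plots[[trait]]
  for (k in seq_along(v)) sums[fi[k], mi[k]] <- sums[fi[k], mi[k]] + v[k]
  x <- sums / des$n_reps
  new_cross_means(x, trait, des$n_reps)
}

#' Construct a `cross_means` object from a matrix of entry means
#'
#' Lower-level constructor used by [entry_means()] and the simulator; also
#' convenient when entry means are available directly (e.g. published
#' tables).
#'
#' @param x Square numeric matrix of entry means, females in rows, males in
#'   columns. Dimnames, when present, are taken as parent labels.
#' @param trait Trait name carried along for labeling.
#' @param n_reps Replication count behind each mean (used by downstream
#'   standard errors); defaults to 1.
#' @return A `cross_means` object (see [entry_means()]).
#' @export
new_cross_means <- function(x, trait = "trait", n_reps = 1L) {
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) stop("entry-mean table must be square")
  if (anyNA(x)) stop("entry-mean table contains missing values")
  p <- nrow(x)
  parents <- rownames(x)
  if (is.null(parents)) {
    parents <- paste0("P", seq_len(p))
    dimnames(x) <- list(parents, parents)
  }
  structure(
    list(trait = trait, x = x,
         row_totals = rowSums(x), col_totals = colSums(x),
         grand_total = sum(x), n_parents = p, n_reps = as.integer(n_reps),
         parents = parents),
    class = "cross_means")
}

#' @export
print.cross_means <- function(x, digits = 3, ...) {
  cat(sprintf("Entry means for trait '%s' (%d x %d, %d rep(s) per entry)\n",
              x$trait, x$n_parents, x$n_parents, x$n_reps))
  print(round(x$x, digits))
  invisible(x)
}
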