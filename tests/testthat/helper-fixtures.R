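# Shared fixtures built in code.

# Random entry-mean table (no structure beyond optional symmetry).
random_means <- function(p, seed, symmetric = FALSE, n_reps = 1L) {
  set.seed(seed)
  x <- matrix(rnorm(p * p, 50, 10), p, p)
  if (symmetric) x <- (x + t(x)) / 2
  new_cross_means(x, "y", n_reps)
}

# Small complete plot-level data.frame with deterministic values.
toy_plots <- function(p = 3, r = 2, traits = c("y1", "y2"), seed = 11) {
  set.seed(seed)
  parents <- paste0("P", seq_len(p))
  grid <- expand.grid(rep = seq_len(r), male = parents, female = parents,
                      stringsAsFactors = FALSE)
  df <- data.frame(female = grid$female, male = grid$male, rep = grid$rep,
                   stringsAsFactors = FALSE)
  for (tr in traits) df[[tr]] <- round(rnorm(nrow(df), 100, 15), 3)
  df
}

# Least-squares oracle for the additive (GCA) fit: project the entry means
# onto span{1, row_i + col_j} by QR, independent of the closed forms.
lsq_additive_fit <- function(x) {
  p <- nrow(x)
  n <- p * p
  X <- matrix(0, n, 1 + p)
  y <- numeric(n)
  k <- 0
  for (i in seq_len(p)) for (j in seq_len(p)) {
    k <- k + 1
    X[k, 1] <- 1
    X[k, 1 + i] <- X[k, 1 + i] + 1 # parent i contributes (as female)
    X[k, 1 + j] <- X[k, 1 + j] + 1 # parent j contributes (as male)
    y[k] <- x[i, j]
  }
  fit <- lm.fit(X, y) # rank-deficient; use fitted values + sweep to effects
  co <- qr.coef(qr(X), y)
  co[is.na(co)] <- 0
  a <- co[-1]
  a_centred <- a - mean(a)
  mu <- mean(x)
  list(mu = mu, g = a_centred, fitted = matrix(fit$fitted.values, p, p,
                                               byrow = TRUE))
}
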