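# Published genetic-parameter table (8 maize traits) used for closure
# checks: the derived columns must follow from the printed variance
# components under sigma2_A = 2 sigma2_gca, sigma2_D = sigma2_sca,
# sigma2_P = sigma2_A + sigma2_D + sigma2_rca + sigma2_e / r (r = 3).
published_genetics <- read.table(header = TRUE, text = "
trait   gca   sca    rca    P      e     A     D      AD   H2    h2    baker
DTT     1.52  3.50   0.76   7.58   0.82  3.04  3.50   0.87 86.36 40.13 0.46
DTS     0.80  4.40   0.11   6.35   0.71  1.60  4.40   0.36 94.54 25.25 0.27
NKR     1.66  19.08  4.57   27.06  0.27  3.32  19.08  0.17 82.78 12.26 0.15
NKRC    0.21  0.35   0.13   0.91   0.06  0.41  0.35   1.17 83.51 45.26 0.54
CG      0.02  0.11   0.01   0.15   0.004 0.03  0.11   0.27 92.62 21.05 0.23
CL      0.36  3.96   0.94   5.63   0.03  0.72  3.96   0.18 83.12 12.82 0.15
HGW     1.72  17.04  2.37   22.99  0.38  3.45  17.04  0.20 89.14 15.00 0.17
GY      22.09 271.25 118.6  439.3  15.81 44.18 271.25 0.16 71.80 10.06 0.14
")

test_that("variance components follow the entry-mean EMS solution", {
  mn <- random_means(6, seed = 21, n_reps = 3)
  ca <- combining_ability_anova(mn, ms_residual = 3.2, df_residual = 70, r = 3)
  vc <- variance_components(ca, p = 6, r = 3)
  tab <- ca$table
  ms <- function(src) tab$MS_mean[tab$source == src]
  s2e <- 3.2 / 3
  expect_equal(unname(vc["var_err"]), s2e)
  expect_equal(unname(vc["var_gca"]), max(0, (ms("GCA") - s2e) / 12))
  expect_equal(unname(vc["var_sca"]), max(0, ms("SCA") - s2e))
  expect_equal(unname(vc["var_rca"]), max(0, (ms("Reciprocal") - s2e) / 2))

  # all mean squares equal to the error mean square -> all components zero
  flat <- data.frame(source = c("GCA", "SCA", "Reciprocal", "Residual"),
                     MS_mean = rep(2, 4))
  expect_equal(unname(variance_components(flat, 6, 3)), c(0, 0, 0, 2),
               ignore_attr = TRUE)
  expect_error(variance_components(flat[-2, ], 6, 3), "SCA")
  neg <- flat
  neg$MS_mean <- c(1, 1, 1, 2)
  expect_warning(variance_components(neg, 6, 3), "truncated")
})

test_that("reciprocal variance from published plot-basis mean squares", {
  # kernel-row trait: MS_rec = 28.29, MS_resid = 0.82, r = 3
  flat <- data.frame(source = c("GCA", "SCA", "Reciprocal", "Residual"),
                     MS_mean = c(51.93, 102.80, 28.29, 0.82) / 3)
  vc <- variance_components(flat, p = 8, r = 3)
  expect_equal(unname(vc["var_rca"]), (28.29 - 0.82) / 6)
  expect_equal(unname(vc["var_rca"]), 4.57, tolerance = 0.01 + 1e-9)
})

test_that("derived genetics reproduce published point values", {
  dts <- derived_genetics(c(var_gca = 0.80, var_sca = 4.40,
                            var_rca = 0.11, var_err = 0.71), r = 3)
  expect_equal(dts$var_P, 6.3467, tolerance = 1e-4)
  expect_equal(dts$H2, 94.54, tolerance = 0.01 + 1e-9)

  gy <- derived_genetics(c(var_gca = 22.09, var_sca = 271.25,
                           var_rca = 118.6, var_err = 15.81), r = 3)
  expect_equal(gy$var_P, 439.3, tolerance = 0.1 + 1e-9)
  expect_equal(gy$h2, 10.06, tolerance = 0.01 + 1e-9)
  expect_equal(gy$baker, 0.14, tolerance = 0.01 + 1e-9)

  z <- derived_genetics(c(var_gca = 0, var_sca = 0, var_rca = 0,
                          var_err = 2), r = 3)
  expect_equal(z$H2, 0)
  expect_equal(z$h2, 0)
  expect_equal(z$baker, 0)
})

test_that("full published table closes under input-rounding intervals", {
  # The printed components are rounded (2 decimals; 3 for the smallest,
  # 1 for the largest), so each derived cell is checked against the range
  # the formulas can produce over the rounding box of its inputs, widened
  # by half a unit in the cell's own last printed decimal. Formulas are
  # monotone in each component, so evaluating the 16 corners bounds the
  # range exactly.
  for (k in seq_len(nrow(published_genetics))) {
    row <- published_genetics[k, ]
    h <- c(gca = 0.005, sca = 0.005,
           rca = if (row$trait == "GY") 0.05 else 0.005,
           e = if (row$trait == "CG") 0.0005 else 0.005)
    corners <- expand.grid(gca = row$gca + c(-1, 1) * h["gca"],
                           sca = row$sca + c(-1, 1) * h["sca"],
                           rca = row$rca + c(-1, 1) * h["rca"],
                           e = row$e + c(-1, 1) * h["e"])
    vals <- apply(corners, 1, function(cc) {
      cc <- as.numeric(cc)
      g <- derived_genetics(c(var_gca = cc[1], var_sca = cc[2],
                              var_rca = cc[3], var_err = cc[4]), r = 3)
      c(A = g$var_A, D = g$var_D, P = g$var_P, AD = g$ratio_AD,
        H2 = g$H2, h2 = g$h2, baker = g$baker)
    })
    for (col in c("A", "D", "P", "AD", "H2", "h2", "baker")) {
      printed <- row[[col]]
      out_half <- if (col == "P" && row$trait == "GY") 0.05 else 0.005
      lo <- min(vals[col, ]) - out_half - 1e-9
      hi <- max(vals[col, ]) + out_half + 1e-9
      expect_true(printed >= lo && printed <= hi,
                  label = sprintf("%s %s: printed %.4g in [%.4g, %.4g]",
                                  row$trait, col, printed, lo, hi))
    }
  }
})

test_that("heritability ratios are monotone and scale-free", {
  base <- c(var_gca = 2, var_sca = 5, var_rca = 1, var_err = 3)
  g0 <- derived_genetics(base, 3)
  up_gca <- derived_genetics(base + c(1, 0, 0, 0), 3)
  up_sca <- derived_genetics(base + c(0, 4, 0, 0), 3)
  expect_gt(up_gca$baker, g0$baker)
  expect_lt(up_sca$baker, g0$baker)
  expect_gt(up_gca$H2, g0$H2)

  scaled <- derived_genetics(base * 7.3, 3)
  expect_equal(scaled$H2, g0$H2)
  expect_equal(scaled$h2, g0$h2)
  expect_equal(scaled$baker, g0$baker)
  expect_equal(scaled$var_A, 7.3 * g0$var_A)
})
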