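# Cohort statistics: descriptives and partial correlation adjusted for the
# fracture/lumbar BMD ratio.

#' Descriptive statistics
#'
#' Sample mean, SD (n - 1 denominator), minimum and maximum.
#'
#' @param values numeric vector, length >= 2.
#' @return list with `mean`, `sd`, `min`, `max`, `n`.
#' @export
descriptive <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("descriptive statistics need n >= 2")
  list(mean = mean(values), sd = stats::sd(values),
       min = min(values), max = max(values), n = length(values))
}

#' Partial correlation adjusted for one covariate
#'
#' Correlation between `x` and `y` after removing the linear effect of `z`
#' from both: each variable is residualised on `z` by ordinary least squares
#' (with intercept) and the Pearson correlation of the residuals is returned.
#' The two-sided p-value uses `t = r * sqrt(df / (1 - r^2))` with
#' `df = n - 3`.
#'
#' @param x,y numeric vectors of equal length (n >= 4).
#' @param z covariate vector of the same length.
#' @param names optional character pair naming (x, y) in the result.
#' @return list of class `partial_correlation`: `r`, `p`, `df`, `n`, `pair`.
#' @export
partial_correlation <- function(x, y, z, names = c("x", "y")) {
  n <- length(x)
  if (length(y) != n || length(z) != n) stop("x, y, z must have equal length")
  if (n < 4) stop("partial correlation needs n >= 4 (df = n - 3 >= 1)")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant variable: correlation undefined")
  rx <- stats::residuals(stats::lm.fit(cbind(1, z), x))
  ry <- stats::residuals(stats::lm.fit(cbind(1, z), y))
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("residual variance is zero after adjustment")
  r <- stats::cor(rx, ry)
  df <- n - 3
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  structure(list(r = r, p = p, df = df, n = n, t = tval,
                 pair = names), class = "partial_correlation")
}

#' @export
print.partial_correlation <- function(x, ...) {
  cat(sprintf("partial correlation %s ~ %s | covariate: r = %.3f, p = %.4g (df = %d)\n",
              x$pair[1], x$pair[2], x$r, x$p, x$df))
  invisible(x)
}

#' Partial-correlation panel over the cohort table
#'
#' Runs the four partial correlations of the cohort analysis: the failure
#' load of the fracture-centred functional spinal unit (`fsu_f`, dependent)
#' against the L1-L3 unit failure load, the mean L1-L3 vBMD, the mean L1-L3
#' failure displacement, and the mean L1-L3 failure load, each adjusted for
#' the fracture/lumbar BMD ratio (`bmd_ratio`).  Significance is flagged at
#' p < 0.05.
#'
#' @param records data.frame with columns `fsu_f`, `fsu_l1l3`,
#'   `bmd_l1l3_mean`, `displacement_l1l3_mean`, `load_l1l3_mean`,
#'   `bmd_ratio`; one row per subject (>= 4 rows).
#' @return data.frame of class `correlation_panel` with one row per
#'   independent variable: `independent`, `r`, `p`, `df`, `n`,
#'   `significant`.
#' @export
run_correlation_panel <- function(records) {
  needed <- c("fsu_f", "fsu_l1l3", "bmd_l1l3_mean",
              "displacement_l1l3_mean", "load_l1l3_mean", "bmd_ratio")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("records lack columns: ", paste(missing_cols, collapse = ", "))
  records <- records[stats::complete.cases(records[needed]), ]
  if (nrow(records) < 4) stop("need >= 4 complete subjects")
  ivs <- c(FSU_L1L3 = "fsu_l1l3", BMD_L1L3 = "bmd_l1l3_mean",
           Displacement_L1L3 = "displacement_l1l3_mean",
           Load_L1L3 = "load_l1l3_mean")
  rows <- lapply(names(ivs), function(nm) {
    pc <- partial_correlation(records$fsu_f, records[[ivs[nm]]],
                              records$bmd_ratio, names = c("FSU_F", nm))
    data.frame(independent = nm, r = pc$r, p = pc$p, df = pc$df, n = pc$n,
               significant = pc$p < 0.05)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("correlation_panel", "data.frame")
  out
}

#' @export
print.correlation_panel <- function(x, ...) {
  cat("Partial correlations with FSU_F (adjusted for fracture/lumbar BMD ratio):\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-18s r = %6.3f  p = %.4g%s\n", x$independent[i],
                x$r[i], x$p[i], if (x$significant[i]) " *" else ""))
  invisible(x)
}

#' Simulate cohort records with a built-in partial correlation
#'
#' Draws records from a Gaussian model in which the partial correlation
#' between `fsu_f` and each independent measure, given the `bmd_ratio`
#' covariate, equals `partial_r` exactly: with independent standard normals
#' `u`, `v`, `w`, the covariate loading `gamma` feeds `w` into both
#' variables, and the residual parts are correlated at `partial_r`.  Used
#' for parameter-recovery checks of the statistics layer.
#'
#' @param n number of subjects.
#' @param partial_r target partial correlation in (-1, 1).
#' @param gamma covariate loading in \[0, 1).
#' @param seed integer seed.
#' @return data.frame with the columns expected by
#'   [run_correlation_panel()]; ground-truth partial correlation is
#'   `partial_r` for every independent variable.
#' @export
simulate_cohort_records <- function(n, partial_r = 0.8, gamma = 0.5,
                                    seed = 1L) {
  stopifnot(abs(partial_r) < 1, gamma >= 0, gamma < 1)
  local_seed(seed, {
    w <- stats::rnorm(n)   # drives the covariate
    u <- stats::rnorm(n)
    mk <- function() {
      v <- stats::rnorm(n)
      gamma * w + sqrt(1 - gamma^2) * (partial_r * u + sqrt(1 - partial_r^2) * v)
    }
    x <- gamma * w + sqrt(1 - gamma^2) * u
    data.frame(
      subject = seq_len(n),
      fsu_f = 1500 + 400 * x,
      fsu_l1l3 = 1800 + 450 * mk(),
      bmd_l1l3_mean = 65 + 12 * mk(),
      displacement_l1l3_mean = 0.8 + 0.15 * mk(),
      load_l1l3_mean = 1600 + 420 * mk(),
      bmd_ratio = 1 + 0.15 * w
    )
  })
}
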