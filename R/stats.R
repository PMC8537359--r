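#' Two-sample t test of a treated group against control
#'
#' Two-sided, Welch (unequal variance) by default — group variances are
#' not expected to be equal under quenching; the pooled Student variant
#' is available via `var_equal`. Comparing a sample against itself gives
#' t = 0 and p = 1 exactly. If both samples are constant with equal
#' means the test statistic is undefined and p = 1 is returned by
#' convention (with a message).
#'
#' @param treated,control numeric samples, each of length >= 2.
#' @param var_equal use the pooled-variance Student t.
#' @return two-sided p-value.
#' @export
t_test_vs_control <- function(treated, control, var_equal = FALSE) {
  if (length(treated) < 2 || length(control) < 2)
    stop("both samples need n >= 2")
  if (sd(treated) == 0 && sd(control) == 0) {
    if (mean(treated) == mean(control)) {
      message("both samples constant with equal means; p = 1 by convention")
      return(1)
    }
    return(0)
  }
  unname(t.test(treated, control, var.equal = var_equal)$p.value)
}

#' Wilcoxon-Mann-Whitney test of a treated group against control
#'
#' Two-sided rank-sum test of whether the two samples come from the same
#' distribution: exact enumeration when the combined sample size is at
#' most 12 and there are no ties, the normal approximation with
#' continuity and tie correction otherwise.
#'
#' @param treated,control numeric samples, each of length >= 2.
#' @return two-sided p-value.
#' @export
mww_test_vs_control <- function(treated, control) {
  if (length(treated) < 2 || length(control) < 2)
    stop("both samples need n >= 2")
  if (sd(treated) == 0 && sd(control) == 0 &&
      mean(treated) == mean(control)) {
    message("both samples constant and equal; p = 1 by convention")
    return(1)
  }
  n <- length(treated) + length(control)
  exact <- n <= 12 && !anyDuplicated(c(treated, control))
  p <- unname(suppressWarnings(
    wilcox.test(treated, control, exact = exact, correct = TRUE)$p.value))
  if (is.nan(p)) 1 else p
}

# Monte-Carlo null table of the Lilliefors statistic at sample size n,
# memoised: D is computed against a normal with mean/sd estimated from
# each draw, whose null distribution depends on n only.
lilliefors_null <- function(n, nsim = 10000, null_seed = 104729) {
  key <- sprintf("lf_%d_%d_%d", n, nsim, null_seed)
  if (!is.null(.cq_cache[[key]])) return(.cq_cache[[key]])
  tab <- with_seed(null_seed, {
    vapply(seq_len(nsim), function(i) {
      z <- rnorm(n)
      lilliefors_stat(z)
    }, numeric(1))
  })
  .cq_cache[[key]] <- tab
  tab
}

lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  p <- pnorm(z)
  max(seq_len(n) / n - p, p - (seq_len(n) - 1) / n)
}

#' Kolmogorov-Smirnov test of normality
#'
#' One-sample KS test of a sample against a normal with mean and s.d.
#' estimated from that sample. Because the parameters are estimated, the
#' classical KS null is anti-conservative; the primary p-value therefore
#' comes from a seeded Monte-Carlo simulation of the Lilliefors null
#' (memoised per sample size). The classical KS p is also reported for
#' comparability with analyses that used it.
#'
#' @param sample numeric sample, n >= 5, non-constant.
#' @param nsim Monte-Carlo draws for the Lilliefors null.
#' @param null_seed seed of the null simulation (fixed by default so
#'   results are reproducible run-to-run).
#' @return list with `statistic` (D), `p` (Monte-Carlo Lilliefors),
#'   `p_classical` (standard KS null, anti-conservative).
#' @export
ks_normality <- function(sample, nsim = 10000, null_seed = 104729) {
  if (length(sample) < 5) stop("KS normality test needs n >= 5")
  if (sd(sample) == 0) stop("zero-variance sample: normality is undefined")
  d <- lilliefors_stat(sample)
  null_tab <- lilliefors_null(length(sample), nsim, null_seed)
  p_mc <- (1 + sum(null_tab >= d)) / (nsim + 1)
  p_cl <- suppressWarnings(
    ks.test(sample, "pnorm", mean(sample), sd(sample))$p.value)
  list(statistic = unname(d), p = p_mc, p_classical = unname(p_cl))
}

#' Group-versus-control comparison table and shared histograms
#'
#' For every group (control included, compared against itself): sample
#' size, mean intensity, Welch t p, Wilcoxon-Mann-Whitney p, and the
#' KS-normality p (Monte-Carlo Lilliefors, with the classical KS p
#' alongside). Histogram counts use one shared set of bins across all
#' groups so the distributions can be stacked in one plot. No
#' multiple-testing correction is applied by default; `bonferroni`
#' multiplies the t and MWW p-values by the number of treated groups.
#'
#' @param samples named list of numeric vectors (per-cell mean
#'   intensities per group), or a pooled data.frame with `group` and
#'   `mean_intensity` columns.
#' @param control name of the control group.
#' @param alpha significance level used for the `significant` flag.
#' @param n_bins number of shared histogram bins.
#' @param var_equal,ks_nsim,ks_null_seed passed to the underlying tests.
#' @param bonferroni apply a Bonferroni correction across treated groups.
#' @return list with `table` (one row per group) and `histograms`
#'   (long-format data.frame: group, bin_left, bin_right, count).
#' @export
summarize_groups <- function(samples, control = "control", alpha = 0.05,
                             n_bins = 30, var_equal = FALSE,
                             ks_nsim = 10000, ks_null_seed = 104729,
                             bonferroni = FALSE) {
  if (is.data.frame(samples))
    samples <- split(samples$mean_intensity, samples$group)
  if (!control %in% names(samples))
    stop("control group '", control, "' not found among: ",
         paste(names(samples), collapse = ", "))
  # control first, then the others in input order, as in a results table
  ord <- c(control, setdiff(names(samples), control))
  samples <- samples[ord]
  ctrl <- samples[[control]]
  n_treated <- max(1L, length(samples) - 1L)
  adj <- function(p) if (bonferroni) min(1, p * n_treated) else p

  rows <- lapply(names(samples), function(g) {
    x <- samples[[g]]
    # a degenerate (constant) sample has no defined normality p
    ks <- tryCatch(ks_normality(x, nsim = ks_nsim, null_seed = ks_null_seed),
                   error = function(e) list(p = NA_real_,
                                            p_classical = NA_real_))
    p_t <- t_test_vs_control(x, ctrl, var_equal = var_equal)
    p_m <- mww_test_vs_control(x, ctrl)
    if (g != control) {
      p_t <- adj(p_t); p_m <- adj(p_m)
    }
    data.frame(group = g, n = length(x), mean = mean(x),
               p_t = p_t, p_mww = p_m,
               p_ks_normal = ks$p, p_ks_classical = ks$p_classical,
               significant = g != control & p_t < alpha,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  all_vals <- unlist(samples, use.names = FALSE)
  breaks <- seq(min(all_vals), max(all_vals), length.out = n_bins + 1)
  if (breaks[1] == breaks[n_bins + 1])
    breaks <- breaks[1] + seq(-0.5, 0.5, length.out = n_bins + 1)
  hists <- do.call(rbind, lapply(names(samples), function(g) {
    cnt <- graphics::hist(samples[[g]], breaks = breaks, plot = FALSE)$counts
    data.frame(group = g, bin_left = breaks[-length(breaks)],
               bin_right = breaks[-1], count = cnt,
               stringsAsFactors = FALSE)
  }))
  rownames(hists) <- NULL
  list(table = tab, histograms = hists, alpha = alpha, control = control)
}
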