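#' Configuration of a simulated union-hypothesis testing study
#'
#' Describes the data-generating mechanism of the Monte-Carlo harness: for
#' each of \code{m} hypothesis pairs, two test statistics are drawn with unit
#' variance, standard normal for true component hypotheses and mean-shifted
#' by \code{snr1}/\code{snr2} (per column) for false ones, then converted to
#' one-sided p-values \eqn{p = 1 - \Phi(Z)}.  Pair types are laid out as
#' \code{m0} double-null pairs, \code{m1} one-false pairs (the false column
#' is randomised per pair and replicate), and \code{m2} double-false pairs.
#' Optional equicorrelation \code{rho} induces compound-symmetry dependence
#' among the \code{m} statistics within each column (columns independent);
#' \code{cs_joint = TRUE} instead correlates all \code{2m} statistics
#' jointly.
#'
#' @param m0,m1,m2 pair-type counts (see [mixture_model()]).
#' @param snr1,snr2 mean shifts of false statistics in columns 1 and 2;
#'   \code{snr2} defaults to \code{snr1}.
#' @param rho compound-symmetry correlation in \code{[0, 1)}.
#' @param cs_joint correlate all \code{2m} statistics jointly rather than
#'   within columns only.
#' @param reps number of Monte-Carlo replicates.
#' @param alpha familywise error level for the FWER procedures.
#' @param k per-family error budget for the \code{"pfer"} method.
#' @param methods procedures to run: subset of \code{"default"} (fixed
#'   \eqn{c = \alpha/m}, test at \eqn{\alpha/|S|}), \code{"fixed"} (fixed
#'   \code{c}, test at \eqn{\alpha/|S|}), \code{"adaptive"},
#'   \code{"bonferroni"}, \code{"oracle"} (fixed threshold from
#'   [oracle_threshold()] at the true mixture parameters, test at
#'   \eqn{\alpha/|S|}), \code{"pfer"}.
#' @param c fixed screening threshold, required for \code{"fixed"}.
#' @param seed integer seed driving all randomness.
#' @return A list of class \code{"sim_config"}.
#' @details Under unequal shifts the oracle threshold is computed under the
#'   convention of a single common snr, taken as \code{min(snr1, snr2)}
#'   (override via \code{oracle_snr}).
#' @param oracle_snr single snr used by the oracle solver; defaults to
#'   \code{min(snr1, snr2)}.
#' @export
sim_config <- function(m0 = 0L, m1 = 0L, m2 = 0L, snr1 = 3, snr2 = snr1,
                       rho = 0, cs_joint = FALSE, reps = 1000L,
                       alpha = 0.05, k = 1,
                       methods = base::c("default", "adaptive", "bonferroni"),
                       c = NULL, seed = 1L, oracle_snr = min(snr1, snr2)) {
  # base:: throughout: `c` is the fixed-threshold argument in this scope
  m <- m0 + m1 + m2
  if (m < 1L) stop("need at least one hypothesis pair", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("`rho` must lie in [0, 1)", call. = FALSE)
  if (reps < 1L) stop("`reps` must be at least 1", call. = FALSE)
  methods <- match.arg(methods, base::c("default", "fixed", "adaptive",
                                        "bonferroni", "oracle", "pfer"),
                       several.ok = TRUE)
  if ("fixed" %in% methods && is.null(c))
    stop("method \"fixed\" needs an explicit threshold `c`", call. = FALSE)
  structure(list(m0 = as.integer(m0), m1 = as.integer(m1),
                 m2 = as.integer(m2), m = as.integer(m),
                 snr1 = snr1, snr2 = snr2, rho = rho, cs_joint = cs_joint,
                 reps = as.integer(reps), alpha = alpha, k = k,
                 methods = methods, c = c, seed = as.integer(seed),
                 oracle_snr = oracle_snr),
            class = "sim_config")
}

# Draw `nr` replicate tables as nr x m matrices, consuming the current RNG
# stream in a fixed order (column-1 noise, shared factor, column-2 noise,
# shared factor, false-column assignment).
sim_pvalue_matrices <- function(config, nr) {
  m <- config$m
  types <- rep.int(c(0L, 1L, 2L), c(config$m0, config$m1, config$m2))
  draw_noise <- function(w_shared) {
    E <- matrix(stats::rnorm(nr * m), nr, m)
    if (config$rho > 0) {
      W <- if (is.null(w_shared)) stats::rnorm(nr) else w_shared
      list(eps = sqrt(config$rho) * W + sqrt(1 - config$rho) * E, W = W)
    } else list(eps = E, W = NULL)
  }
  n1 <- draw_noise(NULL)
  n2 <- draw_noise(if (config$cs_joint) n1$W else NULL)
  false1 <- matrix(0, nr, m)
  false2 <- matrix(0, nr, m)
  idx11 <- which(types == 2L)
  false1[, idx11] <- 1
  false2[, idx11] <- 1
  idx01 <- which(types == 1L)
  if (length(idx01)) {
    in_col1 <- matrix(stats::runif(nr * length(idx01)) < 0.5,
                      nr, length(idx01))
    false1[, idx01] <- in_col1
    false2[, idx01] <- !in_col1
  }
  p1 <- stats::pnorm(-(n1$eps + config$snr1 * false1))
  p2 <- stats::pnorm(-(n2$eps + config$snr2 * false2))
  list(p1 = p1, p2 = p2, pmin = pmin(p1, p2), pmax = pmax(p1, p2),
       types = types)
}

#' Generate one synthetic p-value table
#'
#' Draws a single replicate from the design in a [sim_config()],
#' reproducibly determined by \code{(seed, rep_index)}.
#'
#' @param config a [sim_config()].
#' @param rep_index replicate number (positive integer).
#' @return A [pvalue_table()] with attribute \code{pair_type}, an integer
#'   vector coding each row 0 = both components true, 1 = exactly one
#'   false, 2 = both false.
#' @examples
#' cfg <- sim_config(m1 = 10, snr1 = 2, seed = 7)
#' tab <- generate_table(cfg, rep_index = 1)
#' table(attr(tab, "pair_type"))
#' @export
generate_table <- function(config, rep_index = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (rep_index < 1L) stop("`rep_index` must be positive", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((config$seed + 1000003 * (rep_index - 1L)) %% 2147483629L)
  mats <- sim_pvalue_matrices(config, 1L)
  out <- pvalue_table(p1 = drop(mats$p1), p2 = drop(mats$p2))
  attr(out, "pair_type") <- mats$types
  out
}

# Per-replicate rejection matrices (nr x m logical) for the requested
# methods, from pmin/pmax matrices.  Matches the per-table procedures
# row for row.
decide_methods <- function(mats, config) {
  nr <- nrow(mats$pmin)
  m <- config$m
  alpha <- config$alpha
  two_stage <- function(c0) {
    sel <- mats$pmin <= c0
    s <- rowSums(sel)
    thr <- ifelse(s > 0L, alpha / s, -Inf)   # recycles down columns
    sel & mats$pmax <= thr
  }
  single_threshold <- function(budget) {
    thr <- vapply(seq_len(nr), function(i)
      adaptive_threshold_pmin(mats$pmin[i, ], budget), numeric(1))
    mats$pmin <= thr & mats$pmax <= thr
  }
  out <- list()
  for (meth in config$methods) {
    out[[meth]] <- switch(meth,
      default    = two_stage(alpha / m),
      fixed      = two_stage(config$c),
      oracle     = two_stage(oracle_threshold_for(config)),
      adaptive   = single_threshold(alpha),
      pfer       = single_threshold(config$k),
      bonferroni = mats$pmax <= alpha / m)
  }
  out
}

oracle_threshold_for <- function(config) {
  as.numeric(oracle_threshold(
    mixture_model(config$m0, config$m1, config$m2, snr = config$oracle_snr),
    config$alpha))
}

#' Monte-Carlo error-rate and power estimates
#'
#' Runs every requested procedure on every simulated replicate of the
#' design in \code{config} and summarises: the familywise error rate is the
#' share of replicates in which at least one true union hypothesis (pair
#' type 0 or 1) is rejected; power is the mean over replicates of the
#' fraction of double-false pairs rejected.  All methods share the same
#' replicate stream (common random numbers), so differences between methods
#' are paired.
#'
#' @param config a [sim_config()].
#' @param chunk_size replicates generated per block, to bound memory
#'   (default 2000).
#' @return A data frame of class \code{"simulation_summary"}, one row per
#'   method, with columns \code{method}, \code{fwer}, \code{fwer_se},
#'   \code{power}, \code{power_se} (\code{NA} when the design has no
#'   double-false pair), \code{mean_selected} (for the default-threshold
#'   screen; \code{NA} if \code{"default"} not requested), \code{mean_v}
#'   (mean number of true unions rejected), \code{reps}, \code{seed}.
#'   Standard errors are binomial, \eqn{\sqrt{\hat p (1-\hat p)/reps}}.
#' @examples
#' cfg <- sim_config(m0 = 20, m2 = 5, snr1 = 3, reps = 200, seed = 42)
#' estimate_error_rates(cfg)
#' @export
estimate_error_rates <- function(config, chunk_size = 2000L) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  methods <- config$methods
  acc <- list()
  for (meth in methods)
    acc[[meth]] <- list(any_false = 0, v_sum = 0, pow_sum = 0)
  sel_default_sum <- 0
  done <- 0L
  types <- rep.int(c(0L, 1L, 2L), c(config$m0, config$m1, config$m2))
  true_union <- types != 2L
  while (done < config$reps) {
    nr <- min(chunk_size, config$reps - done)
    mats <- sim_pvalue_matrices(config, nr)
    rej <- decide_methods(mats, config)
    sel_default_sum <- sel_default_sum +
      sum(mats$pmin <= config$alpha / config$m)
    for (meth in methods) {
      V <- rowSums(rej[[meth]][, true_union, drop = FALSE])
      acc[[meth]]$any_false <- acc[[meth]]$any_false + sum(V >= 1L)
      acc[[meth]]$v_sum <- acc[[meth]]$v_sum + sum(V)
      if (config$m2 > 0L)
        acc[[meth]]$pow_sum <- acc[[meth]]$pow_sum +
          sum(rej[[meth]][, !true_union, drop = FALSE]) / config$m2
    }
    done <- done + nr
  }
  reps <- config$reps
  fwer <- vapply(methods, function(mt) acc[[mt]]$any_false / reps, numeric(1))
  power <- if (config$m2 > 0L)
    vapply(methods, function(mt) acc[[mt]]$pow_sum / reps, numeric(1))
  else rep(NA_real_, length(methods))
  out <- data.frame(
    method = methods,
    fwer = fwer,
    fwer_se = sqrt(fwer * (1 - fwer) / reps),
    power = power,
    power_se = if (config$m2 > 0L) sqrt(power * (1 - power) / reps)
               else rep(NA_real_, length(methods)),
    mean_selected = if ("default" %in% methods) sel_default_sum / reps
                    else NA_real_,
    mean_v = vapply(methods, function(mt) acc[[mt]]$v_sum / reps, numeric(1)),
    reps = reps, seed = config$seed,
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("simulation_summary", "data.frame")
  out
}

#' Error-rate study across signal strengths in the all-one-false design
#'
#' The worst case for the default fixed threshold: every pair has exactly
#' one false component, so every union hypothesis is true and any rejection
#' is a familywise error.  Runs the requested procedures over a grid of
#' signal-to-noise ratios and reports estimated FWER in percent with
#' Monte-Carlo standard errors.
#'
#' @param reps replicates per signal level (20,000 reproduces the published
#'   precision; smaller values give a quick smoke run).
#' @param seed integer seed.
#' @param snr numeric vector of signal levels (default
#'   \code{seq(3.1, 3.9, by = 0.2)}).
#' @param m number of pairs (default 200).
#' @param alpha level (default 0.05).
#' @param methods procedures to include.
#' @return Data frame with one row per (snr, method): columns \code{snr},
#'   \code{method}, \code{fwer_pct}, \code{se_pct}, \code{reps}.
#' @export
replicate_table1 <- function(reps = 1000L, seed = 1L,
                             snr = seq(3.1, 3.9, by = 0.2), m = 200L,
                             alpha = 0.05,
                             methods = c("oracle", "adaptive", "default",
                                         "bonferroni")) {
  rows <- lapply(seq_along(snr), function(i) {
    cfg <- sim_config(m1 = m, snr1 = snr[i], reps = reps, alpha = alpha,
                      methods = methods, seed = seed + (i - 1L))
    est <- estimate_error_rates(cfg)
    data.frame(snr = snr[i], method = est$method,
               fwer_pct = 100 * est$fwer, se_pct = 100 * est$fwer_se,
               reps = reps, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
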