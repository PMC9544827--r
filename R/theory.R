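#' CDF of a one-sided Gaussian p-value under a mean shift
#'
#' The working model for nonnull p-values: a test statistic
#' \eqn{Z \sim N(\mathrm{snr}, 1)} with one-sided p-value
#' \eqn{p = 1 - \Phi(Z)} has \eqn{P(p \le u) = \Phi(\mathrm{snr} -
#' z_{1-u})}.  With \code{snr = 0} this is the identity (uniform null
#' p-values); for \code{snr > 0} it strictly dominates the uniform and has a
#' strictly decreasing density, the shape assumed throughout the theory.
#'
#' @param u evaluation point(s) in \code{[0, 1]}.
#' @param snr nonnegative mean shift of the nonnull statistic
#'   (signal-to-noise ratio).
#' @return \eqn{F(u)}, vectorised over \code{u}.
#' @examples
#' gaussian_p_cdf(0.005, snr = 2)  # ~0.28
#' @export
gaussian_p_cdf <- function(u, snr) {
  if (any(is.na(u)) || any(u < 0) || any(u > 1))
    stop("`u` must lie in [0, 1]", call. = FALSE)
  if (snr < 0) stop("`snr` must be nonnegative", call. = FALSE)
  out <- stats::pnorm(snr + stats::qnorm(u))
  out[u == 0] <- 0
  out[u == 1] <- 1
  out
}

#' Mixture model of hypothesis-pair types
#'
#' Describes a family of \eqn{m} hypothesis pairs by the integer counts of
#' each type: \code{m0} pairs with both components true (0,0), \code{m1}
#' with exactly one false component (0,1)/(1,0), \code{m2} with both false
#' (1,1).  Nonnull component p-values follow the Gaussian-shift CDF
#' [gaussian_p_cdf()] with a common \code{snr}; null p-values are uniform and
#' all p-values are independent.
#'
#' @param m0,m1,m2 nonnegative integer counts of (0,0), one-false, and (1,1)
#'   pairs.
#' @param snr common mean shift of nonnull test statistics.
#' @return An object of class \code{"mixture_model"} with elements
#'   \code{m0, m1, m2, m, snr} and proportions \code{pi0, pi1, pi2}.
#' @details Counts, not proportions, are stored: this removes any rounding
#'   ambiguity when proportions of an \eqn{m}-sized family are specified.
#' @examples
#' mixture_model(m1 = 10, snr = 2)  # the 10-pair single-false family
#' @export
mixture_model <- function(m0 = 0L, m1 = 0L, m2 = 0L, snr = 0) {
  counts <- c(m0, m1, m2)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("pair counts must be nonnegative integers", call. = FALSE)
  m <- sum(counts)
  if (m < 1L) stop("the family must contain at least one pair", call. = FALSE)
  if (snr < 0) stop("`snr` must be nonnegative", call. = FALSE)
  structure(list(m0 = as.integer(m0), m1 = as.integer(m1),
                 m2 = as.integer(m2), m = as.integer(m), snr = snr,
                 pi0 = m0 / m, pi1 = m1 / m, pi2 = m2 / m),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("mixture of %d hypothesis pairs: m0 = %d, m1 = %d, m2 = %d, snr = %g\n",
              x$m, x$m0, x$m1, x$m2, x$snr))
  invisible(x)
}

#' Conditional CDF of the maximum p-value after selection (one false component)
#'
#' For a pair with exactly one false component hypothesis, the distribution
#' of the maximum p-value \eqn{\bar p} conditional on the pair being selected
#' (\eqn{p_{(min)} \le c}) is
#' \deqn{P(\bar p \le u \mid p_{(min)} \le c) = \frac{u F(u)}{D}
#'       \quad (u \le c), \qquad
#'       \frac{c F(u) + u F(c) - c F(c)}{D} \quad (u \ge c),}
#' with \eqn{D = F(c) + c - cF(c)} the selection probability.  Evaluated at
#' the testing threshold this is the conditional null p-value distribution
#' \eqn{P_0(u, c)}; screening is harmless exactly when \eqn{P_0(u,c) \le u}.
#'
#' @param u evaluation point(s) in \code{[0, 1]} (values above 1 are capped).
#' @param c screening threshold in \code{(0, 1)}.
#' @param snr mean shift of the false component's statistic.
#' @return \eqn{P_0(u, c)}, vectorised over \code{u}.
#' @examples
#' cond_cdf_mixed(0.05, c = 0.005, snr = 2)
#' @export
cond_cdf_mixed <- function(u, c, snr) {
  check_theory_threshold(c)
  u <- pmin(u, 1)
  Fc <- gaussian_p_cdf(c, snr)
  D <- Fc + c - c * Fc
  if (D <= 0) stop("degenerate selection probability at c = ", c, call. = FALSE)
  Fu <- gaussian_p_cdf(u, snr)
  ifelse(u <= c, u * Fu / D, (c * Fu + u * Fc - c * Fc) / D)
}

#' Conditional CDF of the maximum p-value after selection (double null)
#'
#' For a pair with both component hypotheses true (two independent uniform
#' p-values), the maximum p-value conditional on selection has CDF
#' \deqn{\frac{u^2}{c(2-c)} \quad (u \le c), \qquad
#'       \frac{2u - c}{2 - c} \quad (u \ge c).}
#'
#' @inheritParams cond_cdf_mixed
#' @return The conditional CDF value(s), vectorised over \code{u}.
#' @export
cond_cdf_doublenull <- function(u, c) {
  check_theory_threshold(c)
  u <- pmin(u, 1)
  ifelse(u <= c, u^2 / (c * (2 - c)), (2 * u - c) / (2 - c))
}

#' Probability that a pair passes the screening
#'
#' Under independence a pair is selected unless both component p-values
#' exceed \eqn{c}: types (0,0), one-false, (1,1) give \eqn{2c - c^2},
#' \eqn{F(c) + c - cF(c)}, and \eqn{1 - (1 - F(c))^2} respectively.
#'
#' @param pair_type one of \code{"00"}, \code{"01"}, \code{"11"} (where
#'   \code{"01"} covers both one-false orderings).
#' @param c screening threshold in \code{(0, 1)}.
#' @param snr mean shift of false components (ignored for type \code{"00"}).
#' @return The selection probability.
#' @examples
#' selection_prob("01", c = 0.005, snr = 2)  # ~0.29
#' @export
selection_prob <- function(pair_type, c, snr = 0) {
  # base:: needed: `c` is the threshold argument in this scope
  pair_type <- match.arg(as.character(pair_type), base::c("01", "00", "11"))
  check_theory_threshold(c)
  Fc <- gaussian_p_cdf(c, snr)
  switch(pair_type,
         "00" = 2 * c - c^2,
         "01" = Fc + c - c * Fc,
         "11" = 1 - (1 - Fc)^2)
}

#' Exact distribution of the selected-set size
#'
#' Under independence, the number of selected pairs \eqn{|S(c)|} is the sum
#' of three independent binomials, one per pair type, with sizes
#' \eqn{(m_0, m_1, m_2)} and the type-specific selection probabilities.  The
#' PMF is computed by direct convolution.  When only one type is present
#' this reduces to a single binomial (e.g. \eqn{Bi(m, P_{sel})}).
#'
#' @param model a [mixture_model()].
#' @param c screening threshold in \code{(0, 1)}.
#' @return An object of class \code{"selection_size_pmf"}: list with
#'   \code{prob} (vector over \eqn{|S| = 0, \dots, m}), \code{threshold},
#'   and \code{mean}.
#' @export
selection_size_pmf <- function(model, c) {
  stopifnot(inherits(model, "mixture_model"))
  check_theory_threshold(c)
  probs <- base::c(selection_prob("00", c),       # `c` is the threshold here
                   selection_prob("01", c, model$snr),
                   selection_prob("11", c, model$snr))
  sizes <- base::c(model$m0, model$m1, model$m2)
  pmf <- 1
  for (j in 1:3) {
    if (sizes[j] > 0L)
      pmf <- convolve_pmf(pmf, stats::dbinom(0:sizes[j], sizes[j], probs[j]))
  }
  pmf <- pmf / sum(pmf)
  structure(list(prob = pmf, threshold = c,
                 mean = sum(pmf * seq_along(pmf)) - sum(pmf)),
            class = "selection_size_pmf")
}

convolve_pmf <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a))
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

#' Expected selected-set size
#'
#' \eqn{E|S(c)| = m_0 P_{sel}^{00} + m_1 P_{sel}^{01} + m_2 P_{sel}^{11}};
#' equals the mean of [selection_size_pmf()].
#'
#' @inheritParams selection_size_pmf
#' @return The expectation (a scalar).
#' @export
expected_selection_size <- function(model, c) {
  stopifnot(inherits(model, "mixture_model"))
  check_theory_threshold(c)
  model$m0 * selection_prob("00", c) +
    model$m1 * selection_prob("01", c, model$snr) +
    model$m2 * selection_prob("11", c, model$snr)
}

#' Finite-sample familywise error bound of the two-stage procedure
#'
#' Evaluates
#' \deqn{E\left[\left(1 - (1 - P_0(\alpha/|S|, c))^{|S|}\right)
#'       I\{|S| > 0\}\right]}
#' exactly over the selected-set size distribution: the sum over
#' \eqn{s = 1, \dots, m} of \eqn{P(|S| = s)\,[1 - (1 - P_0(\alpha/s, c))^s]}
#' with \eqn{P_0} from [cond_cdf_mixed()] and the size law from
#' [selection_size_pmf()].  This bounds the familywise error rate of the
#' fixed-threshold procedure, with equality exactly when every pair has one
#' false component (\eqn{\pi_1 = 1}), in which case it is the exact FWER.
#'
#' @param model a [mixture_model()].
#' @param c screening threshold in \code{(0, 1)}.
#' @param alpha testing level in \code{(0, 1)}.
#' @return The bound (a probability).
#' @examples
#' # exact FWER of the default-threshold procedure on 10 one-false pairs
#' fwer_bound(mixture_model(m1 = 10, snr = 2), c = 0.005, alpha = 0.05)
#' @export
fwer_bound <- function(model, c, alpha) {
  stopifnot(inherits(model, "mixture_model"))
  check_level(alpha)
  pmf <- selection_size_pmf(model, c)$prob
  s <- seq_len(model$m)
  p0 <- cond_cdf_mixed(pmin(alpha / s, 1), c, model$snr)
  sum(pmf[s + 1L] * (1 - exp(s * log1p(-p0))))
}

#' Power to reject a false pair, conditional on the selected-set size
#'
#' For a pair with both components false, the joint probability of passing
#' the screen and the Bonferroni test given \eqn{|S| = s} is
#' \deqn{2F(c)F(\alpha/s) - F(c)^2 \quad (cs \le \alpha), \qquad
#'       F(\alpha/s)^2 \quad (cs > \alpha),}
#' and 0 for \eqn{s = 0}.  Real-valued \eqn{s} is accepted so the same
#' expression serves the mean-size approximation.
#'
#' @param s selected-set size (nonnegative; may be non-integer).
#' @param c screening threshold in \code{(0, 1)}.
#' @param alpha testing level in \code{(0, 1)}.
#' @param snr mean shift of the false components.
#' @return The conditional rejection probability, vectorised over \code{s}.
#' @export
conditional_power <- function(s, c, alpha, snr) {
  check_theory_threshold(c)
  check_level(alpha)
  Fc <- gaussian_p_cdf(c, snr)
  Fa <- gaussian_p_cdf(pmin(alpha / pmax(s, 1e-300), 1), snr)
  out <- ifelse(c * s <= alpha, 2 * Fc * Fa - Fc^2, Fa^2)
  out[s <= 0] <- 0
  out
}

#' Unconditional power of the fixed-threshold procedure
#'
#' Averages [conditional_power()] over the distribution of the selected-set
#' size.  Two accountings of the focal false pair are available:
#' \describe{
#'   \item{\code{"decomposed"}}{(default) the focal (1,1) pair is removed
#'     from the size law and re-enters through the joint event: power
#'     \eqn{= \sum_t P(T = t)\, \mathrm{cp}(t + 1)} where \eqn{T} counts
#'     selections among the other \eqn{m - 1} pairs, so that \eqn{|S| =
#'     T + 1} whenever the focal pair is selected.  Exact for \eqn{m = 1}.}
#'   \item{\code{"conditioned"}}{the conditional power is averaged directly
#'     over the full-model size law \eqn{P(|S| = s)}, \eqn{s \ge 1},
#'     glossing the focal pair's own contribution to \eqn{|S|}.}
#' }
#' The two agree closely for moderate-to-large \eqn{m}.
#'
#' @param model a [mixture_model()] with \code{m2 >= 1}.
#' @param c screening threshold in \code{(0, 1)}.
#' @param alpha testing level in \code{(0, 1)}.
#' @param focal accounting of the focal pair, \code{"decomposed"} or
#'   \code{"conditioned"}.
#' @return The rejection probability for a (1,1) pair.
#' @export
power_exact <- function(model, c, alpha, focal = "decomposed") {
  stopifnot(inherits(model, "mixture_model"))
  focal <- match.arg(focal, base::c("decomposed", "conditioned"))
  if (model$m2 < 1L)
    stop("`model` must contain at least one (1,1) pair", call. = FALSE)
  if (focal == "conditioned") {
    pmf <- selection_size_pmf(model, c)$prob
    s <- seq_len(model$m)
    sum(pmf[s + 1L] * conditional_power(s, c, alpha, model$snr))
  } else {
    # m = 1 family: removing the focal pair leaves nothing, T = 0 surely
    pmf <- if (model$m == 1L) 1 else
      selection_size_pmf(mixture_model(model$m0, model$m1, model$m2 - 1L,
                                       snr = model$snr), c)$prob
    t <- seq_along(pmf) - 1L
    sum(pmf * conditional_power(t + 1, c, alpha, model$snr))
  }
}

#' Mean-size approximation to the familywise error rate
#'
#' Replaces the expectation over \eqn{|S|} by evaluation at its mean:
#' \deqn{\hat P(V \ge 1) = 1 - (1 - P_0(\alpha/\hat E, c))^{\hat E}},
#' \eqn{\hat E = E|S(c)|}, computed via \code{exp(\hat E \log(1 - P_0))}
#' for stability at small \eqn{P_0}.  Returns 0 when \eqn{\hat E = 0}.
#'
#' @inheritParams fwer_bound
#' @return The approximate familywise error rate.
#' @export
approx_fwer <- function(model, c, alpha) {
  stopifnot(inherits(model, "mixture_model"))
  check_level(alpha)
  E <- expected_selection_size(model, c)
  if (E <= 0) return(0)
  p0 <- cond_cdf_mixed(pmin(alpha / E, 1), c, model$snr)
  -expm1(E * log1p(-p0))
}

#' Mean-size approximation to the power
#'
#' [conditional_power()] evaluated at the real-valued mean selected-set size
#' \eqn{\hat E = E|S(c)|}.
#'
#' @inheritParams fwer_bound
#' @return The approximate rejection probability for a (1,1) pair.
#' @export
approx_power <- function(model, c, alpha) {
  stopifnot(inherits(model, "mixture_model"))
  conditional_power(expected_selection_size(model, c), c, alpha, model$snr)
}

#' Oracle selection threshold
#'
#' The power-maximising threshold subject to approximate familywise error
#' control is the smallest \eqn{c \in (0, \alpha]} with
#' \eqn{\hat P(V(c) \ge 1) \le \alpha} ([approx_fwer()]).  The feasible
#' boundary is bracketed on a log-spaced grid and refined by bisection.
#'
#' @param model a [mixture_model()].
#' @param alpha level in \code{(0, 1)}.
#' @param grid_size number of log-spaced scan points in
#'   \code{[alpha/(10 m), alpha]} (default 400).
#' @param tol absolute bisection tolerance on \eqn{c} (default 1e-10).
#' @return The threshold \eqn{c^*}, with attributes
#'   \code{power_maximal} (logical: \eqn{c^*} attains the best
#'   [approx_power()] over the scan grid, up to numerical tolerance) and
#'   \code{unconstrained_feasible} (logical: the smallest scanned \eqn{c}
#'   is already feasible, i.e. the constraint never binds).
#' @examples
#' oracle_threshold(mixture_model(m0 = 70, m1 = 25, m2 = 5, snr = 2),
#'                  alpha = 0.05)
#' @export
oracle_threshold <- function(model, alpha, grid_size = 400L, tol = 1e-10) {
  stopifnot(inherits(model, "mixture_model"))
  check_level(alpha)
  lo <- alpha / (10 * model$m)
  grid <- exp(seq(log(lo), log(alpha), length.out = grid_size))
  feas <- vapply(grid, function(cc) approx_fwer(model, cc, alpha) <= alpha,
                 logical(1))
  if (!any(feas))
    stop("no feasible threshold in (0, alpha]: the approximate familywise ",
         "error constraint cannot be met", call. = FALSE)
  first <- which(feas)[1L]
  if (first == 1L) {
    cstar <- grid[1L]
    unconstrained <- TRUE
  } else {
    # boundary lies in (grid[first-1], grid[first]]; approx_fwer decreases
    # through it, so bisect on feasibility
    lo_c <- grid[first - 1L]; hi_c <- grid[first]
    while (hi_c - lo_c > tol) {
      mid <- (lo_c + hi_c) / 2
      if (approx_fwer(model, mid, alpha) <= alpha) hi_c <- mid else lo_c <- mid
    }
    cstar <- hi_c
    unconstrained <- FALSE
  }
  pw <- vapply(grid[feas], function(cc) approx_power(model, cc, alpha),
               numeric(1))
  structure(cstar,
            power_maximal = approx_power(model, cstar, alpha) >=
              max(pw) - 1e-9,
            unconstrained_feasible = unconstrained)
}

#' Threshold solving the mean-size calibration equation
#'
#' For large families the feasibility boundary is well approximated by the
#' root of \eqn{g(c) = c\,E|S(c)| - \alpha}, which is strictly increasing in
#' \eqn{c}, so the root is unique.  Found by bisection on \eqn{(0, \alpha]};
#' if even \eqn{g(\alpha) < 0} (the root would exceed the testing level) the
#' threshold is capped at \eqn{\alpha} and flagged.
#'
#' @inheritParams oracle_threshold
#' @param tol absolute bisection tolerance (default 1e-12).
#' @return The root (a scalar), with attribute \code{capped} (logical).
#' @export
approx_oracle_threshold <- function(model, alpha, tol = 1e-12) {
  stopifnot(inherits(model, "mixture_model"))
  check_level(alpha)
  g <- function(cc) cc * expected_selection_size(model, cc) - alpha
  if (g(alpha) < 0)
    return(structure(alpha, capped = TRUE))
  lo <- 0; hi <- alpha
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (mid <= 0 || g(mid) < 0) lo <- mid else hi <- mid
  }
  structure((lo + hi) / 2, capped = FALSE)
}

check_theory_threshold <- function(c) {
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c <= 0 || c >= 1)
    stop("threshold `c` must be a single number in (0, 1)", call. = FALSE)
  invisible(c)
}
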