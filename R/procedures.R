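#' Screen hypothesis pairs on the minimum p-value
#'
#' First stage of the two-stage procedure: pair \eqn{i} is selected when its
#' minimum component p-value satisfies \eqn{p_{(min),i} \le c}.  Selection is
#' closed at the threshold (ties are selected).
#'
#' @param table a [pvalue_table()].
#' @param c screening threshold in \code{(0, 1]}.
#' @return An object of class \code{"selection_result"}: a list with
#'   \code{threshold}, logical \code{selected} per row, integer index set
#'   \code{set} (sorted), and \code{size} = \eqn{|S(c)|}.
#' @examples
#' tab <- pvalue_table(p1 = c(0.001, 0.2), p2 = c(0.3, 0.01))
#' screen(tab, c = 0.05)
#' @export
screen <- function(table, c) {
  table <- as_pvalue_table(table)
  check_threshold(c)
  sel <- table$pmin <= c
  structure(list(threshold = c, selected = sel,
                 set = which(sel), size = sum(sel)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("screening at c = %.4g: |S| = %d of %d pairs selected\n",
              x$threshold, x$size, length(x$selected)))
  invisible(x)
}

#' Two-stage procedure with a fixed screening threshold
#'
#' Screens pairs at threshold \code{c} on the minimum p-value, then applies a
#' Bonferroni correction over the survivors to the maximum p-value: the
#' adjusted p-value of a selected pair is \eqn{p^*_i = \min(|S| \bar p_i, 1)}
#' and unselected pairs get \eqn{p^*_i = 1}.  Pair \eqn{i} is rejected when
#' \eqn{p^*_i \le \alpha}, i.e. when \eqn{\bar p_i \le \alpha/|S|}.  The
#' recommended default screening threshold is \eqn{c = \alpha/m}.
#'
#' @param table a [pvalue_table()].
#' @param c screening threshold in \code{(0, 1]}; default \eqn{\alpha/m}.
#' @param alpha familywise error level in \code{(0, 1)}.
#' @return A \code{"screenmin_result"}: the input table with columns
#'   \code{selected}, \code{p_adjusted}, \code{rejected} appended, plus a
#'   \code{meta} attribute (procedure, thresholds, \eqn{|S|}).  Row order
#'   matches the input.
#' @details With \code{c = 1} every pair is selected and the procedure
#'   reduces exactly to [bonferroni_maxp()].  An empty selection yields all
#'   \eqn{p^* = 1} and no rejections.
#' @examples
#' tab <- pvalue_table(p1 = c(0.001, 0.01, 0.3), p2 = c(0.002, 0.9, 0.4))
#' screenmin_adjust(tab, c = 0.05, alpha = 0.05)
#' @export
screenmin_adjust <- function(table, c = NULL, alpha = 0.05) {
  table <- as_pvalue_table(table)
  check_level(alpha)
  if (is.null(c)) c <- alpha / nrow(table)
  sel <- screen(table, c)
  s <- sel$size
  p_adj <- rep(1, nrow(table))
  if (s > 0L)
    p_adj[sel$selected] <- pmin(s * table$pmax[sel$selected], 1)
  rejected <- sel$selected & p_adj <= alpha
  decision_result(table, sel, p_adj, rejected,
                  meta = list(procedure = "screenmin_fixed",
                              c = c, alpha = alpha, n_selected = s,
                              test_threshold = if (s > 0L) alpha / s else NA_real_))
}

#' Adaptive selection threshold
#'
#' Searches the grid \eqn{\{\alpha/m, \dots, \alpha/2, \alpha\}} for the
#' largest threshold \eqn{c} whose estimated per-family error
#' \eqn{c\,|S(c)|} does not exceed \eqn{\alpha}:
#' \deqn{\gamma = \max\{c \in \{\alpha/j : j = m, \dots, 1\} :
#'       c\,|S(c)| \le \alpha\}.}
#' The grid always contains a feasible point, since at \eqn{c = \alpha/m} the
#' product is at most \eqn{\alpha}.
#'
#' @param table a [pvalue_table()].
#' @param alpha familywise error level in \code{(0, 1)}.
#' @return The threshold \eqn{\gamma} (a scalar).
#' @examples
#' tab <- pvalue_table(p1 = c(0.001, 0.01, 0.02, 0.5), p2 = rep(1, 4))
#' adaptive_threshold(tab, alpha = 0.05)  # 0.05/3
#' @export
adaptive_threshold <- function(table, alpha = 0.05) {
  table <- as_pvalue_table(table)
  check_level(alpha)
  adaptive_threshold_pmin(table$pmin, alpha)
}

# grid scan on a bare pmin vector; shared with the vectorised harness.
# feasibility c_j |S(c_j)| <= budget with c_j = budget/j is count_j <= j,
# and count_j = |{pmin <= budget/j}| is nonincreasing in j while j increases,
# so the smallest feasible j gives the largest feasible grid point.
adaptive_threshold_pmin <- function(pmin_vec, budget) {
  m <- length(pmin_vec)
  grid <- pmin(budget / (m:1), 1)            # increasing in c
  counts <- findInterval(grid, sort(pmin_vec))
  feasible <- grid * counts <= budget + 1e-12
  grid[max(which(feasible))]
}

#' Adaptive single-threshold procedure
#'
#' Uses the adaptive threshold \eqn{\gamma} of [adaptive_threshold()] for
#' both stages: pair \eqn{i} is selected when \eqn{p_{(min),i} \le \gamma}
#' and rejected when \eqn{\bar p_i \le \gamma}.  Because the testing
#' threshold coincides with the screening threshold, the conditional null
#' distribution of the maximum p-value is dominated by the uniform at
#' \eqn{\gamma} and familywise error control holds in finite samples.
#'
#' @inheritParams adaptive_threshold
#' @return A \code{"screenmin_result"} (see [screenmin_adjust()]).  The
#'   reported adjusted p-values \eqn{p^*_i = \min(|S(\gamma)| \bar p_i, 1)}
#'   are a reporting convention only; the rejection decision is the
#'   threshold comparison \eqn{\bar p_i \le \gamma}.
#' @export
adaptive_procedure <- function(table, alpha = 0.05) {
  table <- as_pvalue_table(table)
  check_level(alpha)
  gamma <- adaptive_threshold_pmin(table$pmin, alpha)
  sel <- screen(table, gamma)
  s <- sel$size
  p_adj <- rep(1, nrow(table))
  if (s > 0L)
    p_adj[sel$selected] <- pmin(s * table$pmax[sel$selected], 1)
  rejected <- sel$selected & table$pmax <= gamma
  decision_result(table, sel, p_adj, rejected,
                  meta = list(procedure = "screenmin_adaptive",
                              gamma = gamma, alpha = alpha, n_selected = s,
                              test_threshold = gamma))
}

#' Estimate the per-family error rate of a screening threshold
#'
#' For a data-independent threshold \eqn{c} used in both stages, the product
#' \eqn{|S(c)|\,c} is an unbiased-or-upward-biased estimate of the expected
#' number of falsely rejected true union hypotheses, \eqn{E(V)}.
#'
#' @param selection a \code{"selection_result"} from [screen()].
#' @return The estimate \eqn{|S(c)| \cdot c}.
#' @export
pfer_estimate <- function(selection) {
  stopifnot(inherits(selection, "selection_result"))
  selection$size * selection$threshold
}

#' Single-threshold procedure controlling the per-family error rate
#'
#' Chooses the largest grid threshold \eqn{c_k \in \{k/m, \dots, k/2, k\}}
#' (grid points capped at 1) with \eqn{c_k\,|S(c_k)| \le k}, then uses it for
#' both selection and testing: reject pair \eqn{i} when
#' \eqn{\bar p_i \le c_k}.  The expected number of true union hypotheses
#' rejected is then bounded by the budget \eqn{k}.
#'
#' @param table a [pvalue_table()].
#' @param k per-family error budget, \eqn{k > 0} (e.g. \code{k = 1} tolerates
#'   one expected false positive).
#' @return A \code{"screenmin_result"} (see [screenmin_adjust()]); its
#'   \code{meta} records \eqn{c_k}.  Adjusted p-values are reported as
#'   \eqn{\min(|S| \bar p_i / k, 1)} for selected rows, again a reporting
#'   convention; the decision is \eqn{\bar p_i \le c_k}.
#' @export
pfer_procedure <- function(table, k = 1) {
  table <- as_pvalue_table(table)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0)
    stop("`k` must be a positive number", call. = FALSE)
  ck <- adaptive_threshold_pmin(table$pmin, k)
  sel <- screen(table, ck)
  s <- sel$size
  p_adj <- rep(1, nrow(table))
  if (s > 0L)
    p_adj[sel$selected] <- pmin(s * table$pmax[sel$selected] / k, 1)
  rejected <- sel$selected & table$pmax <= ck
  decision_result(table, sel, p_adj, rejected,
                  meta = list(procedure = "screenmin_pfer",
                              c_k = ck, k = k, n_selected = s,
                              test_threshold = ck))
}

#' One-stage Bonferroni on maximum p-values
#'
#' The classical baseline: the maximum of the two component p-values is a
#' valid p-value for the union hypothesis, so Bonferroni over all \eqn{m}
#' pairs rejects when \eqn{\bar p_i \le \alpha/m}, with adjusted p-value
#' \eqn{\min(m \bar p_i, 1)}.  Conservative when most pairs are double
#' nulls, which is what motivates screening.
#'
#' @inheritParams screenmin_adjust
#' @return A \code{"screenmin_result"}; every row counts as selected.
#' @export
bonferroni_maxp <- function(table, alpha = 0.05) {
  table <- as_pvalue_table(table)
  check_level(alpha)
  m <- nrow(table)
  p_adj <- pmin(m * table$pmax, 1)
  rejected <- p_adj <= alpha
  sel <- screen(table, 1)
  decision_result(table, sel, p_adj, rejected,
                  meta = list(procedure = "bonferroni_maxp",
                              alpha = alpha, n_selected = m,
                              test_threshold = alpha / m))
}

# ---- shared internals -------------------------------------------------------

as_pvalue_table <- function(table) {
  if (inherits(table, "pvalue_table")) return(table)
  if (is.data.frame(table) && all(c("p1", "p2") %in% names(table)))
    return(pvalue_table(table$p1, table$p2,
                        id = if ("id" %in% names(table)) table$id else NULL))
  stop("`table` must be a pvalue_table or a data frame with columns p1, p2",
       call. = FALSE)
}

check_threshold <- function(c) {
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c <= 0 || c > 1)
    stop("screening threshold `c` must be a single number in (0, 1]",
         call. = FALSE)
  invisible(c)
}

check_level <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("`alpha` must be a single number in (0, 1)", call. = FALSE)
  invisible(alpha)
}

decision_result <- function(table, sel, p_adj, rejected, meta) {
  out <- as.data.frame(table)
  out$selected <- sel$selected
  out$p_adjusted <- p_adj
  out$rejected <- rejected
  class(out) <- c("screenmin_result", "data.frame")
  attr(out, "meta") <- meta
  out
}

#' @export
print.screenmin_result <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("%s: %d of %d pairs selected, %d rejected\n",
              meta$procedure, meta$n_selected, nrow(x), sum(x$rejected)))
  thr <- meta[setdiff(names(meta), c("procedure", "n_selected"))]
  cat(paste(sprintf("  %s = %s", names(thr),
                    vapply(thr, function(v) format(v, digits = 4), "")),
            collapse = "\n"), "\n")
  if (any(x$rejected)) {
    cat("rejected pairs (sorted by adjusted p-value):\n")
    rej <- x[x$rejected, c("id", "pmin", "pmax", "p_adjusted")]
    print.data.frame(rej[order(rej$p_adjusted), ], row.names = FALSE)
  }
  invisible(x)
}
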