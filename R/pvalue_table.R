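#' Construct a table of component p-value pairs
#'
#' A \code{pvalue_table} holds the two component p-values of each union
#' hypothesis: \code{p1} for the first component (e.g. exposure--mediator
#' association, or study 1) and \code{p2} for the second (mediator--outcome,
#' or study 2).  The row-wise minimum \code{pmin} and maximum \code{pmax} are
#' derived on construction and recomputed whenever the table is rebuilt, so
#' they can never drift out of step with \code{p1}/\code{p2}.
#'
#' @param p1 numeric vector of p-values in \code{[0, 1]} for the first
#'   component hypothesis of each pair.
#' @param p2 numeric vector of p-values in \code{[0, 1]} for the second
#'   component hypothesis; same length as \code{p1}.
#' @param id optional row identifiers (coerced to character); defaults to
#'   \code{"1" ... "m"}.
#'
#' @return A \code{data.frame} of class \code{"pvalue_table"} with columns
#'   \code{id}, \code{p1}, \code{p2}, \code{pmin}, \code{pmax}.
#'
#' @details P-values exactly 0 or 1 are accepted: continuity is a modelling
#'   assumption of the theory, not an input constraint.  A 0 passes any
#'   screening threshold and a 1 is never rejected.
#'
#' @examples
#' pvalue_table(p1 = c(0.001, 0.9, 0.3), p2 = c(0.002, 0.01, 0.4))
#' @export
pvalue_table <- function(p1, p2, id = NULL) {
  p1 <- as.numeric(p1)
  p2 <- as.numeric(p2)
  if (length(p1) != length(p2))
    stop("`p1` and `p2` must have the same length", call. = FALSE)
  m <- length(p1)
  if (m < 1L) stop("a p-value table needs at least one row", call. = FALSE)
  check_pvals(p1, "p1")
  check_pvals(p2, "p2")
  if (is.null(id)) id <- as.character(seq_len(m))
  id <- as.character(id)
  if (length(id) != m)
    stop("`id` must have one entry per row", call. = FALSE)
  out <- data.frame(id = id, p1 = p1, p2 = p2,
                    pmin = pmin(p1, p2), pmax = pmax(p1, p2),
                    stringsAsFactors = FALSE)
  class(out) <- c("pvalue_table", "data.frame")
  out
}

check_pvals <- function(p, what) {
  bad <- which(is.na(p) | p < 0 | p > 1)
  if (length(bad))
    stop(sprintf("column `%s`: invalid p-values (NA or outside [0,1]) at row(s) %s",
                 what, paste(utils::head(bad, 5L), collapse = ", ")),
         call. = FALSE)
  invisible(p)
}

#' @export
print.pvalue_table <- function(x, ...) {
  cat(sprintf("p-value table: %d hypothesis pairs\n", nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10L), row.names = FALSE, ...)
  if (nrow(x) > 10L) cat(sprintf("... and %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Read a p-value table from delimited text
#'
#' Reads a TSV or CSV file with a header into a [pvalue_table()].  The
#' delimiter is inferred from the file extension (\code{.csv} = comma,
#' anything else = tab) unless given.  Lines starting with \code{#} are
#' treated as comments, so files written by [write_results()] round-trip.
#'
#' @param path path to the file.
#' @param p1,p2 names of the two p-value columns (default \code{"p1"},
#'   \code{"p2"}).
#' @param id optional name of an identifier column.
#' @param delim field delimiter; \code{NULL} (default) infers from the
#'   extension.
#' @return A [pvalue_table()].
#' @export
read_pvalue_table <- function(path, p1 = "p1", p2 = "p2", id = NULL,
                              delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim))
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (nrow(df) == 0L) stop("no data rows in ", path, call. = FALSE)
  for (col in c(p1, p2, id)) {
    if (!col %in% names(df))
      stop(sprintf("column `%s` not found in %s", col, path), call. = FALSE)
  }
  for (col in c(p1, p2)) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop(sprintf("column `%s`: non-numeric value at row(s) %s",
                     col, paste(utils::head(bad, 5L), collapse = ", ")),
             call. = FALSE)
      df[[col]] <- vn
    }
  }
  pvalue_table(p1 = df[[p1]], p2 = df[[p2]],
               id = if (!is.null(id)) df[[id]] else NULL)
}

#' Write procedure results to delimited text
#'
#' Emits one row per hypothesis pair with columns \code{id, p1, p2, pmin,
#' pmax, selected, p_adjusted, rejected}, preceded by \code{#}-prefixed
#' metadata lines recording the procedure, its thresholds and the selected-set
#' size.  Output is deterministic byte-for-byte for fixed inputs, and the
#' p-value columns round-trip through [read_pvalue_table()].
#'
#' @param decision a \code{screenmin_result} from [screenmin_adjust()],
#'   [adaptive_procedure()], [pfer_procedure()] or [bonferroni_maxp()].
#' @param path output path.
#' @param delim field delimiter (default tab).
#' @return \code{path}, invisibly.
#' @export
write_results <- function(decision, path, delim = "\t") {
  stopifnot(inherits(decision, "screenmin_result"))
  meta <- attr(decision, "meta")
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (key in names(meta))
    writeLines(sprintf("# %s: %s", key, format(meta[[key]], digits = 15)), con)
  tab <- as.data.frame(decision)
  tab$selected <- as.integer(tab$selected)
  tab$rejected <- as.integer(tab$rejected)
  utils::write.table(tab, con, sep = delim, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Metabolite p-value pairs from the fish-intake colorectal adenoma study
#'
#' The packaged fixture: minimum and maximum component p-values for the 22
#' circulating metabolites (out of 149 screened) that passed the adaptive
#' selection threshold in a case-control mediation analysis of fish intake
#' and colorectal adenoma risk.  For each metabolite, one component p-value
#' tests its association with daily fish intake and the other its association
#' with case-control status; \code{min_ind} records which association gave
#' the minimum (1 = fish intake, 2 = adenoma).
#'
#' @param as_table if \code{TRUE} (default) return a [pvalue_table()] with
#'   \code{p1}/\code{p2} reconstructed from \code{(pmin, pmax, min_ind)};
#'   otherwise the raw fixture data frame.
#' @return A [pvalue_table()] of 22 rows (or the raw data frame).  The
#'   attribute \code{m_total = 149} records the size of the full screened
#'   family, needed to form thresholds such as \code{0.05/149}; the unprinted
#'   127 metabolites all have \code{pmin} above the largest value here.
#' @examples
#' navy <- navy_metabolites()
#' sel <- screen(navy, c = 0.05 / attr(navy, "m_total"))
#' sel$size  # 13 pairs pass the default screening threshold
#' @export
navy_metabolites <- function(as_table = TRUE) {
  path <- system.file("extdata", "navy_metabolites.tsv", package = "screenmin",
                      mustWork = TRUE)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (!as_table) return(raw)
  p1 <- ifelse(raw$min_ind == 1L, raw$pmin, raw$pmax)
  p2 <- ifelse(raw$min_ind == 1L, raw$pmax, raw$pmin)
  out <- pvalue_table(p1 = p1, p2 = p2, id = raw$name)
  attr(out, "m_total") <- 149L
  out
}
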