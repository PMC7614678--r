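#' One source of pre-experimental information
#'
#' A historical summary holds a normal approximation `N(mean, variance)` of
#' the effect estimate from one pre-experimental source (a historical study
#' or an elicited expert opinion), together with its prior probability of
#' incommensurability `weight` in \[0, 1\]: `weight = 1` means no borrowing
#' from this source, `weight = 0` means no robustification (full borrowing).
#'
#' @param mean Effect estimate on the analysis scale (e.g. a log-odds ratio).
#' @param variance Variance of the estimate; must be positive.
#' @param weight Prior probability of incommensurability, in \[0, 1\].
#' @param label Optional identifier used in printed output and reports.
#' @return An object of class `cpssd_summary`.
#' @examples
#' historical_summary(-0.26, 0.25, weight = 0.15, label = "expert 1")
#' @export
historical_summary <- function(mean, variance, weight = 0.5, label = NULL) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean))
  if (!is.numeric(variance) || length(variance) != 1L || !is.finite(variance) ||
      variance <= 0) {
    stop("'variance' must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(weight) || length(weight) != 1L || is.na(weight) ||
      weight < 0 || weight > 1) {
    stop("'weight' must be a single number in [0, 1]", call. = FALSE)
  }
  structure(
    list(mean = as.numeric(mean), variance = as.numeric(variance),
         weight = as.numeric(weight),
         label = if (is.null(label)) NA_character_ else as.character(label)),
    class = "cpssd_summary"
  )
}

#' @export
print.cpssd_summary <- function(x, digits = 3, ...) {
  lab <- if (is.na(x$label)) "" else paste0(" [", x$label, "]")
  cat(sprintf("Historical summary%s: N(%s, %s), incommensurability weight w = %s\n",
              lab, format(x$mean, digits = digits),
              format(x$variance, digits = digits),
              format(x$weight, digits = digits)))
  invisible(x)
}

#' Build a list of historical summaries from a data frame
#'
#' Accepts a data frame with columns `mean`, `variance`, `w` (or `weight`)
#' and optionally `label`, as read e.g. from a CSV file.
#'
#' @param x A data frame, one row per source.
#' @return A list of [historical_summary()] objects.
#' @seealso [read_summaries()]
#' @export
as_historical_summaries <- function(x) {
  x <- as.data.frame(x)
  wcol <- if ("w" %in% names(x)) "w" else "weight"
  if (!all(c("mean", "variance") %in% names(x)) || !wcol %in% names(x)) {
    stop("need columns 'mean', 'variance' and 'w' (or 'weight')", call. = FALSE)
  }
  labs <- if ("label" %in% names(x)) as.character(x$label) else
    paste0("source", seq_len(nrow(x)))
  lapply(seq_len(nrow(x)), function(i) {
    historical_summary(x$mean[i], x$variance[i], x[[wcol]][i], labs[i])
  })
}

#' Read historical summaries from a CSV file
#'
#' The file must have columns `label`, `mean`, `variance`, `w`
#' (header required; `label` optional).
#'
#' @param path Path to a CSV file.
#' @return A list of [historical_summary()] objects.
#' @export
read_summaries <- function(path) {
  as_historical_summaries(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Normal summary of a log-odds ratio from a 2x2 table
#'
#' Converts a 2x2 table of counts (rows = arms A, B; columns = event,
#' no event) into the Wald normal summary of the log-odds ratio of
#' treatment benefit: mean `log(a d / (b c))`, variance
#' `1/a + 1/b + 1/c + 1/d`. If any cell is zero, the Haldane-Anscombe
#' continuity correction adds 0.5 to every cell; the returned object then
#' carries `attr(, "continuity_corrected") = TRUE`.
#'
#' @param table A 2x2 matrix (or length-4 vector, filled by row) of
#'   non-negative counts `rbind(c(a, b), c(c, d))` with `a` the events on
#'   arm A and `c` the events on arm B.
#' @param weight,label Passed on to [historical_summary()].
#' @return A [historical_summary()]; a zero row or column margin is an error.
#' @examples
#' log_odds_summary(rbind(c(10, 10), c(10, 10)))  # mean 0, variance 0.4
#' @export
log_odds_summary <- function(table, weight = 0.5, label = NULL) {
  if (!is.matrix(table)) table <- matrix(as.numeric(table), 2, 2, byrow = TRUE)
  if (!identical(dim(table), c(2L, 2L)) || any(table < 0) || any(!is.finite(table))) {
    stop("'table' must be a 2x2 matrix of non-negative counts", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("a whole row or column of the 2x2 table is zero; the log-odds ratio is undefined",
         call. = FALSE)
  }
  corrected <- any(table == 0)
  if (corrected) table <- table + 0.5
  m <- log(table[1, 1] * table[2, 2] / (table[1, 2] * table[2, 1]))
  v <- sum(1 / table)
  out <- historical_summary(m, v, weight, label)
  attr(out, "continuity_corrected") <- corrected
  out
}

#' Hellinger distance between two normal summaries
#'
#' Closed form for univariate normals:
#' `H^2 = 1 - sqrt(2*s_a*s_b / (s_a^2 + s_b^2)) * exp(-(m_a - m_b)^2 / (4*(s_a^2 + s_b^2)))`
#' with `s = sqrt(variance)`. The distance lies in \[0, 1\] and is a useful
#' discrepancy measure between pre-experimental sources when choosing the
#' incommensurability weights.
#'
#' @param a,b Either [historical_summary()] objects or numeric vectors
#'   `c(mean, variance)`.
#' @return The Hellinger distance, a number in \[0, 1\].
#' @examples
#' hellinger_distance(c(0, 1), c(1, 1))  # sqrt(1 - exp(-1/8))
#' @export
hellinger_distance <- function(a, b) {
  a <- .as_mv(a); b <- .as_mv(b)
  sa2 <- a[2]; sb2 <- b[2]
  h2 <- 1 - sqrt(2 * sqrt(sa2) * sqrt(sb2) / (sa2 + sb2)) *
    exp(-(a[1] - b[1])^2 / (4 * (sa2 + sb2)))
  # guard tiny negative round-off at a == b
  sqrt(max(h2, 0))
}

.as_mv <- function(x) {
  if (inherits(x, "cpssd_summary")) return(c(x$mean, x$variance))
  if (is.numeric(x) && length(x) == 2L) {
    if (x[2] <= 0) stop("variance must be positive", call. = FALSE)
    return(as.numeric(x))
  }
  stop("expected a historical_summary or c(mean, variance)", call. = FALSE)
}

#' Pairwise Hellinger distances between sources
#'
#' Reports the matrix of pairwise Hellinger distances between the normal
#' summaries of a set of sources. The matrix is offered as an aid when
#' eliciting the incommensurability weights; no automatic mapping from
#' distances to weights is imposed.
#'
#' @param sources A list of [historical_summary()] objects.
#' @return A symmetric K x K matrix with zero diagonal.
#' @export
hellinger_matrix <- function(sources) {
  K <- length(sources)
  out <- matrix(0, K, K)
  labs <- vapply(sources, function(s) s$label, character(1))
  if (!anyNA(labs)) dimnames(out) <- list(labs, labs)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i < j) out[i, j] <- out[j, i] <- hellinger_distance(sources[[i]], sources[[j]])
  }
  out
}
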