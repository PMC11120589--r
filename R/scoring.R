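#' Default optimization direction of each response
#'
#' A response is a *benefit* criterion when larger values are preferable
#' and a *cost* criterion when smaller values are. Radical-scavenging
#' IC50 values (DPPH, ABTS) are costs — a lower IC50 means a stronger
#' antioxidant — and titratable acidity is treated as a cost; all other
#' responses are benefits. Directions can be overridden per analysis.
#'
#' @return Named character vector (`"benefit"` or `"cost"`) over the
#'   13 responses.
#' @export
default_directions <- function() {
  dirs <- stats::setNames(rep("benefit", 13L), od_response_names())
  dirs[c("DPPH", "ABTS", "acidity")] <- "cost"
  dirs
}

#' Min-max normalize one criterion column
#'
#' Maps raw values onto `[0, 1]` relative to the column extremes:
#' benefit criteria as `(x - min) / (max - min)`, cost criteria as
#' `(max - x) / (max - min)`, so the preferable extreme always scores 1.
#' A constant column carries no ranking information; it scores 0.5
#' everywhere, with a warning.
#'
#' @param values numeric vector, length >= 2.
#' @param direction `"benefit"` or `"cost"`.
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' normalize_criterion(c(1, 2, 3), "cost")
#' @export
normalize_criterion <- function(values, direction = c("benefit", "cost")) {
  direction <- match.arg(direction)
  if (length(values) < 2L) stop("need at least 2 values to normalize")
  rng <- range(values)
  if (rng[1] == rng[2]) {
    warning("constant criterion column; all scores set to 0.5")
    return(rep(0.5, length(values)))
  }
  s <- (values - rng[1]) / (rng[2] - rng[1])
  if (direction == "cost") 1 - s else s
}

#' Multi-criteria standard scores for all runs
#'
#' Normalizes every criterion column with [normalize_criterion()] and
#' averages the scores per run into the standard score `SS` in `[0, 1]`.
#' Runs are ranked by decreasing SS; exact SS ties are broken by run id
#' (ascending) with a warning. The run maximizing SS is the recommended
#' processing condition.
#'
#' @param table an `od_design` table (or data frame with the columns).
#' @param directions named vector of `"benefit"`/`"cost"` per criterion;
#'   defaults to [default_directions()]. Its names select the criterion
#'   columns used.
#' @return Data frame of class `"od_scores"`: `run`, one normalized score
#'   column per criterion, `SS` and `rank`.
#' @examples
#' sc <- standard_scores(load_design_table("table1"))
#' sc$run[sc$rank == 1]
#' @export
standard_scores <- function(table, directions = default_directions()) {
  missing <- setdiff(names(directions), names(table))
  if (length(missing) > 0L) {
    stop("unknown criterion column(s): ", paste(missing, collapse = ", "))
  }
  bad <- setdiff(directions, c("benefit", "cost"))
  if (length(bad) > 0L) stop("directions must be 'benefit' or 'cost'")
  scores <- vapply(names(directions),
                   function(cn) normalize_criterion(table[[cn]], directions[[cn]]),
                   numeric(nrow(table)))
  SS <- rowMeans(scores)
  if (anyDuplicated(SS)) warning("tied standard scores; ties broken by run id")
  out <- data.frame(run = table$run, scores, SS = SS, check.names = FALSE)
  out$rank <- rank_by_ss(SS, table$run)
  attr(out, "directions") <- directions
  class(out) <- c("od_scores", "data.frame")
  out
}

# Descending SS, ties by ascending run id.
rank_by_ss <- function(SS, run) {
  ord <- order(-SS, run)
  rk <- integer(length(SS))
  rk[ord] <- seq_along(SS)
  rk
}

#' @export
print.od_scores <- function(x, ...) {
  best <- x[x$rank == 1L, ]
  cat(sprintf("Standard scores for %d runs; best run %s (SS = %.3f)\n",
              nrow(x), best$run, best$SS))
  print.data.frame(x, digits = 3, ...)
  invisible(x)
}
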