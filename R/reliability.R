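#' Lin's concordance correlation coefficient
#'
#' CCC = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2), with
#' population (n) denominators per Lin's original definition. Degenerate
#' conventions: both inputs constant with equal means gives 1; constant
#' input with unequal means gives 0.
#'
#' @param x,y numeric vectors of equal length >= 3 (the two readers'
#'   values of one feature across patients).
#' @return CCC in `[-1, 1]`.
#' @examples
#' linCcc(c(1, 2, 3), c(2, 3, 4)) # 4/7
#' @export
linCcc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L,
            all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) return(1)          # identical constants
  if (vx == 0 && vy == 0) return(0)  # constants at different levels
  2 * cxy / denom
}

#' Inter-reader reliability filter
#'
#' Computes Lin's CCC for every feature between the two readers' tables and
#' keeps features with CCC >= `cutoff` ("excellent" reproducibility). Kept
#' features are merged as the arithmetic mean of the two readers.
#'
#' @param table_r1,table_r2 numeric matrices (patients x features) with
#'   identical dimnames.
#' @param cutoff minimum CCC to keep a feature (default 0.8).
#' @return list with `report` (data.frame feature, ccc, kept), `merged`
#'   (patients x kept-features matrix) and `cutoff`.
#' @export
reliabilityFilter <- function(table_r1, table_r2, cutoff = 0.8) {
  if (!identical(colnames(table_r1), colnames(table_r2)) ||
      !identical(rownames(table_r1), rownames(table_r2)))
    petradStop("petrad_schema_mismatch",
               "reader tables must share patients and feature names")
  ccc <- vapply(seq_len(ncol(table_r1)),
                function(j) linCcc(table_r1[, j], table_r2[, j]),
                numeric(1))
  kept <- ccc >= cutoff
  merged <- (table_r1[, kept, drop = FALSE] +
             table_r2[, kept, drop = FALSE]) / 2
  list(report = data.frame(feature = colnames(table_r1), ccc = ccc,
                           kept = kept, stringsAsFactors = FALSE),
       merged = merged, cutoff = cutoff)
}
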