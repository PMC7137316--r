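#' Quantile binning of a continuous variable
#'
#' Labels each value by its empirical quantile bin (right-closed intervals,
#' the lowest bin including the minimum), for use as post-stratification
#' cells. Errors rather than silently merging when the data cannot support
#' `k` distinct bins.
#'
#' @param values Numeric vector, length at least `k`.
#' @param k Number of bins (default 4, i.e. quartiles).
#' @return Integer bin labels in `1:k`.
#' @examples
#' discretize(1:8, 4)  # 1 1 2 2 3 3 4 4
#' @export
discretize <- function(values, k = 4L) {
  if (k < 2L) stop("k must be at least 2")
  if (length(values) < k) stop("need at least k = ", k, " values")
  if (any(is.na(values))) stop("values must not contain NA")
  breaks <- quantile(values, probs = seq(0, 1, length.out = k + 1L),
                     names = FALSE, type = 7)
  if (anyDuplicated(breaks)) {
    stop("fewer than ", k, " distinct quantile bins in the data; ",
         "use a smaller k")
  }
  as.integer(cut(values, breaks = breaks, include.lowest = TRUE,
                 labels = FALSE))
}

#' Exact cell post-stratification weights
#'
#' Given the post-stratification cell of each sampled subject and the known
#' population share of every cell, returns weights
#' `population_share(cell) / sample_share(cell)` so that the weighted cell
#' shares reproduce the population shares exactly. The mean weight is 1.
#'
#' No collapsing or raking is attempted: a population cell with positive
#' share that is empty in the sample is an error, because its contribution
#' cannot be represented.
#'
#' @param sample_cells Vector of cell labels, one per sampled subject.
#' @param population_cell_shares Named numeric vector mapping every cell
#'   label to its population share; shares must sum to 1.
#' @return A weight vector aligned with `sample_cells`.
#' @examples
#' post_stratify(c("a", "b", "b", "b"), c(a = 0.5, b = 0.5))
#' @export
post_stratify <- function(sample_cells, population_cell_shares) {
  pop <- population_cell_shares
  if (is.null(names(pop)) || any(!nzchar(names(pop)))) {
    stop("population_cell_shares must be a named vector")
  }
  if (abs(sum(pop) - 1) > 1e-9) {
    stop("population cell shares must sum to 1 (got ", format(sum(pop)), ")")
  }
  cells <- as.character(sample_cells)
  unknown <- setdiff(unique(cells), names(pop))
  if (length(unknown)) {
    stop("sample cells absent from the population map: ",
         paste(unknown, collapse = ", "))
  }
  empty <- setdiff(names(pop)[pop > 0], unique(cells))
  if (length(empty)) {
    stop("population cells with positive share are empty in the sample: ",
         paste(empty, collapse = ", "),
         "; coarsen the cells before post-stratifying")
  }
  n <- length(cells)
  sample_share <- table(cells) / n
  w <- as.numeric(pop[cells] / sample_share[cells])
  w
}
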