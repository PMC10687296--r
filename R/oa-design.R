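# Mixed-level orthogonal array L36(2^11 x 3^12) and factorial-plan arithmetic.
#
# Level indices are 1-based throughout (L1 = 1, L2 = 2, L3 = 3), matching the
# usual Taguchi notation.  Columns W1..W11 are two-level factors, W12..W23
# three-level factors.

#' Load the L36(2^11 x 3^12) orthogonal array
#'
#' Returns the 36-run mixed-level Taguchi orthogonal array with 11 two-level
#' factors (`W1`--`W11`) and 12 three-level factors (`W12`--`W23`), stored as
#' package data.  The array is validated on every load: each two-level column
#' must contain each level 18 times, each three-level column each level 12
#' times, and every pair of columns must show every level combination equally
#' often (9 times for two-level pairs, 6 times for mixed pairs).  A corrupt
#' transcription therefore cannot be loaded silently.
#'
#' @param validate Logical; run the full balance validation (default `TRUE`).
#' @return An object of class `"orthogonal_array"`: a list with elements
#'   `cells` (36 x 23 integer matrix of level indices, rows named
#'   `ANN1`..`ANN36`), `n_levels` (integer vector of length 23, values 2 or 3)
#'   and `n_rows` (36).
#' @seealso [oa_balance()], [candidates_from_array()]
#' @examples
#' oa <- oa_l36()
#' oa$n_rows
#' oa$cells["ANN2", ]   # W1..W11 at L1, W12..W23 at L2
#' @export
oa_l36 <- function(validate = TRUE) {
  path <- system.file("extdata", "l36_array.csv", package = "annL36",
                      mustWork = TRUE)
  cells <- as.matrix(utils::read.csv(path, colClasses = "integer"))
  storage.mode(cells) <- "integer"
  rownames(cells) <- paste0("ANN", seq_len(nrow(cells)))
  oa <- structure(
    list(cells = cells,
         n_levels = c(rep(2L, 11L), rep(3L, 12L)),
         n_rows = nrow(cells)),
    class = "orthogonal_array")
  if (validate) {
    rep_ <- oa_balance(oa)
    if (nrow(rep_$violations) > 0L) {
      v <- rep_$violations[1L, ]
      stop("orthogonal array integrity failure: ", v$check, " at ", v$where,
           call. = FALSE)
    }
  }
  oa
}

#' @export
print.orthogonal_array <- function(x, ...) {
  cat(sprintf("Orthogonal array OA(%d, 2^%d 3^%d), %d columns\n",
              x$n_rows, sum(x$n_levels == 2L), sum(x$n_levels == 3L),
              ncol(x$cells)))
  invisible(x)
}

#' Balance report for an orthogonal array
#'
#' Counts level occurrences per column and level-pair occurrences for every
#' pair of a two-level column with any other column, and flags every
#' violation of the L36 balance invariants: 18/18 per two-level column,
#' 12/12/12 per three-level column, 9 per combination for two-level pairs and
#' 6 per combination for (two-level, three-level) pairs.
#'
#' @param oa An `"orthogonal_array"` as returned by [oa_l36()].
#' @return A list with `column_counts` (list of named level-count vectors per
#'   factor), `pair_counts` (data frame of pairwise combination counts) and
#'   `violations` (data frame with columns `check` and `where`; zero rows for
#'   a valid array).
#' @export
oa_balance <- function(oa) {
  stopifnot(inherits(oa, "orthogonal_array"))
  cells <- oa$cells
  p <- ncol(cells)
  factor_ids <- colnames(cells)
  viol <- list()
  note <- function(check, where) {
    viol[[length(viol) + 1L]] <<- data.frame(check = check, where = where,
                                             stringsAsFactors = FALSE)
  }

  column_counts <- vector("list", p)
  names(column_counts) <- factor_ids
  for (j in seq_len(p)) {
    L <- oa$n_levels[j]
    cnt <- tabulate(cells[, j], nbins = max(oa$n_levels))
    if (any(cells[, j] > L))
      note("cell value exceeds column level count", factor_ids[j])
    expected <- oa$n_rows / L
    if (any(cnt[seq_len(L)] != expected) || any(cnt[-seq_len(L)] != 0L))
      note("unbalanced column level counts", factor_ids[j])
    cc <- cnt[seq_len(L)]
    names(cc) <- paste0("L", seq_len(L))
    column_counts[[j]] <- cc
  }

  pair <- list()
  for (i in seq_len(p - 1L)) {
    for (j in seq(i + 1L, p)) {
      if (oa$n_levels[i] != 2L && oa$n_levels[j] != 2L) next
      tab <- table(factor(cells[, i], levels = seq_len(oa$n_levels[i])),
                   factor(cells[, j], levels = seq_len(oa$n_levels[j])))
      expected <- oa$n_rows / (oa$n_levels[i] * oa$n_levels[j])
      if (any(tab != expected))
        note("unbalanced pairwise combination counts",
             paste0(factor_ids[i], ":", factor_ids[j]))
      pair[[length(pair) + 1L]] <- data.frame(
        factor_a = factor_ids[i], factor_b = factor_ids[j],
        expected = expected, min_count = min(tab), max_count = max(tab),
        stringsAsFactors = FALSE)
    }
  }

  list(column_counts = column_counts,
       pair_counts = do.call(rbind, pair),
       violations = if (length(viol)) do.call(rbind, viol)
                    else data.frame(check = character(), where = character(),
                                    stringsAsFactors = FALSE))
}

#' Size of a full factorial plan
#'
#' Number of runs an exhaustive design needs: the product over all factors of
#' their level counts, `L^P` for `P` factors at a common `L` levels.  For the
#' 11 two-level and 12 three-level weights of the L36 network this is
#' 2^11 * 3^12 = 1,088,391,168 experiments, against which the 36-run
#' orthogonal plan is measured.
#'
#' Computed in double precision, which is exact here (the result is far below
#' 2^53); inputs that would overflow exact integer representation are
#' rejected.
#'
#' @param plan A `factorial_plan` from [factorial_plan()], or a bare integer
#'   vector of per-factor level counts.
#' @return The number of runs, as a double holding an exact integer.
#' @examples
#' full_factorial_size(factorial_plan(c(rep(2, 11), rep(3, 12))))
#' @export
full_factorial_size <- function(plan) {
  plan <- as_factorial_plan(plan)
  size <- prod(as.numeric(plan$n_levels))
  if (size > 2^53)
    stop("full factorial size exceeds exact double-precision range",
         call. = FALSE)
  size
}

#' Declare a full factorial plan
#'
#' @param n_levels Integer vector of level counts, one per factor; every
#'   entry must be at least 2.
#' @param factor_ids Optional character vector of factor names.
#' @return An object of class `"factorial_plan"`.
#' @export
factorial_plan <- function(n_levels, factor_ids = NULL) {
  if (length(n_levels) == 0L)
    stop("a factorial plan needs at least one factor", call. = FALSE)
  n_levels <- as.integer(n_levels)
  if (anyNA(n_levels) || any(n_levels < 2L))
    stop("every factor must have at least 2 levels", call. = FALSE)
  if (is.null(factor_ids)) factor_ids <- paste0("F", seq_along(n_levels))
  structure(list(n_levels = n_levels, factor_ids = factor_ids),
            class = "factorial_plan")
}

as_factorial_plan <- function(x) {
  if (inherits(x, "factorial_plan")) x else factorial_plan(x)
}

#' Fraction of the full factorial plan saved by a smaller design
#'
#' `1 - n_runs / full_factorial_size(plan)`: the proportion of exhaustive
#' experiments an `n_runs`-run design avoids.  For the L36 plan against the
#' 2^11 * 3^12 full factorial this is 1 - 36/1,088,391,168 = 0.99999996692...,
#' i.e. a 99.9999967% reduction.
#'
#' @param plan A `factorial_plan` or vector of level counts.
#' @param n_runs Number of runs of the reduced design; must be between 1 and
#'   the full factorial size.
#' @return The reduction fraction in `[0, 1]`.
#' @export
reduction_fraction <- function(plan, n_runs) {
  plan <- as_factorial_plan(plan)
  n_runs <- as.numeric(n_runs)
  if (length(n_runs) != 1L || is.na(n_runs) || n_runs < 1)
    stop("n_runs must be a single count >= 1", call. = FALSE)
  size <- full_factorial_size(plan)
  if (n_runs > size)
    stop("n_runs exceeds the full factorial size", call. = FALSE)
  1 - n_runs / size
}

#' Write / read an orthogonal array as CSV
#'
#' Plain-text round trip of the level-index matrix (header `W1..W23`, values
#' 1/2/3).  Reading re-validates the array, so an edited file that breaks
#' balance is rejected.
#'
#' @param oa An `"orthogonal_array"`.
#' @param path File path.
#' @return `write_oa_csv` returns `path` invisibly; `read_oa_csv` returns a
#'   validated `"orthogonal_array"`.
#' @export
write_oa_csv <- function(oa, path) {
  stopifnot(inherits(oa, "orthogonal_array"))
  utils::write.csv(as.data.frame(oa$cells), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_oa_csv
#' @export
read_oa_csv <- function(path) {
  cells <- as.matrix(utils::read.csv(path, colClasses = "integer"))
  storage.mode(cells) <- "integer"
  rownames(cells) <- paste0("ANN", seq_len(nrow(cells)))
  oa <- structure(
    list(cells = cells,
         n_levels = apply(cells, 2L, max),
         n_rows = nrow(cells)),
    class = "orthogonal_array")
  rep_ <- oa_balance(oa)
  if (nrow(rep_$violations) > 0L)
    stop("orthogonal array integrity failure: ",
         rep_$violations$check[1L], " at ", rep_$violations$where[1L],
         call. = FALSE)
  oa
}
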