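# Taguchi robust-design weight search.
#
# Per iteration: instantiate the 36 candidate networks given by the L36
# array and the current level table, score each by training MMRE on the
# decoded percent scale, record the winner row, additionally evaluate the
# main-effects (marginal-means) predicted-optimum combination as a
# confirmation run, cache the best candidate ever seen, re-centre the level
# table on it, and stop when the relative improvement of the best objective
# stays below the threshold.  The level spacing contracts geometrically;
# by default only after an iteration that failed to improve the incumbent
# (a mesh-adaptive schedule -- see the methods vignette for why the
# unconditional schedule stalls).

#' Search configuration
#'
#' @param delta0 Initial level spacing (default 1: two-level factors start
#'   at \{-1, +1\}, three-level at \{-1, 0, +1\}).
#' @param contraction Spacing contraction factor in (0, 1), default 0.5.
#' @param epsilon Stopping threshold on the improvement of the best
#'   objective (default 0.01).
#' @param stop_mode `"relative"` (improvement measured relative to the
#'   previous best, the default) or `"absolute"` (in MMRE percentage
#'   points).
#' @param patience Number of consecutive sub-threshold iterations required
#'   before stopping (default 2).
#' @param max_iterations Iteration cap (default 20).
#' @param adaptive If `TRUE` (default) the spacing contracts only after an
#'   iteration with no improvement; if `FALSE` it contracts every
#'   iteration.
#' @param confirmation Evaluate the marginal-means predicted-optimum
#'   combination each iteration (default `TRUE`).
#' @param split_ratio Training fraction for [run_search()]'s internal
#'   split.
#' @param seed Seed for the split.
#' @return An object of class `"search_config"`.
#' @export
search_config <- function(delta0 = 1, contraction = 0.5, epsilon = 0.01,
                          stop_mode = c("relative", "absolute"),
                          patience = 2L, max_iterations = 20L,
                          adaptive = TRUE, confirmation = TRUE,
                          split_ratio = 0.7, seed = 1L) {
  stop_mode <- match.arg(stop_mode)
  if (contraction <= 0 || contraction >= 1)
    stop("contraction must lie strictly between 0 and 1", call. = FALSE)
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  structure(list(delta0 = delta0, contraction = contraction,
                 epsilon = epsilon, stop_mode = stop_mode,
                 patience = as.integer(patience),
                 max_iterations = as.integer(max_iterations),
                 adaptive = adaptive, confirmation = confirmation,
                 split_ratio = split_ratio, seed = as.integer(seed)),
            class = "search_config")
}

#' Initial level table
#'
#' Current candidate level values and spacing for every factor.  With the
#' defaults, two-level factors start at `\{-1, +1\}` and three-level
#' factors at `\{-1, 0, +1\}`: every factor's levels span the same coded
#' interval `centre +/- delta0`.  After refinement (see [refine_levels()])
#' two-level factors sit at `centre +/- delta/2`.
#'
#' @param delta0 Initial spacing.
#' @param centre Numeric centre(s), length 1 or 23 (default 0).
#' @return An object of class `"level_table"`: list with `values` (list of
#'   23 ascending level vectors), `delta`, `iteration`.
#' @export
level_table <- function(delta0 = 1, centre = 0) {
  centre <- rep_len(centre, 23L)
  values <- lapply(seq_len(23L), function(j) {
    if (j <= 11L) centre[j] + c(-delta0, delta0)
    else centre[j] + c(-delta0, 0, delta0)
  })
  names(values) <- paste0("W", 1:23)
  structure(list(values = values, delta = delta0, iteration = 0L),
            class = "level_table")
}

#' Instantiate the 36 candidate weight vectors
#'
#' Candidate `i` sets every weight to the level value indexed by the
#' array cell `(i, factor)`.
#'
#' @param oa An `"orthogonal_array"` from [oa_l36()].
#' @param levels A `"level_table"`.
#' @return A 36 x 23 numeric matrix, rows named `ANN1`..`ANN36`.
#' @export
candidates_from_array <- function(oa, levels) {
  stopifnot(inherits(oa, "orthogonal_array"),
            inherits(levels, "level_table"))
  out <- matrix(NA_real_, nrow = oa$n_rows, ncol = 23L,
                dimnames = list(rownames(oa$cells), paste0("W", 1:23)))
  for (j in seq_len(23L)) {
    vals <- levels$values[[j]]
    idx <- oa$cells[, j]
    if (any(idx > length(vals)))
      stop("level index exceeds level table for factor W", j,
           call. = FALSE)
    out[, j] <- vals[idx]
  }
  out
}

#' Score candidate weight vectors by training MMRE
#'
#' @param candidates Numeric matrix of weight vectors (one per row).
#' @param dataset An `"ann_dataset"`.
#' @param rows Optional row indices of the dataset to evaluate on
#'   (training split); default all.
#' @return Numeric vector of MMRE objectives, one per candidate, in
#'   candidate order.
#' @export
evaluate_candidates <- function(candidates, dataset, rows = NULL) {
  stopifnot(inherits(dataset, "ann_dataset"))
  if (is.null(rows)) rows <- seq_len(nrow(dataset$X))
  X <- dataset$X[rows, , drop = FALSE]
  y <- dataset$y[rows]
  apply(candidates, 1L, function(w) {
    out <- build_network(w)
    mmre(y, dataset$decode(predict(out, X)))
  })
}

#' Contract the level table around a winner
#'
#' New spacing `delta' = contraction * delta` (when `contract = TRUE`);
#' each three-level factor gets `\{c - delta', c, c + delta'\}` and each
#' two-level factor `\{c - delta'/2, c + delta'/2\}` around the winner's
#' value `c` for that factor.  The iteration index is incremented.
#'
#' @param levels A `"level_table"`.
#' @param winner Numeric weight vector of length 23 (the centre).
#' @param config A `"search_config"` (supplies the contraction factor).
#' @param contract Apply the spacing contraction (default `TRUE`); with
#'   `FALSE` the table is re-centred at the current spacing.
#' @return The refined `"level_table"`.
#' @export
refine_levels <- function(levels, winner, config = search_config(),
                          contract = TRUE) {
  stopifnot(inherits(levels, "level_table"), length(winner) == 23L)
  delta <- if (contract) levels$delta * config$contraction else levels$delta
  values <- lapply(seq_len(23L), function(j) {
    c0 <- winner[j]
    if (j <= 11L) c0 + c(-delta / 2, delta / 2)
    else c0 + c(-delta, 0, delta)
  })
  names(values) <- paste0("W", 1:23)
  structure(list(values = values, delta = delta,
                 iteration = levels$iteration + 1L),
            class = "level_table")
}

# marginal-means predicted optimum: for each factor, the level whose mean
# objective over the 36 runs is smallest (classical Taguchi main-effects
# analysis, smaller-the-better)
marginal_optimum <- function(oa, levels, objectives) {
  vapply(seq_len(23L), function(j) {
    vals <- levels$values[[j]]
    means <- vapply(seq_along(vals), function(l)
      mean(objectives[oa$cells[, j] == l]), numeric(1L))
    vals[which.min(means)]
  }, numeric(1L))
}

#' Run the Taguchi robust-design weight search
#'
#' Fits the 23-weight network to a prevalence dataset by iterated
#' evaluation over the L36 array.  The dataset is split 70/30 (stratified
#' by year, seed-controlled) unless explicit training rows are given; the
#' objective is the MMRE of decoded predictions against actual percentages
#' on the training rows.  Ties between equal-objective candidates go to the
#' lowest row index.  The best candidate ever evaluated is cached and
#' returned even when the contracted grid no longer contains it, so the
#' best-so-far trace is non-increasing by construction.
#'
#' Non-convergence within `max_iterations` is not an error: the best-so-far
#' network is returned with `converged = FALSE`.
#'
#' @param dataset An `"ann_dataset"` from [ann_dataset()].
#' @param config A [search_config()].
#' @param train_rows Optional explicit training row indices (overrides the
#'   internal split).
#' @param oa The orthogonal array (default [oa_l36()]).
#' @return An object of class `"ann_l36_fit"`: list with `network` (best
#'   `"ann_l36_network"`), `best_objective` (training MMRE percent),
#'   `trace` (data frame: `iteration`, `winner_row`, `winner_objective`,
#'   `confirmation_objective`, `best_objective`, `delta`), `converged`,
#'   `iterations`, `train_rows`, `test_rows`, `config`.
#' @examples
#' ds <- ann_dataset(ann_training_table(), coding = "fuzzy")
#' fit <- run_search(ds, search_config(seed = 1))
#' fit$iterations
#' round(fit$best_objective, 4)
#' @export
run_search <- function(dataset, config = search_config(),
                       train_rows = NULL, oa = oa_l36()) {
  stopifnot(inherits(dataset, "ann_dataset"),
            inherits(config, "search_config"))
  if (is.null(train_rows)) {
    sp <- split_dataset(dataset, config$split_ratio, config$seed)
    train_rows <- sp$train
    test_rows <- sp$test
  } else {
    test_rows <- setdiff(seq_len(nrow(dataset$X)), train_rows)
  }

  levels <- level_table(config$delta0)
  best <- Inf
  best_w <- NULL
  stall <- 0L
  trace <- vector("list", config$max_iterations)
  converged <- FALSE

  for (k in seq_len(config$max_iterations)) {
    cand <- candidates_from_array(oa, levels)
    objs <- evaluate_candidates(cand, dataset, train_rows)
    win <- which.min(objs)          # ties: lowest row index (which.min)
    iter_best_obj <- objs[win]
    iter_best_w <- cand[win, ]

    conf_obj <- NA_real_
    if (config$confirmation) {
      conf_w <- marginal_optimum(oa, levels, objs)
      conf_obj <- evaluate_candidates(matrix(conf_w, nrow = 1L),
                                      dataset, train_rows)
      if (conf_obj < iter_best_obj) {
        iter_best_obj <- conf_obj
        iter_best_w <- conf_w
      }
    }

    prev_best <- best
    improved <- iter_best_obj < best
    if (improved) {
      best <- iter_best_obj
      best_w <- iter_best_w
    }

    trace[[k]] <- data.frame(
      iteration = k, winner_row = rownames(oa$cells)[win],
      winner_objective = objs[win],
      confirmation_objective = conf_obj,
      best_objective = best, delta = levels$delta)

    gain <- prev_best - best
    threshold <- if (config$stop_mode == "relative")
      config$epsilon * prev_best else config$epsilon
    small <- is.finite(prev_best) && gain <= threshold
    stall <- if (small) stall + 1L else 0L
    if (stall >= config$patience) { converged <- TRUE; break }

    contract <- if (config$adaptive) !improved else TRUE
    levels <- refine_levels(levels, best_w, config, contract = contract)
  }

  trace <- do.call(rbind, trace[!vapply(trace, is.null, logical(1L))])
  structure(list(network = build_network(best_w),
                 best_objective = best,
                 trace = trace,
                 converged = converged,
                 iterations = nrow(trace),
                 train_rows = train_rows,
                 test_rows = test_rows,
                 config = config),
            class = "ann_l36_fit")
}

#' @export
print.ann_l36_fit <- function(x, ...) {
  cat(sprintf(
    "ANN-L36 fit: %d iterations (%s), training MMRE %.4g%%\n",
    x$iterations,
    if (x$converged) "converged" else "iteration cap reached",
    x$best_objective))
  invisible(x)
}

#' Predict percent-scale prevalences from a fit
#'
#' @param object An `"ann_l36_fit"`.
#' @param dataset The `"ann_dataset"` to predict for (defaults must be
#'   supplied by the caller; the fit does not store the data).
#' @param rows Optional row indices.
#' @param ... Unused.
#' @return Numeric vector of decoded percent predictions.
#' @export
predict.ann_l36_fit <- function(object, dataset, rows = NULL, ...) {
  stopifnot(inherits(dataset, "ann_dataset"))
  if (is.null(rows)) rows <- seq_len(nrow(dataset$X))
  dataset$decode(predict(object$network,
                         dataset$X[rows, , drop = FALSE]))
}
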