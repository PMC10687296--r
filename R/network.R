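# The fixed-topology 23-weight feed-forward network.
#
# Topology: 10 inputs, 2 logistic hidden units without hidden bias, 1 linear
# output with bias.  The canonical weight map ties the array's column types
# to the architecture: the 11 two-level factors are the first hidden
# pathway (W1..W10 input weights, W11 output weight) and the 12 three-level
# factors the second pathway plus output bias (W12..W21 input weights, W22
# output weight, W23 bias).

#' Network topology constant
#'
#' @return A list describing the canonical 10-2-1 topology: input count,
#'   hidden count, the weight map, and the factor split (two-level factors
#'   `W1`--`W11`, three-level factors `W12`--`W23`).
#' @export
ann_l36_topology <- function() {
  list(n_inputs = 10L, n_hidden = 2L, n_outputs = 1L,
       n_weights = 23L,
       hidden_activation = "logistic sigmoid",
       output_activation = "identity",
       weight_map = c(
         "W1-W10  input -> hidden 1",
         "W11     hidden 1 -> output",
         "W12-W21 input -> hidden 2",
         "W22     hidden 2 -> output",
         "W23     output bias"),
       two_level_factors = paste0("W", 1:11),
       three_level_factors = paste0("W", 12:23))
}

#' Build a network from a 23-weight vector
#'
#' @param weights Numeric vector of length 23 (order `W1..W23`), all finite.
#' @return An immutable object of class `"ann_l36_network"`.  Networks built
#'   from equal weights produce bitwise-identical predictions.
#' @examples
#' net <- build_network(rep(0, 23))
#' predict(net, matrix(rnorm(10), nrow = 1))   # 0: zero bias, zero gains
#' @export
build_network <- function(weights) {
  weights <- as.numeric(weights)
  if (length(weights) != 23L)
    stop("expected exactly 23 weights, got ", length(weights),
         call. = FALSE)
  if (any(!is.finite(weights)))
    stop("weights must all be finite", call. = FALSE)
  names(weights) <- paste0("W", 1:23)
  structure(list(weights = weights), class = "ann_l36_network")
}

#' @export
print.ann_l36_network <- function(x, ...) {
  cat("ANN-L36 network (10-2-1, 23 weights)\n")
  print(round(x$weights, 6))
  invisible(x)
}

#' Forward pass
#'
#' Computes `W23 + W11 * s(sum(W1..W10 * f)) + W22 * s(sum(W12..W21 * f))`
#' where `s` is the logistic sigmoid and `f` the 10 input features.  The
#' output is on the coded target scale ("Est_Effort" before decoding) and is
#' bounded by `|W23| + |W11| + |W22|`.
#'
#' @param object An `"ann_l36_network"`.
#' @param features Numeric vector of length 10, or a matrix with 10 columns
#'   (one row per observation); all values finite.
#' @param ... Unused.
#' @return Numeric vector of coded-scale outputs, one per row.
#' @export
predict.ann_l36_network <- function(object, features, ...) {
  X <- if (is.matrix(features)) features else matrix(features, nrow = 1L)
  if (ncol(X) != 10L)
    stop("feature vectors must have length 10", call. = FALSE)
  if (any(!is.finite(X)))
    stop("non-finite feature value", call. = FALSE)
  w <- object$weights
  h1 <- stats::plogis(X %*% w[1:10])
  h2 <- stats::plogis(X %*% w[12:21])
  as.vector(w[23L] + w[11L] * h1 + w[22L] * h2)
}

#' Write / read network weights as CSV
#'
#' Two-column plain text (`factor`, `value`) with full precision
#' (`%.17g`), so that the round trip is bit-exact.
#'
#' @param net An `"ann_l36_network"`.
#' @param path File path.
#' @export
write_weights_csv <- function(net, path) {
  stopifnot(inherits(net, "ann_l36_network"))
  df <- data.frame(factor = names(net$weights),
                   value = sprintf("%.17g", net$weights))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_weights_csv
#' @export
read_weights_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "character"))
  w <- as.numeric(df$value)
  names(w) <- df$factor
  build_network(w[paste0("W", 1:23)])
}
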