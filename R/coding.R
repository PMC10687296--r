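# Coding (encoding/decoding) of model inputs and targets: triangular fuzzy
# partition with centroid defuzzification, logarithmic compression, min-max
# normalization and z-standardization.  All coders are monotone with exact
# inverses on their support.

#' Triangular fuzzy scheme
#'
#' A partition of a real interval into `n_terms` linguistic terms with
#' triangular membership functions.  Peaks are the term centres; the first
#' and last peak coincide with the support ends, and adjacent triangles
#' overlap so that memberships sum to exactly 1 everywhere on the support
#' (a Ruspini partition).
#'
#' @param support Numeric length-2 interval `c(min, max)`, `min < max`.
#' @param n_terms Number of terms (default 3: low / medium / high).
#' @param peaks Optional strictly increasing term centres; defaults to
#'   `n_terms` equally spaced points spanning the support.
#' @return An object of class `"fuzzy_scheme"`.
#' @examples
#' sc <- fuzzy_scheme(c(0, 100))
#' fuzzify(50, sc)      # (0, 1, 0)
#' defuzzify(c(0.5, 0.5, 0), sc)
#' @export
fuzzy_scheme <- function(support, n_terms = 3L, peaks = NULL) {
  stopifnot(length(support) == 2L, is.finite(support))
  if (support[1L] >= support[2L])
    stop("support must be a non-degenerate interval", call. = FALSE)
  n_terms <- as.integer(n_terms)
  if (n_terms < 2L) stop("need at least 2 terms", call. = FALSE)
  if (is.null(peaks))
    peaks <- seq(support[1L], support[2L], length.out = n_terms)
  if (length(peaks) != n_terms || any(diff(peaks) <= 0))
    stop("peaks must be strictly increasing, one per term", call. = FALSE)
  if (peaks[1L] != support[1L] || peaks[n_terms] != support[2L])
    stop("first and last peak must equal the support ends", call. = FALSE)
  structure(list(support = support, n_terms = n_terms, peaks = peaks),
            class = "fuzzy_scheme")
}

#' Fuzzify a crisp value
#'
#' Maps `x` to its membership degrees over the scheme's terms.  With
#' triangular partition membership the result is non-negative and sums to 1.
#' Values outside the support are an error; callers that want clamping must
#' clamp explicitly.
#'
#' @param x Numeric vector within the scheme support.
#' @param scheme A [fuzzy_scheme()].
#' @return A numeric matrix, one row per value of `x`, one column per term.
#' @export
fuzzify <- function(x, scheme) {
  stopifnot(inherits(scheme, "fuzzy_scheme"))
  if (any(!is.finite(x)))
    stop("non-finite input to fuzzify", call. = FALSE)
  if (any(x < scheme$support[1L] | x > scheme$support[2L]))
    stop("value outside fuzzy scheme support; clamp explicitly if intended",
         call. = FALSE)
  p <- scheme$peaks
  k <- scheme$n_terms
  m <- matrix(0, nrow = length(x), ncol = k,
              dimnames = list(NULL, paste0("term", seq_len(k))))
  for (j in seq_len(k)) {
    mj <- rep(0, length(x))
    if (j > 1L) {
      idx <- x >= p[j - 1L] & x <= p[j]
      mj[idx] <- (x[idx] - p[j - 1L]) / (p[j] - p[j - 1L])
    }
    if (j < k) {
      idx <- x > p[j] & x <= p[j + 1L]
      mj[idx] <- (p[j + 1L] - x[idx]) / (p[j + 1L] - p[j])
    }
    mj[x == p[j]] <- 1
    m[, j] <- mj
  }
  m
}

#' Defuzzify membership degrees
#'
#' Peak-weighted centroid: the term peaks averaged with the membership
#' degrees as weights.  For memberships produced by [fuzzify()] on a
#' triangular partition this inverts fuzzification exactly.
#'
#' @param memberships Numeric vector of length `n_terms`, or a matrix with
#'   one row per observation; non-negative, each row summing to > 0.
#' @param scheme A [fuzzy_scheme()].
#' @return Crisp value(s) within the scheme support.
#' @export
defuzzify <- function(memberships, scheme) {
  stopifnot(inherits(scheme, "fuzzy_scheme"))
  m <- if (is.matrix(memberships)) memberships else
    matrix(memberships, nrow = 1L)
  if (ncol(m) != scheme$n_terms)
    stop("membership length does not match the number of terms",
         call. = FALSE)
  if (any(m < 0)) stop("negative membership degree", call. = FALSE)
  s <- rowSums(m)
  if (any(s <= 0))
    stop("degenerate input: all-zero membership vector", call. = FALSE)
  out <- as.vector(m %*% scheme$peaks) / s
  out
}

#' Logarithmic coding
#'
#' `log_encode` maps `x` in `[0, x_max]` to `log(1 + x) / log(1 + x_max)` in
#' `[0, 1]`; `log_decode` inverts it.  Compresses the upper end of a skewed
#' non-negative scale, the usual motivation for a log coding of effort- or
#' rate-like targets.
#'
#' @param x Non-negative numeric vector (coded values in `[0, 1]` for
#'   `log_decode`).
#' @param x_max Positive scale maximum.
#' @return Coded values in `[0, 1]`, or decoded values in `[0, x_max]`.
#' @export
log_encode <- function(x, x_max) {
  if (!is.finite(x_max) || x_max <= 0)
    stop("x_max must be positive", call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0))
    stop("x must be non-negative and finite", call. = FALSE)
  if (any(x > x_max))
    stop("x exceeds x_max", call. = FALSE)
  log1p(x) / log1p(x_max)
}

#' @rdname log_encode
#' @export
log_decode <- function(x, x_max) {
  if (!is.finite(x_max) || x_max <= 0)
    stop("x_max must be positive", call. = FALSE)
  expm1(x * log1p(x_max))
}

#' Min-max normalization and z-standardization
#'
#' Affine coders with exact inverses.  `minmax_normalize` maps `[min, max]`
#' onto `[0, 1]`; `z_standardize` centres and scales by a mean and positive
#' standard deviation.
#'
#' @param x Numeric vector.
#' @param min,max Range bounds, `max > min`.
#' @param mean,sd Centre and positive scale.
#' @return Coded or decoded numeric vector.
#' @export
minmax_normalize <- function(x, min, max) {
  if (!is.finite(min) || !is.finite(max) || max <= min)
    stop("degenerate range: require max > min", call. = FALSE)
  (x - min) / (max - min)
}

#' @rdname minmax_normalize
#' @export
minmax_denormalize <- function(x, min, max) {
  if (!is.finite(min) || !is.finite(max) || max <= min)
    stop("degenerate range: require max > min", call. = FALSE)
  min + x * (max - min)
}

#' @rdname minmax_normalize
#' @export
z_standardize <- function(x, mean, sd) {
  if (!is.finite(sd) || sd <= 0) stop("sd must be positive", call. = FALSE)
  (x - mean) / sd
}

#' @rdname minmax_normalize
#' @export
z_destandardize <- function(x, mean, sd) {
  if (!is.finite(sd) || sd <= 0) stop("sd must be positive", call. = FALSE)
  mean + x * sd
}

#' Fit a coding configuration
#'
#' Binds one of the coding kinds (`"fuzzy"`, `"log"`, `"minmax"`, `"zscore"`,
#' `"identity"`) to the parameters it needs.  Parameters default to the data
#' supplied in `x`; percent-scale quantities are better coded on their
#' natural support by passing `support = c(0, 100)`, which makes the coding
#' independent of the training split and removes any need to clamp test
#' values.
#'
#' For the scalar pipeline the fuzzy code of a value is its defuzzified
#' position over normalised term positions `0, 1/(k-1), ..., 1`: the
#' membership-weighted centroid rescaled to `[0, 1]`.  With the default
#' equally spaced peaks this is piecewise linear and invertible.
#'
#' @param kind Coding kind.
#' @param x Numeric data used to fit parameters (ignored where `support`
#'   etc. are given).
#' @param support Optional `c(min, max)` support overriding the observed
#'   range (fuzzy / minmax / log upper bound).
#' @param n_terms Number of fuzzy terms.
#' @return An object of class `"coding_config"` with fields `kind` and
#'   `params`.
#' @seealso [code_values()], [decode_values()]
#' @export
coding_fit <- function(kind = c("fuzzy", "log", "minmax", "zscore",
                                "identity"),
                       x = NULL, support = NULL, n_terms = 3L) {
  kind <- match.arg(kind)
  params <- switch(
    kind,
    identity = list(),
    fuzzy = {
      if (is.null(support)) support <- range(x)
      list(scheme = fuzzy_scheme(support, n_terms = n_terms))
    },
    log = {
      x_max <- if (is.null(support)) max(x) else support[2L]
      if (!is.finite(x_max) || x_max <= 0)
        stop("log coding needs a positive maximum", call. = FALSE)
      list(x_max = x_max)
    },
    minmax = {
      if (is.null(support)) support <- range(x)
      if (support[2L] <= support[1L])
        stop("degenerate range for minmax coding", call. = FALSE)
      list(min = support[1L], max = support[2L])
    },
    zscore = {
      m <- mean(x); s <- stats::sd(x)
      if (!is.finite(s) || s <= 0)
        stop("degenerate sd for zscore coding", call. = FALSE)
      list(mean = m, sd = s)
    })
  structure(list(kind = kind, params = params), class = "coding_config")
}

#' Apply / invert a coding configuration
#'
#' `code_values` maps data onto the coded scale of a fitted
#' [coding_fit()] configuration; `decode_values` inverts it.  Both are
#' monotone non-decreasing, and `decode_values(code_values(x))` recovers `x`
#' to numerical precision for every kind.
#'
#' @param x Numeric vector.
#' @param config A `"coding_config"`.
#' @return Numeric vector on the coded (or original) scale.
#' @export
code_values <- function(x, config) {
  stopifnot(inherits(config, "coding_config"))
  p <- config$params
  switch(config$kind,
         identity = x,
         fuzzy = {
           sc <- p$scheme
           u <- seq(0, 1, length.out = sc$n_terms)
           as.vector(fuzzify(x, sc) %*% u)
         },
         log = log_encode(x, p$x_max),
         minmax = minmax_normalize(x, p$min, p$max),
         zscore = z_standardize(x, p$mean, p$sd))
}

#' @rdname code_values
#' @export
decode_values <- function(x, config) {
  stopifnot(inherits(config, "coding_config"))
  p <- config$params
  switch(config$kind,
         identity = x,
         fuzzy = {
           sc <- p$scheme
           # invert the piecewise-linear position map through the peaks
           u <- seq(0, 1, length.out = sc$n_terms)
           stats::approx(u, sc$peaks, xout = x, rule = 2L)$y +
             ifelse(x < 0, (x - 0) * (sc$peaks[2L] - sc$peaks[1L]) /
                      (u[2L] - u[1L]), 0) +
             ifelse(x > 1, (x - 1) *
                      (sc$peaks[sc$n_terms] - sc$peaks[sc$n_terms - 1L]) /
                      (u[2L] - u[1L]), 0)
         },
         log = log_decode(x, p$x_max),
         minmax = minmax_denormalize(x, p$min, p$max),
         zscore = z_destandardize(x, p$mean, p$sd))
}
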