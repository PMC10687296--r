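# Feature construction for the prevalence-estimation network.
#
# Each prevalence-table row maps to the fixed 10-slot feature vector:
#   1     survey-year indicator (0 = 2013, 1 = 2019; 0.5 if pooled)
#   2     gender code (0 = male, 1 = female, 0.5 = overall)
#   3-6   region one-hot (1/4 each when the row is not region-specific)
#   7     age-band midpoint / 100 (population mean when not age-specific)
#   8     base-rate logit: log-odds of the coded overall disease share
#   9     stratum share (stratum n / year total; 1 for overall rows)
#   10    constant 1
#
# Prevalences are shares, so the base rate enters on the logit scale -- the
# canonical scale for a share feeding a logistic unit.  Coded targets carry
# [0.05, 0.95] headroom, the usual convention for networks with saturating
# units.  A feature that is constant across the table carries no
# information; it is coded 0 (inert) because the explicit constant slot
# already provides a bias path.

age_midpoints <- function() {
  stats::setNames(c(19.5, 29.5, 39.5, 49.5, 59.5, 69.5, 79.5, 90), AGE_GROUPS)
}

squeeze01 <- function(x, lo, hi) lo + (hi - lo) * x
unsqueeze01 <- function(x, lo, hi) (x - lo) / (hi - lo)

#' Fixture table for fitting the ANN-L36 prevalence model
#'
#' The per-year overall prevalences of the most prevalent chronic diseases,
#' taken from the canonical (region-wise) transcribed table.  The survey
#' methodology models the ten most prevalent diseases; `n_diseases` selects
#' the top of the across-year mean prevalence ranking.
#'
#' @param n_diseases Number of diseases to keep (default 10).
#' @return Data frame with `disease`, `year`, `prevalence`, `base_rate`.
#' @export
ann_training_table <- function(n_diseases = 10L) {
  tab <- serbia_prevalence_table("table2")
  mean_prev <- tapply(tab$prevalence, tab$disease, mean)
  keep <- names(sort(mean_prev, decreasing = TRUE))[seq_len(n_diseases)]
  tab <- tab[tab$disease %in% keep, c("disease", "year", "prevalence")]
  tab$base_rate <- tab$prevalence   # overall rows: share equals the target
  tab <- tab[order(tab$year, -tab$prevalence), ]
  rownames(tab) <- NULL
  tab
}

#' Build a model dataset from a prevalence table
#'
#' Turns a prevalence table (one row per disease x stratum x year, percent
#' scale) into the network's feature matrix and coded targets.  The
#' `base_rate` column (overall percent share of the disease in that year) is
#' derived from the table itself when absent: the `n`-weighted mean
#' prevalence per disease and year.
#'
#' @param table Data frame with columns `disease`, `year`, `prevalence`
#'   (percent, positive), and optionally `region`, `age_group`, `gender`,
#'   `n`, `base_rate`.
#' @param coding Target coding kind: `"fuzzy"`, `"log"`, `"minmax"` or
#'   `"zscore"`.
#' @param headroom Coded-target range for the bounded codings (default
#'   `c(0.05, 0.95)`).
#' @param support Percent-scale coding support; defaults to the natural
#'   domain `c(0, 100)` so the coding is split-invariant.
#' @return An object of class `"ann_dataset"`: list with `X` (n x 10
#'   feature matrix), `y` (actual percent), `y_coded`, `decode` (function
#'   from coded scale to percent), `coding`, `meta` (the input rows).
#' @export
ann_dataset <- function(table, coding = c("fuzzy", "log", "minmax",
                                          "zscore"),
                        headroom = c(0.05, 0.95), support = c(0, 100)) {
  coding <- match.arg(coding)
  stopifnot(all(c("disease", "year", "prevalence") %in% names(table)))
  y <- table$prevalence
  if (any(!is.finite(y)) || any(y <= 0))
    stop("prevalence targets must be positive", call. = FALSE)

  n_rows <- nrow(table)
  wt <- if ("n" %in% names(table) && !anyNA(table$n)) table$n else
    rep(1, n_rows)

  if (!"base_rate" %in% names(table)) {
    key <- paste(table$disease, table$year)
    base_map <- tapply(seq_len(n_rows), key, function(i)
      stats::weighted.mean(y[i], wt[i]))
    table$base_rate <- as.numeric(base_map[key])
  }

  # raw feature slots before the inert-constant rule
  f_year <- if (all(is.na(table$year))) rep(0.5, n_rows) else
    ifelse(is.na(table$year), 0.5, as.numeric(table$year == 2019))
  f_gender <- if ("gender" %in% names(table))
    ifelse(table$gender == "female", 1,
           ifelse(table$gender == "male", 0, 0.5)) else rep(0.5, n_rows)
  reg <- if ("region" %in% names(table)) table$region else
    rep("overall", n_rows)
  f_region <- sapply(REGIONS, function(r)
    ifelse(reg == "overall", 0.25, as.numeric(reg == r)))
  if (n_rows == 1L) f_region <- matrix(f_region, nrow = 1L)
  mid <- age_midpoints()
  f_age <- if ("age_group" %in% names(table))
    ifelse(table$age_group %in% AGE_GROUPS,
           mid[table$age_group] / 100, mean(mid) / 100) else
    rep(mean(mid) / 100, n_rows)
  f_share <- if ("stratum_share" %in% names(table)) table$stratum_share else
    rep(1, n_rows)

  lo <- headroom[1L]; hi <- headroom[2L]
  f_base <- stats::qlogis(squeeze01(table$base_rate / 100, lo, hi))

  X <- cbind(f_year, f_gender, f_region, f_age, f_base, f_share,
             rep(1, n_rows))
  colnames(X) <- c("year", "gender", paste0("region_", seq_len(4L)),
                   "age", "base_rate_logit", "stratum_share", "const")

  # inert-constant rule: a constant informative slot is coded 0
  for (j in seq_len(9L)) if (length(unique(X[, j])) == 1L) X[, j] <- 0

  cfg <- coding_fit(coding, x = y, support = support)
  code <- code_values(y, cfg)
  bounded <- coding %in% c("fuzzy", "log", "minmax")
  y_coded <- if (bounded) squeeze01(code, lo, hi) else code
  decode <- if (bounded) {
    function(cc) decode_values(unsqueeze01(cc, lo, hi), cfg)
  } else {
    function(cc) decode_values(cc, cfg)
  }

  structure(list(X = X, y = y, y_coded = y_coded, decode = decode,
                 coding = cfg, headroom = headroom, meta = table),
            class = "ann_dataset")
}

#' @export
print.ann_dataset <- function(x, ...) {
  cat(sprintf("ann_dataset: %d rows, target coding '%s'\n",
              nrow(x$X), x$coding$kind))
  invisible(x)
}

#' Seeded train/test split, stratified by year
#'
#' @param dataset An `"ann_dataset"`.
#' @param ratio Training fraction (default 0.7).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_dataset <- function(dataset, ratio = 0.7, seed = 1L) {
  stopifnot(inherits(dataset, "ann_dataset"))
  yrs <- dataset$meta$year
  yrs[is.na(yrs)] <- 0L
  set.seed(as.integer(seed))
  train <- unlist(lapply(split(seq_along(yrs), yrs), function(idx) {
    k <- max(1L, round(length(idx) * ratio))
    sort(sample(idx, k))
  }), use.names = FALSE)
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(yrs), train))
}
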