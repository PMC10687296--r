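# Survey data model and synthetic cohort generation.
#
# The generator emulates the composition of the two Serbian national health
# surveys (2013, 2019): per-year totals, region / age-band / gender margins,
# and per-disease prevalences.  Cell counts are allocated by independent
# margins with largest-remainder rounding; disease flags are independent
# Bernoulli draws per respondent.

REGIONS <- c("Belgrade", "Vojvodina", "Sumadija-West", "East-South")
AGE_GROUPS <- c("15-24", "25-34", "35-44", "45-54", "55-64", "65-74",
                "75-84", "85+")
GENDERS <- c("male", "female")
YEARS <- c(2013L, 2019L)

#' The seventeen tracked chronic non-communicable diseases
#'
#' In the row order of the source prevalence tables.
#' @return Character vector of length 17.
#' @export
ncd_diseases <- function() {
  c("Asthma", "Chronic lung diseases", "Myocardial infarction",
    "Coronary heart disease", "Hypertension", "Stroke", "Arthrosis",
    "Lower back diseases", "Cervical spine diseases", "Diabetes mellitus",
    "Allergies", "Liver cirrhosis", "Urinary track diseases",
    "Kidney diseases", "Depression", "High Cholesterol", "Cancer")
}

# machine-safe column names for disease flags
disease_cols <- function() {
  gsub("[^A-Za-z0-9]+", "_", tolower(ncd_diseases()))
}

#' Transcribed stratified prevalence tables
#'
#' The published prevalence percentages: per-disease values by survey year
#' from the region-wise and age-wise regression tables, per-gender pooled
#' values, and the narrative percentages (including the variants where the
#' publication is internally inconsistent, e.g. hypertension 2019 printed as
#' 32.2, 32.3, 32.4 and 33.2 in different places).  The `source` column
#' records where each number is printed; the region-wise table is the
#' canonical source used by the modelling helpers.
#'
#' @param source Optional filter (`"table2"`, `"table3"`, `"table4"`,
#'   `"section4"`, `"abstract"`).
#' @return Data frame with columns `disease`, `panel`, `group`, `year`,
#'   `prevalence`, `source`.
#' @export
serbia_prevalence_table <- function(source = NULL) {
  path <- system.file("extdata", "serbia_prevalence.csv",
                      package = "annL36", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(source)) df <- df[df$source %in% source, ]
  df
}

#' Stratum parameters of the Serbian survey cohort
#'
#' The printed survey composition: per-year totals (14623 in 2013, 13178 in
#' 2019, 27801 together), gender, region and age-band counts, plus the
#' per-year, per-disease prevalence probabilities from the canonical
#' prevalence table.  These are the generator's default parameters.
#'
#' @return An object of class `"stratum_params"`: list with `margins` (data
#'   frame of margin counts), `disease_prob` (17 x 2 matrix of Bernoulli
#'   probabilities, diseases x years) and `total`.
#' @export
serbia_stratum_params <- function() {
  path <- system.file("extdata", "serbia_strata.csv",
                      package = "annL36", mustWork = TRUE)
  margins <- utils::read.csv(path, stringsAsFactors = FALSE)
  prev <- serbia_prevalence_table("table2")
  pr <- matrix(NA_real_, nrow = 17L, ncol = 2L,
               dimnames = list(ncd_diseases(), as.character(YEARS)))
  for (yr in YEARS) {
    sub <- prev[prev$year == yr, ]
    pr[sub$disease, as.character(yr)] <- sub$prevalence / 100
  }
  structure(list(margins = margins, disease_prob = pr,
                 total = sum(margins$count[margins$margin == "year"])),
            class = "stratum_params")
}

#' Largest-remainder integer allocation
#'
#' Splits `n` into integers proportional to `shares`, summing exactly to
#' `n`.  Ties in the fractional remainders are broken by first index.
#'
#' @param n Total count.
#' @param shares Non-negative weights.
#' @return Integer vector summing to `n`.
#' @export
allocate_counts <- function(n, shares) {
  if (any(shares < 0) || sum(shares) <= 0)
    stop("shares must be non-negative with positive sum", call. = FALSE)
  q <- n * shares / sum(shares)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(q - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

margin_counts <- function(params, margin) {
  m <- params$margins[params$margins$margin == margin, ]
  stats::setNames(m$count, m$level)
}

#' Generate a synthetic survey cohort
#'
#' One row per respondent: survey `year`, `region`, `age_group`, `gender`
#' and 17 binary disease indicators.  Stratum cell counts are allocated per
#' year from the region, age and gender margins treated as independent
#' (largest-remainder rounding keeps the totals exact); each disease flag is
#' an independent Bernoulli draw with that year's disease probability
#' (overridable per call).  A fixed seed reproduces the cohort exactly.
#'
#' @param params A `"stratum_params"`; defaults to the Serbian survey
#'   composition.
#' @param seed Integer seed.
#' @param years Survey years to generate (default both).
#' @param n Optional total cohort size overriding the margin totals (margins
#'   are rescaled).
#' @param disease_prob Optional named probability override; either a single
#'   per-disease named vector applied to all years, or a matrix like
#'   `params$disease_prob`.
#' @return Data frame of `CohortRecord`s with `n` rows.
#' @examples
#' cohort <- generate_cohort(seed = 1, years = 2013, n = 500)
#' mean(cohort$hypertension)          # ~ 0.34
#' @export
generate_cohort <- function(params = serbia_stratum_params(), seed = 1L,
                            years = YEARS, n = NULL,
                            disease_prob = NULL) {
  stopifnot(inherits(params, "stratum_params"))
  pr <- params$disease_prob
  if (!is.null(disease_prob)) {
    if (is.matrix(disease_prob)) {
      pr <- disease_prob
    } else {
      pr <- matrix(rep(disease_prob, 2L), ncol = 2L,
                   dimnames = list(names(disease_prob),
                                   as.character(YEARS)))
    }
  }
  if (any(pr < 0 | pr > 1, na.rm = TRUE))
    stop("disease probabilities must lie in [0, 1]", call. = FALSE)

  year_counts <- margin_counts(params, "year")[as.character(years)]
  if (!is.null(n)) year_counts <- allocate_counts(n, year_counts)
  names(year_counts) <- as.character(years)

  reg_share <- margin_counts(params, "region")
  age_share <- margin_counts(params, "age_group")
  sex_share <- margin_counts(params, "gender")

  set.seed(as.integer(seed))
  out <- vector("list", length(years))
  for (k in seq_along(years)) {
    yr <- years[k]
    ny <- year_counts[[as.character(yr)]]
    # cell counts: nested largest-remainder allocation region > age > gender
    reg_n <- allocate_counts(ny, reg_share)
    rows <- vector("list", length(REGIONS))
    for (i in seq_along(REGIONS)) {
      age_n <- allocate_counts(reg_n[i], age_share)
      cell <- lapply(seq_along(AGE_GROUPS), function(j) {
        if (age_n[j] == 0L) return(NULL)
        sex_n <- allocate_counts(age_n[j], sex_share)
        data.frame(year = yr, region = REGIONS[i],
                   age_group = AGE_GROUPS[j],
                   gender = rep(GENDERS, times = sex_n),
                   stringsAsFactors = FALSE)
      })
      rows[[i]] <- do.call(rbind, cell)
    }
    df <- do.call(rbind, rows)
    flags <- matrix(0L, nrow = nrow(df), ncol = 17L,
                    dimnames = list(NULL, disease_cols()))
    probs <- pr[, as.character(yr)]
    for (d in seq_len(17L))
      flags[, d] <- stats::rbinom(nrow(df), 1L, probs[d])
    out[[k]] <- cbind(df, as.data.frame(flags))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate a cohort into a prevalence table
#'
#' Prevalence percent = 100 * positives / stratum size for every disease in
#' each stratum defined by the `by` keys (always including `year`).  Empty
#' strata are dropped with a warning.
#'
#' @param records Cohort data frame from [generate_cohort()] (or a microdata
#'   CSV read back with the same columns).
#' @param by Character vector of stratification columns among
#'   `"region"`, `"age_group"`, `"gender"`; empty for overall-by-year.
#' @return Data frame with the stratum keys, `disease`, `year`,
#'   `prevalence` (percent) and `n` (denominator).
#' @export
aggregate_prevalence <- function(records, by = character()) {
  if (nrow(records) == 0L) stop("no records to aggregate", call. = FALSE)
  bad <- setdiff(by, c("region", "age_group", "gender"))
  if (length(bad))
    stop("unknown stratification key: ", paste(bad, collapse = ", "),
         call. = FALSE)
  keys <- c("year", by)
  dcols <- disease_cols()
  split_idx <- interaction(records[keys], drop = TRUE, lex.order = TRUE)
  pieces <- lapply(split(seq_len(nrow(records)), split_idx), function(idx) {
    strat <- records[idx[1L], keys, drop = FALSE]
    pos <- colSums(records[idx, dcols, drop = FALSE])
    data.frame(strat, disease = ncd_diseases(),
               prevalence = 100 * as.numeric(pos) / length(idx),
               n = length(idx), row.names = NULL,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  res
}

#' Round half away from zero
#'
#' Decimal rounding in the "half-up" convention used by the printed tables
#' (R's `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
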