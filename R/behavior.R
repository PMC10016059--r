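#' Simulate test-phase response records
#'
#' Translates generator outcomes into the two-step old/new judgments a
#' participant produces at test: an item response for every test trial and,
#' following an "old" item response, a pair response.  New-object trials
#' receive false alarms at `params$false_alarm_rate`.
#'
#' @param design A [generate_design()] object.
#' @param meta Matching [simulate_behavior()] table (same subject).
#' @param params A [sim_params()] list.
#' @param seed Optional integer seed.
#' @return Data frame, one row per test trial: subject, condition,
#'   item_is_old, item_response, pair_response, pair_is_correct.
#' @export
simulate_responses <- function(design, meta, params = sim_params(), seed = NULL) {
  stopifnot(inherits(design, "study_design"), is.data.frame(meta))
  with_seed(seed, {
    tst <- design$test
    out <- meta$outcome[match(tst$object, meta$object)]
    n <- nrow(tst)
    item_resp <- rep(NA_character_, n)
    pair_resp <- rep(NA_character_, n)
    pair_ok <- rep(NA, n)
    old <- tst$item_old
    item_resp[old] <- ifelse(out[old] == "miss", "new", "old")
    hit <- old & item_resp == "old"
    mm <- tst$condition %in% c("match", "mismatch")
    correct_pair <- ifelse(tst$condition == "match", "old", "new")
    po <- hit & mm
    pair_ok[po] <- out[po] == "pair"
    pair_resp[po] <- ifelse(pair_ok[po], correct_pair[po],
                            ifelse(correct_pair[po] == "old", "new", "old"))
    # old-new trials: the pair is always new; pair correctness is undefined
    pon <- hit & tst$condition == "old_new"
    pair_resp[pon] <- "new"
    new_idx <- which(!old)
    fa <- new_idx[stats::runif(length(new_idx)) < params$false_alarm_rate]
    item_resp[new_idx] <- "new"
    item_resp[fa] <- "old"
    pair_resp[fa] <- "new"
    data.frame(
      subject = meta$subject[1], trial = tst$trial, condition = tst$condition,
      item_is_old = old, item_response = item_resp,
      pair_response = pair_resp, pair_is_correct = pair_ok,
      stringsAsFactors = FALSE
    )
  })
}

#' Categorize test responses into memory outcomes
#'
#' Maps each response record to `miss` ("new" response to an old item),
#' `item_only` (item hit followed by an incorrect pair response), `pair`
#' (item hit followed by a correct pair response) or `excluded`.  Only
#' match and mismatch trials enter the analysis; trials from any other
#' condition, and old-item trials with a missing item response (or a missing
#' pair response after an item hit), are `excluded`.
#'
#' @param records Data frame of response records (see
#'   [simulate_responses()] for the column contract).
#' @return Factor with levels miss, item_only, pair, excluded, one per row.
#' @export
categorize <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("condition", "item_response", "pair_is_correct") %in% names(records)))
  out <- rep("excluded", nrow(records))
  mm <- records$condition %in% c("match", "mismatch")
  has_item <- !is.na(records$item_response)
  out[mm & has_item & records$item_response == "new"] <- "miss"
  hit <- mm & has_item & records$item_response == "old"
  out[hit & !is.na(records$pair_is_correct) & !records$pair_is_correct] <- "item_only"
  out[hit & !is.na(records$pair_is_correct) & records$pair_is_correct] <- "pair"
  factor(out, levels = c("miss", "item_only", "pair", "excluded"))
}

#' Item-memory chance-level check
#'
#' Computes the proportion of correct item responses across the three
#' old-item conditions (match, mismatch, old-new) and compares it against
#' the chance level `response_probability * n_old_items / n_test_trials`
#' (0.5 x 250/400 = 0.31 at study scale).  A subject is kept only when
#' accuracy is strictly above the threshold; ties are excluded.
#'
#' @param records One subject's response records across all test conditions.
#' @param response_probability Assumed probability of an "old" item response
#'   under guessing (default 0.5).
#' @return List with `accuracy`, `threshold` and `keep`.
#' @export
item_chance_check <- function(records, response_probability = 0.5) {
  stopifnot(is.data.frame(records))
  n_total <- nrow(records)
  old <- records$item_is_old & records$condition %in% c("match", "mismatch", "old_new")
  answered <- old & !is.na(records$item_response)
  if (sum(answered) == 0L || n_total == 0L)
    stop("item accuracy undefined: no answered old-item trials")
  accuracy <- mean(records$item_response[answered] == "old")
  threshold <- response_probability * sum(old) / n_total
  list(accuracy = accuracy, threshold = threshold, keep = accuracy > threshold)
}

#' Minimum-trials-per-condition filter
#'
#' Subjects with fewer than `min_trials` trials in any of the three memory
#' outcome conditions are excluded from the EEG analyses.
#'
#' @param counts Named (or positional) counts for miss, item_only and pair.
#' @param min_trials Minimum per-condition trial count (default 10).
#' @return Logical: keep the subject?
#' @export
min_trial_filter <- function(counts, min_trials = 10L) {
  stopifnot(length(counts) == 3L)
  all(counts >= min_trials)
}

#' Per-subject memory response rates
#'
#' Computes miss / item-only / pair response proportions per subject over
#' the included (match + mismatch, categorized) trials.
#'
#' @param events Data frame with columns subject, age_group and outcome
#'   (values among miss/item_only/pair; other values are dropped).
#' @return Data frame: subject, age_group, n, miss, item_only, pair.  Rates
#'   sum to 1 per subject.
#' @export
response_rates <- function(events) {
  stopifnot(all(c("subject", "age_group", "outcome") %in% names(events)))
  ev <- events[events$outcome %in% c("miss", "item_only", "pair"), ]
  if (nrow(ev) == 0L) stop("no categorized trials")
  split_ev <- split(ev, ev$subject)
  rows <- lapply(split_ev, function(d) {
    tab <- table(factor(d$outcome, levels = c("miss", "item_only", "pair")))
    data.frame(subject = d$subject[1], age_group = d$age_group[1],
               n = nrow(d),
               miss = as.numeric(tab["miss"] / nrow(d)),
               item_only = as.numeric(tab["item_only"] / nrow(d)),
               pair = as.numeric(tab["pair"] / nrow(d)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mixed-design ANOVA on response rates
#'
#' Classical two-way mixed ANOVA with age group as the between-subjects
#' factor and memory level (miss / item-only / pair) as the within-subjects
#' factor, subject nested in age group as the error stratum.  No sphericity
#' correction is applied to the within-subject factor.
#'
#' @param rates Rate table from [response_rates()].
#' @return Data frame with one row per effect (`age`, `memory_level`,
#'   `age:memory_level`): df1, df2, F, p.
#' @export
rate_anova <- function(rates) {
  stopifnot(all(c("subject", "age_group", "miss", "item_only", "pair") %in% names(rates)))
  if (min(table(rates$age_group)) < 2L) stop("need >= 2 subjects per age group")
  long <- data.frame(
    subject = factor(rep(rates$subject, 3L)),
    age = factor(rep(rates$age_group, 3L)),
    level = factor(rep(c("miss", "item_only", "pair"), each = nrow(rates)),
                   levels = c("miss", "item_only", "pair")),
    rate = c(rates$miss, rates$item_only, rates$pair)
  )
  fit <- stats::aov(rate ~ age * level + Error(subject / level), data = long)
  sm <- summary(fit)
  between <- sm[["Error: subject"]][[1]]
  within <- sm[["Error: subject:level"]][[1]]
  grab <- function(tab, term) {
    i <- match(term, trimws(rownames(tab)))
    resid <- grep("Residuals", rownames(tab))
    f <- tab[i, "F value"]
    p <- tab[i, "Pr(>F)"]
    # degenerate strata: a zero effect sum of squares is "no effect" even when
    # the residual is also (numerically) zero
    if (tab[i, "Sum Sq"] < 1e-12) { f <- 0; p <- 1 }
    else if (tab[resid, "Sum Sq"] < 1e-12) { f <- Inf; p <- 0 }
    data.frame(df1 = tab[i, "Df"], df2 = tab[resid, "Df"], F = f, p = p)
  }
  out <- rbind(grab(between, "age"), grab(within, "level"), grab(within, "age:level"))
  out <- cbind(effect = c("age", "memory_level", "age:memory_level"), out)
  rownames(out) <- NULL
  out
}

#' Welch t-tests for age differences per memory level
#'
#' Follow-up comparisons after a significant age-by-memory-level
#' interaction: Welch two-sample t-tests of each rate between age groups.
#'
#' @param rates Rate table from [response_rates()].
#' @return Data frame: level, t, df, p, mean_younger, mean_older.
#' @export
rate_age_ttests <- function(rates) {
  levels_ <- c("miss", "item_only", "pair")
  rows <- lapply(levels_, function(lv) {
    y <- rates[[lv]][rates$age_group == "younger"]
    o <- rates[[lv]][rates$age_group == "older"]
    tt <- stats::t.test(y, o)
    data.frame(level = lv, t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, mean_younger = mean(y), mean_older = mean(o))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
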