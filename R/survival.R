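#' Kaplan-Meier product-limit estimate
#'
#' Standard product-limit estimator (events processed before censorings at
#' tied times), with optional administrative truncation: observations beyond
#' the horizon are censored at the horizon before estimation.
#'
#' @param times Non-negative event/censoring times (months).
#' @param events 0/1 event indicators (1 = graft loss).
#' @param horizon Optional administrative censoring horizon (months).
#' @return A tibble `time`, `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
kaplan_meier <- function(times, events, horizon = NULL) {
  assert_that(length(times) > 0, "empty survival input")
  assert_that(length(times) == length(events), "times/events length mismatch")
  assert_that(all(times >= 0), "times must be non-negative")
  if (!is.null(horizon)) {
    events <- ifelse(times > horizon, 0L, events)
    times <- pmin(times, horizon)
  }
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
         n_censor = fit$n.censor, survival = fit$surv)
}

#' Two-group log-rank test
#'
#' Observed-minus-expected events under the hypergeometric null at each
#' distinct event time; variance-summed chi-square with 1 df. With zero
#' events in both groups the statistic is 0 and p = 1.
#'
#' @param times_a,events_a,times_b,events_b Per-group times and 0/1 events.
#' @return A one-row tibble `statistic`, `p_value`, `n_a`, `n_b`,
#'   `events_a`, `events_b`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  assert_that(length(times_a) > 0 && length(times_b) > 0,
              "both groups must be non-empty")
  if (sum(events_a) + sum(events_b) == 0) {
    return(tibble(statistic = 0, p_value = 1,
                  n_a = length(times_a), n_b = length(times_b),
                  events_a = 0L, events_b = 0L))
  }
  grp <- c(rep("a", length(times_a)), rep("b", length(times_b)))
  sd <- survival::survdiff(
    survival::Surv(c(times_a, times_b), c(events_a, events_b)) ~ grp)
  tibble(statistic = unname(sd$chisq),
         p_value = pchisq(sd$chisq, df = 1, lower.tail = FALSE),
         n_a = length(times_a), n_b = length(times_b),
         events_a = sum(events_a), events_b = sum(events_b))
}

#' Median-split survival analysis across gene sets
#'
#' For each gene set: selects each patient's first biopsy, censors
#' administratively at the horizon, splits samples at the full-cohort median
#' score, builds Kaplan-Meier curves for the diagnosis-by-stratum groups, and
#' tests above- vs below-median survival within the test diagnosis by
#' log-rank. False discovery rates are Benjamini-Hochberg across all sets in
#' the call; strata sharing a compact letter (greedy assignment from pairwise
#' log-rank at fdr 0.05 within set) are not significantly different.
#'
#' @param cohort A [bulk_cohort()].
#' @param scores A [score_samples()] result for that cohort.
#' @param sets Sets to analyse; default all in `scores`.
#' @param diagnoses Diagnoses whose strata are plotted (default TCMR and NR).
#' @param test_diagnosis Diagnosis within which above-vs-below is tested
#'   (default `"TCMR"`).
#' @param horizon Administrative censoring horizon in months (default 36).
#' @return An object of class `survival_result` with tibbles `tests`
#'   (set-level log-rank + fdr), `km` (curves per set/stratum) and `letters`
#'   (compact letters per set/stratum).
#' @export
survival_by_score <- function(cohort, scores, sets = NULL,
                              diagnoses = c("TCMR", "NR"),
                              test_diagnosis = "TCMR", horizon = 36) {
  stopifnot(inherits(cohort, "bulk_cohort"))
  strat <- median_stratify(scores, cohort, set_name = sets)
  first <- cohort$clinical |>
    group_by(.data$patient_id) |>
    filter(.data$biopsy_index == min(.data$biopsy_index)) |>
    ungroup() |>
    filter(!is.na(.data$time_months), !is.na(.data$event))
  dat <- dplyr::inner_join(strat, first, by = c(sample = "sample_id"))
  dat <- mutate(dat,
                event_h = ifelse(.data$time_months > horizon, 0L, .data$event),
                time_h = pmin(.data$time_months, horizon))

  set_names <- unique(dat$set)
  tests <- purrr::map_dfr(set_names, function(nm) {
    d <- filter(dat, .data$set == nm, .data$diagnosis == test_diagnosis)
    ab <- filter(d, .data$stratum == "above")
    be <- filter(d, .data$stratum == "below")
    if (nrow(ab) == 0 || nrow(be) == 0) {
      return(tibble(set = nm, n_above = nrow(ab), n_below = nrow(be),
                    statistic = NA_real_, p_value = NA_real_,
                    tested = FALSE, reason = "empty stratum"))
    }
    lr <- logrank_test(ab$time_h, ab$event_h, be$time_h, be$event_h)
    tibble(set = nm, n_above = nrow(ab), n_below = nrow(be),
           statistic = lr$statistic, p_value = lr$p_value,
           tested = TRUE, reason = NA_character_)
  })
  tests$fdr <- NA_real_
  tests$fdr[tests$tested] <- benjamini_hochberg(tests$p_value[tests$tested])

  km <- purrr::map_dfr(set_names, function(nm) {
    d <- filter(dat, .data$set == nm, .data$diagnosis %in% diagnoses)
    d |>
      group_by(.data$diagnosis, .data$stratum) |>
      dplyr::group_modify(~ kaplan_meier(.x$time_h, .x$event_h)) |>
      ungroup() |>
      mutate(set = nm,
             stratum_label = paste(.data$diagnosis, .data$stratum), .before = 1)
  })

  letters_tab <- purrr::map_dfr(set_names, function(nm) {
    d <- filter(dat, .data$set == nm, .data$diagnosis %in% diagnoses) |>
      mutate(stratum_label = paste(.data$diagnosis, .data$stratum))
    compact_letters(d, alpha = 0.05) |>
      mutate(set = nm, .before = 1)
  })

  structure(list(tests = tests, km = km, letters = letters_tab,
                 horizon = horizon, test_diagnosis = test_diagnosis),
            class = "survival_result")
}

# pairwise log-rank among strata; BH within the set; greedy compact-letter
# assignment so that strata sharing a letter are not significantly different
compact_letters <- function(d, alpha = 0.05) {
  labs <- sort(unique(d$stratum_label))
  if (length(labs) < 2) {
    return(tibble(stratum_label = labs, letters = rep("a", length(labs))))
  }
  pairs <- combn(labs, 2)
  p <- apply(pairs, 2, function(pr) {
    a <- filter(d, .data$stratum_label == pr[1])
    b <- filter(d, .data$stratum_label == pr[2])
    logrank_test(a$time_h, a$event_h, b$time_h, b$event_h)$p_value
  })
  padj <- benjamini_hochberg(p)
  differ <- matrix(FALSE, length(labs), length(labs),
                   dimnames = list(labs, labs))
  for (i in seq_len(ncol(pairs))) {
    if (padj[i] < alpha) {
      differ[pairs[1, i], pairs[2, i]] <- TRUE
      differ[pairs[2, i], pairs[1, i]] <- TRUE
    }
  }
  groups <- list()   # each element: a set of mutually non-different strata
  for (lab in labs) {
    placed <- FALSE
    for (gi in seq_along(groups)) {
      if (!any(differ[lab, groups[[gi]]])) {
        groups[[gi]] <- c(groups[[gi]], lab)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1]] <- lab
  }
  lets <- vapply(labs, function(lab) {
    paste(letters[which(vapply(groups, function(g) lab %in% g, logical(1)))],
          collapse = "")
  }, character(1))
  tibble(stratum_label = labs, letters = unname(lets))
}

#' @export
print.survival_result <- function(x, ...) {
  cat(sprintf("<survival_result> %d gene set(s), horizon %g months, tested in %s\n",
              nrow(x$tests), x$horizon, x$test_diagnosis))
  print(x$tests)
  invisible(x)
}

#' @export
tidy.survival_result <- function(x, ...) x$tests

#' @export
glance.survival_result <- function(x, ...) {
  tibble(n_sets = nrow(x$tests),
         n_significant = sum(x$tests$fdr < 0.05, na.rm = TRUE),
         horizon = x$horizon, test_diagnosis = x$test_diagnosis)
}
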