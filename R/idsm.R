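# Scoring of the four-level ordinal depression severity measure (IDSM).
#
# Levels form an ordinal chain: 0 = no depression (or postnatal-only),
# 1 = mild (self-reported lifetime depression), 2 = moderate (additionally a
# GP or psychiatrist diagnosis), 3 = severe/recurrent (additionally defined
# medication and/or more than one treated episode).

.IDSM_FIELDS <- c("ever_depressed", "postnatal_only", "gp_diagnosed",
                  "psychiatrist_diagnosed", "defined_medication",
                  "multiple_treated_episodes")

#' Score questionnaire responses on the ordinal depression severity scale
#'
#' Applies the hierarchical scoring rules to logical answer fields:
#' * level 0 if the respondent never had depression, or had it only
#'   following childbirth (`postnatal_only` overrides everything);
#' * level 1 (mild, self-diagnostic) otherwise;
#' * level 2 (moderate) if additionally a GP or psychiatrist diagnosed
#'   depression;
#' * level 3 (severe/recurrent) if, meeting the level-2 criteria, the
#'   respondent also received defined medication and/or had more than one
#'   treated episode.
#'
#' The returned level is the highest whose criteria (including all lower
#' levels') are met. Missing answers are never defaulted: with
#' `na_action = "error"` (default) they abort with a message naming the
#' field(s); with `na_action = "na"` the affected records score `NA`.
#'
#' @param responses Data frame with logical columns `ever_depressed`,
#'   `postnatal_only`, `gp_diagnosed`, `psychiatrist_diagnosed`,
#'   `defined_medication`, `multiple_treated_episodes`.
#' @param na_action `"error"` or `"na"`.
#' @return Integer vector of levels in `0:3` (possibly `NA`).
#' @examples
#' idsm_score(data.frame(ever_depressed = TRUE, postnatal_only = FALSE,
#'                       gp_diagnosed = TRUE, psychiatrist_diagnosed = FALSE,
#'                       defined_medication = FALSE,
#'                       multiple_treated_episodes = TRUE))  # 3
#' @export
idsm_score <- function(responses, na_action = c("error", "na")) {
  na_action <- match.arg(na_action)
  missing_cols <- setdiff(.IDSM_FIELDS, names(responses))
  if (length(missing_cols))
    stop("missing answer column(s): ", paste(missing_cols, collapse = ", "))
  r <- lapply(responses[.IDSM_FIELDS], as.logical)
  any_na <- Reduce(`|`, lapply(r, is.na))
  if (any(any_na) && na_action == "error") {
    bad <- .IDSM_FIELDS[vapply(r, anyNA, logical(1))]
    stop("missing answers in field(s): ", paste(bad, collapse = ", "))
  }
  level1 <- r$ever_depressed & !r$postnatal_only
  level2 <- level1 & (r$gp_diagnosed | r$psychiatrist_diagnosed)
  level3 <- level2 & (r$defined_medication | r$multiple_treated_episodes)
  score <- as.integer(level1) + as.integer(level2) + as.integer(level3)
  score[any_na] <- NA_integer_
  score
}

#' Score a cohort and tabulate severity prevalences
#'
#' Scores every scoreable row of a response table; rows with any missing
#' answer are excluded (with a message giving the count) rather than imputed.
#'
#' @param responses Data frame of questionnaire responses (see [idsm_score]).
#' @return List with `scores` (integer vector over all rows, `NA` where
#'   excluded), `prevalence` (length-4 probability vector over scored rows),
#'   `n_scored`, `n_excluded`.
#' @export
score_cohort <- function(responses) {
  if (is.null(responses) || nrow(responses) == 0)
    stop("empty response table")
  scores <- idsm_score(responses, na_action = "na")
  n_excluded <- sum(is.na(scores))
  n_scored <- sum(!is.na(scores))
  if (n_scored == 0) stop("no scoreable rows (all have missing answers)")
  if (n_excluded > 0)
    message(n_excluded, " row(s) excluded for missing answers")
  prevalence <- tabulate(scores[!is.na(scores)] + 1L, 4L) / n_scored
  list(scores = scores, prevalence = prevalence,
       n_scored = n_scored, n_excluded = n_excluded)
}

.parse_yes_no <- function(x) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("yes", "y", "true", "1")] <- TRUE
  out[v %in% c("no", "n", "false", "0")] <- FALSE
  bad <- !(v %in% c("yes", "y", "true", "1", "no", "n", "false", "0", "na", "", NA)) & !is.na(v)
  if (any(bad))
    stop("unrecognized answer value(s): ", paste(unique(v[bad]), collapse = ", "))
  out
}

#' Read a questionnaire answer file and append the severity score
#'
#' Reads a CSV with one row per respondent (columns `respondent_id`,
#' `pair_id`, `zygosity`, and the six yes/no/NA answer columns), scores each
#' row, and returns (optionally writes) the table with an added `idsm_level`
#' column.
#'
#' @param path Input CSV path.
#' @param out Optional output CSV path.
#' @return Invisibly, the scored data frame.
#' @export
score_answer_file <- function(path, out = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.IDSM_FIELDS, names(df))
  if (length(missing_cols))
    stop("missing answer column(s): ", paste(missing_cols, collapse = ", "))
  for (f in .IDSM_FIELDS) df[[f]] <- .parse_yes_no(df[[f]])
  df$idsm_level <- idsm_score(df, na_action = "na")
  if (!is.null(out)) write.csv(df, out, row.names = FALSE)
  invisible(df)
}
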