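#' Read per-trial reaction-time records
#'
#' Reads a delimited text file of visual-search trials with the header
#' `subject,condition,rt,correct`. The `condition` column must hold one of
#' the six target labels `C`, `O`, `M`, `CO`, `MO`, `CM`; `rt` is the
#' reaction time; `correct` accepts `0`/`1` or `true`/`false` (any case).
#'
#' @param path Path to a CSV or TSV file. The delimiter is taken from the
#'   file extension (`.tsv`/`.tab` means tab, otherwise comma) unless `sep`
#'   is given.
#' @param sep Field delimiter, overriding the extension-based guess.
#' @param rt_unit Unit of the `rt` column: `"s"` (default) or `"ms"`.
#'   Millisecond input is converted so RTs are always stored in seconds.
#' @return A `data.frame` with columns `subject` (character), `condition`
#'   (character, one of the six labels), `rt` (numeric seconds) and
#'   `correct` (logical).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("subject,condition,rt,correct",
#'              "s1,C,0.61,1", "s1,CO,0.48,1", "s1,M,0.55,0"), f)
#' read_trials(f)
#' @export
read_trials <- function(path, sep = NULL, rt_unit = c("s", "ms")) {
  rt_unit <- match.arg(rt_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", strip.white = TRUE,
                           check.names = FALSE)
  required <- c("subject", "condition", "rt", "correct")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("input is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  rt <- suppressWarnings(as.numeric(raw$rt))
  bad_rt <- which(is.na(rt) & !is.na(raw$rt) & nzchar(raw$rt))
  if (length(bad_rt) > 0) {
    stop("non-numeric rt value '", raw$rt[bad_rt[1]], "' at data row ",
         bad_rt[1])
  }
  if (anyNA(rt)) stop("missing rt value at data row ", which(is.na(rt))[1])
  if (rt_unit == "ms") rt <- rt / 1000
  cond <- toupper(trimws(raw$condition))
  bad_cond <- which(!cond %in% CONDITIONS)
  if (length(bad_cond) > 0) {
    stop("unknown condition label '", raw$condition[bad_cond[1]],
         "' at data row ", bad_cond[1],
         " (expected one of ", paste(CONDITIONS, collapse = ", "), ")")
  }
  correct <- parse_correct(raw$correct)
  if (anyNA(correct)) {
    i <- which(is.na(correct))[1]
    stop("unparseable correct flag '", raw$correct[i], "' at data row ", i)
  }
  trials <- data.frame(subject = raw$subject, condition = cond,
                       rt = rt, correct = correct,
                       stringsAsFactors = FALSE)
  validate_trials(trials)
  trials
}

parse_correct <- function(x) {
  x <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "t")] <- TRUE
  out[x %in% c("0", "false", "f")] <- FALSE
  out
}

validate_trials <- function(trials) {
  stopifnot(is.data.frame(trials),
            all(c("subject", "condition", "rt", "correct") %in% names(trials)))
  if (!all(trials$condition %in% CONDITIONS)) {
    stop("condition labels must be one of ", paste(CONDITIONS, collapse = ", "))
  }
  if (!all(is.finite(trials$rt)) || any(trials$rt <= 0)) {
    stop("all RTs must be finite and positive (seconds)")
  }
  invisible(trials)
}

#' Write trials back to CSV/TSV
#'
#' Inverse of [read_trials()]: writes the `subject,condition,rt,correct`
#' schema with `correct` encoded as 0/1 and RT in seconds.
#'
#' @param trials A trial data frame as returned by [read_trials()].
#' @param path Output file path; `.tsv`/`.tab` extensions select tabs.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  out <- data.frame(subject = trials$subject, condition = trials$condition,
                    rt = trials$rt, correct = as.integer(trials$correct))
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Clean trials by correctness and outlier rules
#'
#' Applies, independently within each (subject, condition) cell, the standard
#' behavioural exclusion rules: trials with an incorrect button press are
#' dropped; among the correct trials the mean `m` and sample SD `s` are
#' computed once (a single pass, including any eventual outliers), and trials
#' with `rt < min_rt` or `rt > m + sd_multiplier * s` are then excluded.
#' Boundary-equal values are retained. One cell's trials never influence
#' another cell's thresholds.
#'
#' @param trials Trial data frame (see [read_trials()]); may contain several
#'   subjects.
#' @param min_rt Short-RT floor in seconds (default 0.2).
#' @param sd_multiplier Upper threshold in SD units above the mean (default 3,
#'   upper side only).
#' @return An object of class `cleaned_trials`: a list with `trials` (the
#'   retained rows) and `report`, a data frame with one row per
#'   (subject, condition) giving `n_total`, `n_incorrect`, `n_outlier` and
#'   `fraction_excluded`.
#' @examples
#' trials <- data.frame(subject = "s1", condition = "C",
#'                      rt = c(0.1, 0.5, 0.6), correct = TRUE)
#' clean_trials(trials)$trials$rt  # 0.1 falls below the 0.2 s floor
#' @export
clean_trials <- function(trials, min_rt = 0.2, sd_multiplier = 3) {
  validate_trials(trials)
  stopifnot(min_rt > 0, sd_multiplier > 0)
  keep <- logical(nrow(trials))
  report <- NULL
  for (sub in unique(trials$subject)) {
    for (cond in unique(trials$condition[trials$subject == sub])) {
      idx <- which(trials$subject == sub & trials$condition == cond)
      rt <- trials$rt[idx]
      ok <- trials$correct[idx]
      if (sum(ok) < 2) {
        stop("subject '", sub, "', condition '", cond,
             "': fewer than 2 correct trials; cannot form an SD")
      }
      m <- mean(rt[ok])
      s <- stats::sd(rt[ok])
      inlier <- ok & rt >= min_rt & rt <= m + sd_multiplier * s
      if (!any(inlier)) {
        stop("subject '", sub, "', condition '", cond,
             "': all trials excluded by cleaning")
      }
      keep[idx[inlier]] <- TRUE
      report <- rbind(report, data.frame(
        subject = sub, condition = cond,
        n_total = length(idx),
        n_incorrect = sum(!ok),
        n_outlier = sum(ok & !inlier),
        fraction_excluded = sum(!inlier) / length(idx),
        stringsAsFactors = FALSE))
    }
  }
  structure(list(trials = trials[keep, , drop = FALSE], report = report,
                 min_rt = min_rt, sd_multiplier = sd_multiplier),
            class = "cleaned_trials")
}

#' @export
print.cleaned_trials <- function(x, ...) {
  cat("Cleaned RT trials:", nrow(x$trials), "retained of",
      sum(x$report$n_total), "\n")
  cat(sprintf("Rules: rt >= %.3f s, correct only, rt <= mean + %g SD (per subject x condition)\n",
              x$min_rt, x$sd_multiplier))
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Serialize a cleaning report to JSON
#'
#' @param cleaned A `cleaned_trials` object from [clean_trials()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to `path`).
#' @export
cleaning_report_json <- function(cleaned, path = NULL) {
  stopifnot(inherits(cleaned, "cleaned_trials"))
  js <- jsonlite::toJSON(cleaned$report, digits = I(10), dataframe = "rows",
                         auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
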