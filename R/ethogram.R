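#' Behavior vocabulary for copulation ethograms
#'
#' The ethogram used to score male rat copulation assigns every behavior
#' label to one of three functional classes that drive mount-bout
#' segmentation:
#'
#' * `copulatory` -- mount, intromission, ejaculation; these are the bout
#'   members.
#' * `bout_breaking` -- behaviors not oriented towards the female
#'   (non-genital autogrooming, head not towards female); any occurrence
#'   between two copulatory behaviors ends the current mount bout.
#' * `bout_neutral` -- female-oriented behaviors plus genital autogrooming
#'   (genital grooming, anogenital sniffing, chasing, head towards female);
#'   these never interrupt a bout.
#'
#' The three classes must be disjoint and together cover the vocabulary.
#'
#' @param copulatory,bout_breaking,bout_neutral character vectors of
#'   behavior labels, one per class.
#' @return An object of class `behavior_vocabulary`: a list with the three
#'   class vectors and a lookup table `class_of`.
#' @seealso [default_vocabulary()], [read_vocabulary()]
#' @export
behavior_vocabulary <- function(copulatory, bout_breaking, bout_neutral) {
  copulatory    <- as.character(copulatory)
  bout_breaking <- as.character(bout_breaking)
  bout_neutral  <- as.character(bout_neutral)
  all_labels <- c(copulatory, bout_breaking, bout_neutral)
  if (anyDuplicated(all_labels))
    stop("vocabulary classes must be disjoint; duplicated label(s): ",
         paste(unique(all_labels[duplicated(all_labels)]), collapse = ", "))
  if (length(copulatory) < 1L)
    stop("vocabulary must contain at least one copulatory behavior")
  class_of <- c(
    stats::setNames(rep("copulatory", length(copulatory)), copulatory),
    stats::setNames(rep("bout_breaking", length(bout_breaking)), bout_breaking),
    stats::setNames(rep("bout_neutral", length(bout_neutral)), bout_neutral)
  )
  structure(
    list(copulatory = copulatory, bout_breaking = bout_breaking,
         bout_neutral = bout_neutral, class_of = class_of),
    class = "behavior_vocabulary"
  )
}

#' Default copulation ethogram vocabulary
#'
#' The standard ethogram for the 30-min copulation test: mounts,
#' intromissions and ejaculations as copulatory behaviors; other (non-genital)
#' grooming and head-not-towards-female as bout-breaking; genital grooming,
#' anogenital sniffing, chasing and head-towards-female as bout-neutral.
#'
#' @return A [behavior_vocabulary()].
#' @export
default_vocabulary <- function() {
  behavior_vocabulary(
    copulatory    = c("mount", "intromission", "ejaculation"),
    bout_breaking = c("other_grooming", "head_not_towards_female"),
    bout_neutral  = c("genital_grooming", "anogenital_sniffing",
                      "chasing", "head_towards_female")
  )
}

#' Read a behavior vocabulary from YAML
#'
#' The YAML file maps each behavior label to its class, e.g.
#' `mount: copulatory`.
#'
#' @param path path to a YAML file.
#' @return A [behavior_vocabulary()].
#' @export
read_vocabulary <- function(path) {
  m <- yaml::read_yaml(path)
  cls <- unlist(m)
  bad <- setdiff(unique(cls), c("copulatory", "bout_breaking", "bout_neutral"))
  if (length(bad))
    stop("unknown vocabulary class(es): ", paste(bad, collapse = ", "))
  behavior_vocabulary(
    copulatory    = names(cls)[cls == "copulatory"],
    bout_breaking = names(cls)[cls == "bout_breaking"],
    bout_neutral  = names(cls)[cls == "bout_neutral"]
  )
}

#' Write a behavior vocabulary to YAML
#'
#' @param vocabulary a [behavior_vocabulary()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocabulary, path) {
  stopifnot(inherits(vocabulary, "behavior_vocabulary"))
  yaml::write_yaml(as.list(vocabulary$class_of), path)
  invisible(path)
}

#' Construct a copulation test log
#'
#' A copulation test log holds the time-ordered behavior events of one
#' subject in one test, together with the vocabulary that classifies them
#' and the test duration (1800 s for the standard 30-min test). Events are
#' stored as intervals `[start, end]` in seconds from test start; point
#' events have `end == start`.
#'
#' @param events a data.frame with columns `behavior`, `start`, `end`
#'   (seconds from test start).
#' @param subject subject identifier.
#' @param vocabulary a [behavior_vocabulary()]; defaults to
#'   [default_vocabulary()].
#' @param test_duration test duration in seconds (default 1800).
#' @param design optional named list of design-cell labels (virus,
#'   treatment, condition) carried through to outputs.
#' @param validate if `TRUE` (default) the constructor stops on any
#'   invariant violation; see [validate_log()].
#' @return An object of class `copulation_log`.
#' @export
copulation_log <- function(events, subject = NA_character_,
                           vocabulary = default_vocabulary(),
                           test_duration = 1800, design = NULL,
                           validate = TRUE) {
  stopifnot(inherits(vocabulary, "behavior_vocabulary"))
  if (is.null(events) || nrow(as.data.frame(events)) == 0L) {
    events <- data.frame(behavior = character(), start = numeric(),
                         end = numeric())
  }
  events <- as.data.frame(events)[, c("behavior", "start", "end")]
  events$behavior <- as.character(events$behavior)
  events$start <- as.numeric(events$start)
  events$end <- as.numeric(events$end)
  events <- events[order(events$start, events$end), , drop = FALSE]
  rownames(events) <- NULL
  log <- structure(
    list(subject = subject, events = events, vocabulary = vocabulary,
         test_duration = as.numeric(test_duration), design = design),
    class = "copulation_log"
  )
  if (validate) {
    v <- validate_log(log)
    if (length(v))
      stop("invalid copulation log:\n  ", paste(v, collapse = "\n  "))
  }
  log
}

#' @export
print.copulation_log <- function(x, ...) {
  cat("<copulation_log> subject:", x$subject,
      "| events:", nrow(x$events),
      "| duration:", x$test_duration, "s\n")
  cls <- x$vocabulary$class_of[x$events$behavior]
  if (nrow(x$events))
    print(table(factor(cls, levels = c("copulatory", "bout_breaking",
                                       "bout_neutral"))))
  invisible(x)
}

#' Validate a copulation test log
#'
#' Checks every log invariant and reports violations without throwing:
#' non-negative times, `end >= start`, events within the test duration,
#' labels drawn from the vocabulary, events sorted by start time, and no
#' two copulatory events overlapping each other (state behaviors may
#' overlap freely; full temporal coverage is not required).
#'
#' @param log a `copulation_log` (built with `validate = FALSE` if you want
#'   to inspect a broken one).
#' @return A character vector of human-readable violations, each naming the
#'   offending event row(s); empty when the log is valid.
#' @export
validate_log <- function(log) {
  stopifnot(inherits(log, "copulation_log"))
  ev <- log$events
  out <- character()
  if (!nrow(ev)) return(out)
  unknown <- which(!(ev$behavior %in% names(log$vocabulary$class_of)))
  for (i in unknown)
    out <- c(out, sprintf("row %d: unknown behavior label '%s'", i,
                          ev$behavior[i]))
  for (i in which(is.na(ev$start) | is.na(ev$end)))
    out <- c(out, sprintf("row %d: missing start or end time", i))
  for (i in which(!is.na(ev$start) & ev$start < 0))
    out <- c(out, sprintf("row %d: negative start time %g", i, ev$start[i]))
  for (i in which(!is.na(ev$start) & !is.na(ev$end) & ev$end < ev$start))
    out <- c(out, sprintf("row %d: end %g before start %g", i, ev$end[i],
                          ev$start[i]))
  for (i in which(!is.na(ev$end) & ev$end > log$test_duration))
    out <- c(out, sprintf("row %d: event ends at %g, beyond test duration %g",
                          i, ev$end[i], log$test_duration))
  # sortedness: one violation per inversion of consecutive starts
  if (nrow(ev) > 1L) {
    for (i in which(diff(ev$start) < 0))
      out <- c(out, sprintf("rows %d-%d: events out of order (%g > %g)",
                            i, i + 1L, ev$start[i], ev$start[i + 1L]))
  }
  # copulatory events must be mutually exclusive in time
  cop <- which(ev$behavior %in% log$vocabulary$copulatory &
                 !is.na(ev$start) & !is.na(ev$end))
  if (length(cop) > 1L) {
    for (k in seq_len(length(cop) - 1L)) {
      i <- cop[k]; j <- cop[k + 1L]
      if (ev$start[j] < ev$end[i])
        out <- c(out, sprintf(
          "rows %d and %d: overlapping copulatory events ('%s' and '%s')",
          i, j, ev$behavior[i], ev$behavior[j]))
    }
  }
  out
}

#' Read a copulation ethogram from CSV
#'
#' Expects a comma-separated, UTF-8, '.'-decimal file with header columns
#' `subject,behavior,start_s,end_s`. Rows are validated against the
#' vocabulary and the log invariants; any violation aborts the read with a
#' message naming the offending row.
#'
#' @param path path to the CSV file.
#' @param vocabulary a [behavior_vocabulary()].
#' @param test_duration test duration in seconds (default 1800).
#' @param subject optional subject filter; by default the file must contain
#'   a single subject.
#' @return A validated, time-sorted [copulation_log()].
#' @export
read_ethogram <- function(path, vocabulary = default_vocabulary(),
                          test_duration = 1800, subject = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("subject", "behavior", "start_s", "end_s")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("ethogram CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!is.null(subject)) df <- df[df$subject == subject, , drop = FALSE]
  subj <- unique(df$subject)
  if (length(subj) > 1L)
    stop("file contains multiple subjects (", paste(subj, collapse = ", "),
         "); pass `subject` to select one")
  if (length(subj) == 0L) subj <- NA_character_
  copulation_log(
    data.frame(behavior = df$behavior, start = df$start_s, end = df$end_s),
    subject = as.character(subj), vocabulary = vocabulary,
    test_duration = test_duration
  )
}

#' Write a copulation ethogram to CSV
#'
#' Inverse of [read_ethogram()]: writes `subject,behavior,start_s,end_s`.
#'
#' @param log a [copulation_log()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ethogram <- function(log, path) {
  stopifnot(inherits(log, "copulation_log"))
  df <- data.frame(subject = rep(log$subject, nrow(log$events)),
                   behavior = log$events$behavior,
                   start_s = log$events$start, end_s = log$events$end)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
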