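# SPV experiment machinery: seeded trial plans (randomly interleaved methods,
# timed pauses) and scoring of response logs into the object-recognition
# outcomes and room-identification confusion matrices with a not-answered
# (NA) category.

stimulus_methods <- c("direct", "edge", "sie_oms")

#' Default object-class synonym groups for scoring
#'
#' Reported classes in the same group count as matching (ovens and microwaves
#' share a rectangular silhouette and are graded together; "dining table"
#' matches "table"). User-editable: pass your own list of character vectors.
#' @export
default_synonyms <- list(c("oven", "microwave"), c("table", "dining table"))

canonical_class <- function(label, synonyms = default_synonyms) {
  for (g in synonyms) if (label %in% g) return(g[1])
  label
}

#' Build a seeded trial plan for one subject
#'
#' Draws `images_per_subject` (scene, method) pairs — stratified across
#' methods as evenly as possible, scenes sampled without replacement so no
#' subject sees the same scene twice under any method — and randomly permutes
#' them so the methods are interleaved. Pause markers are placed after every
#' `pause_every` stimuli. Each stimulus is shown for `display_seconds`; a
#' trial with no response within that window is logged as not answered.
#'
#' @param scenes list of scene annotations (or a character vector of scene
#'   ids).
#' @param subject_id subject identifier.
#' @param images_per_subject trials for this subject (default 54).
#' @param methods stimulus methods to interleave.
#' @param display_seconds seconds each image is displayed (default 10).
#' @param pause_every stimuli between pauses (default 15).
#' @param pause_seconds pause duration (default 30).
#' @param seed non-negative integer seed.
#' @return a `trial_plan`: data frame of (position, scene_id, method,
#'   pause_after) plus the timing parameters.
#' @export
make_plan <- function(scenes, subject_id, images_per_subject = 54L,
                      methods = stimulus_methods, display_seconds = 10,
                      pause_every = 15L, pause_seconds = 30, seed = 0L) {
  ids <- if (is.character(scenes)) scenes
         else vapply(scenes, `[[`, character(1), "scene_id")
  if (anyDuplicated(ids)) spv_input_error("duplicated scene ids")
  n <- as.integer(images_per_subject)
  if (n > length(ids))
    spv_error(sprintf("requested %d trials but only %d scenes are available",
                      n, length(ids)), "spv_planning_error")
  with_seed(seed, {
    # stratify across methods: trial counts differ by at most one
    meth <- sample(rep(methods, length.out = n))
    scene_sel <- sample(ids, n)              # each scene at most once
    ord <- sample.int(n)
    trials <- data.frame(position = seq_len(n),
                         scene_id = scene_sel[ord],
                         method = meth[ord],
                         stringsAsFactors = FALSE)
  })
  trials$pause_after <- trials$position %% as.integer(pause_every) == 0L &
    trials$position < n
  structure(list(subject_id = subject_id, trials = trials,
                 display_seconds = display_seconds,
                 pause_every = as.integer(pause_every),
                 pause_seconds = pause_seconds, seed = as.integer(seed)),
            class = "trial_plan")
}

#' @export
print.trial_plan <- function(x, ...) {
  cat(sprintf(
    "Trial plan for %s: %d stimuli (%g s each), %d pause(s) of %g s\n",
    x$subject_id, nrow(x$trials), x$display_seconds,
    sum(x$trials$pause_after), x$pause_seconds))
  invisible(x)
}

#' Score one object-recognition response
#'
#' A trial is `"na"` when the subject gave no answer within the display
#' window; `"correct"` when at least one reported class matches a
#' ground-truth instance class (after synonym mapping); otherwise
#' `"incorrect"`. Unknown reported class strings raise a validation error.
#'
#' @param reported character vector of reported classes (may be empty).
#' @param truth a `scene_annotation`, or a character vector of true classes.
#' @param answered logical; `FALSE` marks a not-answered trial.
#' @param synonyms list of synonym groups (see [default_synonyms]).
#' @param known vocabulary of valid class names.
#' @return one of `"correct"`, `"incorrect"`, `"na"`.
#' @export
score_objects <- function(reported, truth, answered = length(reported) > 0,
                          synonyms = default_synonyms,
                          known = c(indoor_object_classes,
                                    unlist(synonyms))) {
  if (!answered || length(reported) == 0L) return("na")
  bad <- setdiff(reported, known)
  if (length(bad))
    spv_error(paste("unknown object class(es):", paste(bad, collapse = ", ")),
              "spv_validation_error")
  true_classes <- if (inherits(truth, "scene_annotation"))
    vapply(truth$instances, `[[`, character(1), "label") else truth
  rep_c <- vapply(reported, canonical_class, character(1), synonyms)
  tru_c <- vapply(true_classes, canonical_class, character(1), synonyms)
  if (any(rep_c %in% tru_c)) "correct" else "incorrect"
}

#' Room-identification confusion matrix
#'
#' Tallies actual room (rows) against predicted room plus a not-answered
#' column, then derives per-room recall and per-predicted-room precision, in
#' two variants. `"answered"`: recall divides correct answers by answered
#' trials only. `"total"`: recall divides by all trials including NA.
#' Precision always divides correct answers by the number of times a room was
#' predicted (NA is never a prediction), so it is identical in both variants.
#' Percentages are rounded half-up to 2 decimals; a room never predicted gets
#' `NaN` precision (flagged undefined, not 0).
#'
#' @param records data frame with columns `actual_room` and `reported_room`
#'   (`NA` for unanswered trials).
#' @param variant `"answered"` or `"total"`.
#' @return a `room_confusion`: integer `counts` (6 x 7), `recall` and
#'   `precision` vectors in percent, and the variant.
#' @export
score_rooms <- function(records, variant = c("answered", "total")) {
  variant <- match.arg(variant)
  actual <- factor(records$actual_room, levels = room_labels)
  if (anyNA(actual)) spv_error("unknown actual room label",
                               "spv_validation_error")
  pred_chr <- as.character(records$reported_room)
  pred_chr[is.na(pred_chr) | pred_chr == "NA"] <- "na"
  if (!all(pred_chr %in% c(room_labels, "na")))
    spv_error("unknown reported room label", "spv_validation_error")
  predicted <- factor(pred_chr, levels = c(room_labels, "na"))
  counts <- table(actual = actual, predicted = predicted)

  correct <- diag(counts[, room_labels, drop = FALSE])
  answered <- rowSums(counts[, room_labels, drop = FALSE])
  total <- rowSums(counts)
  denom <- if (variant == "answered") answered else total
  recall <- ifelse(denom > 0, 100 * correct / denom, NaN)
  predicted_n <- colSums(counts[, room_labels, drop = FALSE])
  precision <- ifelse(predicted_n > 0, 100 * correct / predicted_n, NaN)
  structure(list(counts = unclass(counts), variant = variant,
                 recall = round_half_up(recall, 2),
                 precision = round_half_up(precision, 2)),
            class = "room_confusion")
}

#' @export
print.room_confusion <- function(x, ...) {
  cat(sprintf("Room identification confusion matrix (%s variant)\n",
              x$variant))
  m <- cbind(x$counts, recall = x$recall)
  print(m)
  cat("precision:\n")
  print(x$precision)
  invisible(x)
}

#' Summarize outcomes per stimulus method
#'
#' Percentage of correct, incorrect and not-answered trials for each method,
#' with a normal-approximation 95\% confidence half-width
#' `1.96 * sqrt(p(1-p)/n)` on the correct proportion; optionally grouped by
#' room type as well.
#'
#' @param records data frame with columns `method` and `outcome` (values
#'   `"correct"`, `"incorrect"`, `"na"`), plus `actual_room` when
#'   `by_room = TRUE`.
#' @param by_room split by room category too (default `FALSE`).
#' @return data frame with columns method (, room), n, pct_correct, ci95,
#'   pct_incorrect, pct_na. Groups with no records are omitted.
#' @export
summarize_responses <- function(records, by_room = FALSE) {
  groups <- if (by_room) split(records, list(records$method,
                                             records$actual_room), drop = TRUE)
            else split(records, records$method)
  rows <- lapply(names(groups), function(g) {
    r <- groups[[g]]
    n <- nrow(r)
    p <- mean(r$outcome == "correct")
    out <- data.frame(method = r$method[1], n = n,
                      pct_correct = round_half_up(100 * p, 2),
                      ci95 = round_half_up(100 * 1.96 * sqrt(p * (1 - p) / n), 2),
                      pct_incorrect = round_half_up(
                        100 * mean(r$outcome == "incorrect"), 2),
                      pct_na = round_half_up(100 * mean(r$outcome == "na"), 2),
                      stringsAsFactors = FALSE)
    if (by_room) out <- cbind(out[1], room = r$actual_room[1], out[-1])
    out
  })
  do.call(rbind, rows)
}

#' Read or write a response log CSV
#'
#' Column layout: `subject_id, scene_id, method, reported_objects
#' (semicolon-separated), reported_room, answered`.
#'
#' @param path CSV file.
#' @return `read_response_log()` returns a data frame with
#'   `reported_objects` split into character vectors (list column).
#' @export
read_response_log <- function(path) {
  if (!file.exists(path))
    spv_error(paste("missing file:", path), "spv_missing_file_error")
  log <- read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
  log$reported_objects <- lapply(strsplit(
    ifelse(is.na(log$reported_objects), "", log$reported_objects), ";"),
    function(x) x[nzchar(x)])
  log$answered <- as.logical(log$answered)
  log
}

#' @rdname read_response_log
#' @param log data frame in the layout above (`reported_objects` may be a
#'   list column).
#' @export
write_response_log <- function(log, path) {
  log$reported_objects <- vapply(log$reported_objects, paste,
                                 character(1), collapse = ";")
  write.csv(log, path, row.names = FALSE, na = "NA")
  invisible(path)
}
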