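# Paradigm: 30-class QWERTY/stream layout and pseudorandomised schedules.
#
# The speller maps the three QWERTY rows onto three pitch-segregated auditory
# streams: top row -> high stream, middle row -> mid stream, bottom row ->
# low stream.  The four symbols fill the short rows: comma joins the middle
# row, and space/delete/period join the bottom row, giving exactly ten
# classes per stream.

.STREAM_LEVELS <- c("low", "mid", "high")
.ROW_LEVELS <- c("bottom", "middle", "top")

#' Default 30-class letter/stream layout
#'
#' Returns the canonical mapping of the 26 letters and the four symbols
#' (comma, period, space, delete) to the three auditory streams. The top
#' QWERTY row (Q W E R T Y U I O P) maps to the high-pitch stream, the middle
#' row (A S D F G H J K L) plus comma to the mid stream, and the bottom row
#' (Z X C V B N M) plus space, delete and period to the low stream.
#'
#' @return data.frame with columns `class_id` (0-29), `label`, `stream`
#'   (low/mid/high) and `row` (bottom/middle/top); ten classes per stream.
#' @examples
#' layout <- defaultLayout()
#' table(layout$stream)
#' subset(layout, label == "T")
#' @export
defaultLayout <- function() {
  top <- c("Q", "W", "E", "R", "T", "Y", "U", "I", "O", "P")
  middle <- c("A", "S", "D", "F", "G", "H", "J", "K", "L", "<comma>")
  bottom <- c("Z", "X", "C", "V", "B", "N", "M",
              "<space>", "<delete>", "<period>")
  labels <- c(bottom, middle, top)
  stream <- rep(.STREAM_LEVELS, each = 10L)
  row <- rep(.ROW_LEVELS, each = 10L)
  data.frame(
    class_id = 0:29,
    label = labels,
    stream = factor(stream, levels = .STREAM_LEVELS),
    row = factor(row, levels = .ROW_LEVELS),
    stringsAsFactors = FALSE
  )
}

.checkLayout <- function(layout) {
  .check(is.data.frame(layout) && nrow(layout) == 30L,
         "layout must be a 30-row data.frame")
  .check(all(c("class_id", "label", "stream") %in% names(layout)),
         "layout must have class_id, label and stream columns")
  .check(all(table(layout$stream) == 10L),
         "layout must have exactly 10 classes per stream")
  invisible(layout)
}

#' Pseudorandomised stimulus schedule for one letter-selection trial
#'
#' A trial presents `nSequences` sequences; each sequence presents all 30
#' classes exactly once as ten stream-triplets cycling low, mid, high. Within
#' each stream the ten classes are independently and uniformly permuted per
#' sequence, so the within-stream order is unpredictable while consecutive
#' stimuli always alternate streams (the inter-stimulus interval within a
#' stream is exactly `3 * soaS`). Onsets lie on the SOA grid: stimulus `i`
#' (0-based, across the whole trial) starts at `i * soaS` seconds.
#'
#' @param layout layout data.frame from [defaultLayout()].
#' @param target `class_id` of the attended letter.
#' @param nSequences number of sequences (>= 1); 15 gives the standard
#'   450-stimulus trial.
#' @param soaS stimulus-onset asynchrony in seconds (default 0.2).
#' @param seed integer seed for the per-trial permutations (NULL = current
#'   RNG state).
#' @return list of class `TrialSchedule` with elements `target`, `soaS`,
#'   `nSequences` and `events`, a data.frame with one row per stimulus:
#'   `sequence` (1-based), `slot` (0-29 within the sequence), `class_id`,
#'   `label`, `stream`, `onset_s` and `is_target`.
#' @examples
#' sched <- makeTrialSchedule(defaultLayout(), target = 4, seed = 1)
#' nrow(sched$events)      # 450
#' sum(sched$events$is_target)  # 15
#' @export
makeTrialSchedule <- function(layout, target, nSequences = 15L,
                              soaS = 0.2, seed = NULL) {
  .checkLayout(layout)
  .check(length(target) == 1L && target %in% layout$class_id,
         "unknown target class_id")
  .check(nSequences >= 1L, "nSequences must be >= 1")
  .check(soaS > 0, "soaS must be positive")

  byStream <- split(layout$class_id, layout$stream)
  ord <- withSeed(seed, {
    unlist(lapply(seq_len(nSequences), function(s) {
      # independent uniform permutation per stream per sequence,
      # interleaved as ten (low, mid, high) triplets
      perms <- lapply(.STREAM_LEVELS, function(st) sample(byStream[[st]]))
      as.vector(rbind(perms[[1]], perms[[2]], perms[[3]]))
    }))
  })
  n <- length(ord)
  idx <- match(ord, layout$class_id)
  events <- data.frame(
    sequence = rep(seq_len(nSequences), each = 30L),
    slot = rep(0:29, times = nSequences),
    class_id = ord,
    label = layout$label[idx],
    stream = as.character(layout$stream[idx]),
    onset_s = (seq_len(n) - 1) * soaS,
    is_target = ord == target,
    stringsAsFactors = FALSE
  )
  structure(
    list(target = target, soaS = soaS, nSequences = as.integer(nSequences),
         events = events),
    class = "TrialSchedule"
  )
}

#' @export
print.TrialSchedule <- function(x, ...) {
  cat(sprintf(
    "TrialSchedule: target class %d, %d sequences x 30 stimuli, SOA %g s\n",
    x$target, x$nSequences, x$soaS))
  invisible(x)
}

#' Session plan: offline training runs plus online test runs
#'
#' The default session replicates the standard protocol: six offline runs of
#' five trials in which every one of the 30 classes is targeted exactly once
#' (a seeded permutation of the class set partitioned into runs), followed by
#' three online runs of five trials whose targets are drawn from a
#' configurable subset (by default a seeded choice of 15 distinct classes).
#'
#' @param layout layout data.frame.
#' @param seed master integer seed; the offline permutation, the online
#'   subset and every per-trial schedule seed derive from it.
#' @param offlineRuns,onlineRuns,trialsPerRun session geometry; the default
#'   6/3/5 requires `offlineRuns * trialsPerRun == 30`.
#' @param onlineTargets optional integer vector of class_ids to use as online
#'   targets (length `onlineRuns * trialsPerRun`); default is a seeded draw
#'   of 15 distinct classes.
#' @return list of class `SessionPlan` with `runs` (list of lists with
#'   `phase` ("offline"/"online") and `targets`), and `seed`.
#' @examples
#' plan <- makeSessionPlan(defaultLayout(), seed = 7)
#' length(plan$runs)  # 9
#' sort(unlist(lapply(plan$runs[1:6], `[[`, "targets")))  # 0..29
#' @export
makeSessionPlan <- function(layout, seed, offlineRuns = 6L, onlineRuns = 3L,
                            trialsPerRun = 5L, onlineTargets = NULL) {
  .checkLayout(layout)
  .check(offlineRuns * trialsPerRun == 30L,
         "offline runs must cover each of the 30 classes exactly once")
  nOn <- onlineRuns * trialsPerRun
  offTargets <- withSeed(childSeed(seed, 1L), sample(layout$class_id))
  if (is.null(onlineTargets)) {
    # default: distinct classes where possible (15 in the standard plan)
    onlineTargets <- withSeed(childSeed(seed, 2L),
                              sample(layout$class_id, nOn,
                                     replace = nOn > 30L))
  }
  .check(length(onlineTargets) == nOn,
         "onlineTargets must have onlineRuns * trialsPerRun entries")
  .check(all(onlineTargets %in% layout$class_id),
         "onlineTargets must be valid class_ids")

  runs <- vector("list", offlineRuns + onlineRuns)
  for (r in seq_len(offlineRuns)) {
    runs[[r]] <- list(
      phase = "offline",
      targets = offTargets[((r - 1) * trialsPerRun + 1):(r * trialsPerRun)]
    )
  }
  for (r in seq_len(onlineRuns)) {
    runs[[offlineRuns + r]] <- list(
      phase = "online",
      targets = onlineTargets[((r - 1) * trialsPerRun + 1):(r * trialsPerRun)]
    )
  }
  structure(list(runs = runs, seed = as.integer(seed)),
            class = "SessionPlan")
}

#' @export
print.SessionPlan <- function(x, ...) {
  ph <- vapply(x$runs, `[[`, "", "phase")
  cat(sprintf("SessionPlan: %d offline + %d online runs (seed %d)\n",
              sum(ph == "offline"), sum(ph == "online"), x$seed))
  invisible(x)
}

#' Build all trial schedules for a session plan
#'
#' Per-trial schedule seeds are derived deterministically from the plan's
#' master seed and the (run, trial) indices, so a plan fully determines its
#' schedules.
#'
#' @param plan a `SessionPlan`.
#' @param layout layout data.frame.
#' @param nSequences sequences per trial (default 15).
#' @param soaS SOA in seconds (default 0.2).
#' @return nested list: `schedules[[run]][[trial]]` is a `TrialSchedule`.
#' @export
makeSessionSchedules <- function(plan, layout, nSequences = 15L, soaS = 0.2) {
  lapply(seq_along(plan$runs), function(r) {
    tg <- plan$runs[[r]]$targets
    lapply(seq_along(tg), function(tr) {
      makeTrialSchedule(layout, tg[tr], nSequences = nSequences, soaS = soaS,
                        seed = childSeed(plan$seed, 10L + r, tr))
    })
  })
}

#' Write / read a stimulus events table as TSV
#'
#' One row per stimulus with columns `onset_s`, `run`, `trial`, `sequence`,
#' `slot`, `class_id`, `label`, `stream`, `is_target`; tab-separated with a
#' header and "." as the decimal mark.
#'
#' @param events events data.frame (e.g. from an [EEGRecording-class] or a
#'   `TrialSchedule`).
#' @param path file path.
#' @return `writeEventsTsv` returns `path` invisibly; `readEventsTsv`
#'   returns the events data.frame.
#' @export
writeEventsTsv <- function(events, path) {
  cols <- intersect(
    c("onset_s", "run", "trial", "sequence", "slot", "class_id",
      "label", "stream", "is_target"),
    names(events))
  write.table(events[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE, dec = ".")
  invisible(path)
}

#' @rdname writeEventsTsv
#' @export
readEventsTsv <- function(path) {
  ev <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!is.null(ev$is_target)) ev$is_target <- as.logical(ev$is_target)
  ev
}

#' Write a layout or session plan to YAML/JSON
#'
#' @param layout layout data.frame.
#' @param path output path; format chosen by extension (.yaml/.yml or .json).
#' @return `path`, invisibly.
#' @export
writeLayout <- function(layout, path) {
  .checkLayout(layout)
  obj <- lapply(seq_len(nrow(layout)), function(i) list(
    class_id = layout$class_id[i], label = layout$label[i],
    stream = as.character(layout$stream[i]),
    row = as.character(layout$row[i])))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

#' @rdname writeLayout
#' @export
readLayout <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  out <- do.call(rbind, lapply(obj, function(x)
    data.frame(class_id = as.integer(x$class_id), label = x$label,
               stream = x$stream, row = x$row, stringsAsFactors = FALSE)))
  out$stream <- factor(out$stream, levels = .STREAM_LEVELS)
  out$row <- factor(out$row, levels = .ROW_LEVELS)
  .checkLayout(out)
  out
}
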