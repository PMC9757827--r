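#' Pipeline configuration
#'
#' Controls the pipelined batch executor: reads are grouped into batches of
#' `batch_size`, and at most `batch_count` batches are in flight at any
#' instant (between stage-1 entry and stage-4 exit). With four stages and the
#' default window of 3, the executor realizes the schedule in which batch
#' *n* is in calibration while batch *n + 1* is in alignment and batch
#' *n + 2* is in event detection.
#'
#' @param batch_size Reads per batch.
#' @param batch_count Window of concurrently in-flight batches (>= 1).
#' @param threads Worker count handed to the HMM phase-A block assignment.
#' @param stage_durations Logical duration of each of the four stages, used
#'   for the trace timestamps.
#' @param stage_resources Resource class per stage (`"cpu"` or
#'   `"accelerator"`), bookkeeping only.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(batch_size = 10, batch_count = 3, threads = 1,
                            stage_durations = c(1, 1, 1, 1),
                            stage_resources = c("cpu", "accelerator",
                                                "cpu", "accelerator")) {
  stopifnot(batch_size >= 1, batch_count >= 1, threads >= 1,
            length(stage_durations) == 4, all(stage_durations > 0),
            length(stage_resources) == 4)
  structure(list(batch_size = as.integer(batch_size),
                 batch_count = as.integer(batch_count),
                 threads = as.integer(threads),
                 stage_durations = as.numeric(stage_durations),
                 stage_resources = stage_resources),
            class = "pipeline_config")
}

#' Run batches through the four-stage pipeline
#'
#' Executes the four stage functions on every batch under the pipelined
#' schedule: (a) at most `batch_count` batches are in flight at any instant;
#' (b) per stage, batches enter in `batch_id` order and at most one batch
#' occupies a stage at a time (the next batch waits until the previous one is
#' done with that stage); (c) because the stage functions are pure per-batch
#' transformations, the combined output is identical to serial execution.
#'
#' The schedule is computed deterministically on a logical clock (stage
#' durations from the config) and the stage functions are executed in
#' schedule order, so the trace and all outputs are reproducible to the byte
#' for any window size.
#'
#' @param batches A list of batch payloads (any object a stage function
#'   accepts; typically a tibble of reads).
#' @param config A [pipeline_config()].
#' @param stage_fns A list of exactly 4 functions, each `function(batch)`
#'   returning the transformed batch. A stage error marks the batch failed;
#'   remaining batches are drained.
#' @return A list of class `pipeline_run`: `results` (per-batch outputs, in
#'   batch order; `NULL` for failed batches), `trace` (a `pipeline_trace`
#'   tibble: `time`, `batch_id`, `stage`, `event`), `failed` (tibble of
#'   `batch_id`, `stage`, `message`), `ok` (logical).
#' @export
run_pipeline <- function(batches, config = pipeline_config(), stage_fns) {
  stopifnot(is.list(stage_fns), length(stage_fns) == 4)
  nb <- length(batches)
  stage_names <- c("event_detection", "alignment", "calibration",
                   "methylation_score")
  if (nb == 0) {
    return(structure(list(results = list(),
                          trace = empty_trace(),
                          failed = tibble(batch_id = integer(),
                                          stage = character(),
                                          message = character()),
                          ok = TRUE),
                     class = "pipeline_run"))
  }
  dur <- config$stage_durations
  w <- config$batch_count

  # Closed-form schedule realizing the window semaphore + per-stage locks +
  # in-order stage entry. enter[b, s] = max(own previous stage done,
  # previous batch left stage s, admission slot free).
  enter <- matrix(0, nb, 4)
  exit <- matrix(0, nb, 4)
  for (b in seq_len(nb)) {
    for (s in 1:4) {
      t <- if (s > 1) exit[b, s - 1] else 0
      if (b > 1) t <- max(t, exit[b - 1, s])
      if (s == 1 && b > w) t <- max(t, exit[b - w, 4])
      enter[b, s] <- t
      exit[b, s] <- t + dur[s]
    }
  }

  # Execute in schedule order (ties broken by batch then stage; stage
  # dependencies are respected because enter times are non-decreasing along
  # each batch's stages).
  ord <- order(enter[cbind(rep(seq_len(nb), 4), rep(1:4, each = nb))],
               rep(seq_len(nb), 4), rep(1:4, each = nb))
  events <- data.frame(batch = rep(seq_len(nb), 4),
                       stage = rep(1:4, each = nb))[ord, ]

  results <- batches
  failed_at <- rep(NA_integer_, nb)
  failed_msg <- rep(NA_character_, nb)
  for (i in seq_len(nrow(events))) {
    b <- events$batch[i]; s <- events$stage[i]
    if (!is.na(failed_at[b])) next
    res <- tryCatch(stage_fns[[s]](results[[b]]), error = function(e) e)
    if (inherits(res, "error")) {
      failed_at[b] <- s
      failed_msg[b] <- conditionMessage(res)
      results[b] <- list(NULL)
    } else {
      results[[b]] <- res
    }
  }

  trace <- tibble(
    time = c(as.vector(t(enter)), as.vector(t(exit))),
    batch_id = rep(rep(seq_len(nb), each = 4), 2),
    stage = rep(rep(stage_names, nb), 2),
    event = rep(c("enter", "exit"), each = 4 * nb)
  )
  trace <- dplyr::arrange(trace, .data$time,
                          factor(.data$event, levels = c("exit", "enter")),
                          .data$batch_id)
  class(trace) <- c("pipeline_trace", class(trace))

  failed <- tibble(batch_id = which(!is.na(failed_at)),
                   stage = stage_names[failed_at[!is.na(failed_at)]],
                   message = failed_msg[!is.na(failed_at)])
  structure(list(results = results, trace = trace, failed = failed,
                 ok = nrow(failed) == 0),
            class = "pipeline_run")
}

empty_trace <- function() {
  tr <- tibble(time = numeric(), batch_id = integer(),
               stage = character(), event = character())
  class(tr) <- c("pipeline_trace", class(tr))
  tr
}

#' Maximum number of concurrently in-flight batches in a trace
#'
#' Sweep-line over the trace: a batch is in flight between its
#' `event_detection` enter and its `methylation_score` exit. Exits at a
#' timestamp are processed before enters at the same timestamp (the leaving
#' batch frees its window slot).
#'
#' @param trace A `pipeline_trace` tibble.
#' @return Integer maximum concurrency (0 for an empty trace).
#' @export
max_concurrency <- function(trace) {
  if (nrow(trace) == 0) return(0L)
  first_stage <- "event_detection"
  last_stage <- "methylation_score"
  starts <- trace$time[trace$stage == first_stage & trace$event == "enter"]
  ends <- trace$time[trace$stage == last_stage & trace$event == "exit"]
  pts <- rbind(data.frame(t = starts, d = 1L, o = 2L),
               data.frame(t = ends, d = -1L, o = 1L))
  pts <- pts[order(pts$t, pts$o), ]
  max(cumsum(pts$d))
}

#' Per-batch stage occupancy intervals of a trace
#'
#' @param trace A `pipeline_trace` tibble.
#' @return A tibble with `batch_id`, `stage`, `enter`, `exit`.
#' @export
stage_intervals <- function(trace) {
  ent <- trace[trace$event == "enter", c("batch_id", "stage", "time")]
  ext <- trace[trace$event == "exit", c("batch_id", "stage", "time")]
  names(ent)[3] <- "enter"
  names(ext)[3] <- "exit"
  out <- dplyr::left_join(ent, ext, by = c("batch_id", "stage"))
  as_tibble(out)
}

#' Write a pipeline trace as tab-separated text
#'
#' @param trace A `pipeline_trace` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_tsv <- function(trace, path) {
  lines <- c("time\tbatch_id\tstage\tevent",
             sprintf("%.6g\t%d\t%s\t%s", trace$time, trace$batch_id,
                     trace$stage, trace$event))
  writeLines(lines, path)
  invisible(path)
}

#' Gantt-style plot of a pipeline trace
#'
#' @param object A `pipeline_trace` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pipeline_trace <- function(object, ...) {
  iv <- stage_intervals(object)
  iv$stage <- factor(iv$stage, levels = c("event_detection", "alignment",
                                          "calibration", "methylation_score"))
  ggplot(iv, aes(y = factor(.data$batch_id), colour = .data$stage)) +
    geom_segment(aes(x = .data$enter, xend = .data$exit,
                     yend = factor(.data$batch_id)), linewidth = 3) +
    labs(x = "logical time", y = "batch", colour = "stage") +
    theme_minimal()
}
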