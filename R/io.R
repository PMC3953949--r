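#' Write a behavioural session to CSV
#'
#' Two plain-text files: \code{<stem>.csv} with one row per trial
#' (index, odor, valence, the four lick-bin booleans, ITI, and the scored
#' response when present) and \code{<stem>_beam.csv} with the beam-break
#' traces (first column \code{trial}, remaining columns one per time
#' point, header giving the time in ms).
#'
#' @param session a \code{glom_session}.
#' @param stem output path without extension.
#' @return invisibly, the two file paths.
#' @export
write_session_csv <- function(session, stem) {
  trial_path <- paste0(stem, ".csv")
  beam_path <- paste0(stem, "_beam.csv")
  tr <- session$trials
  meta <- sprintf("# mouse=%s odor_pair=%s dilution_exponent=%d group=%s",
                  session$mouse_id, paste(session$odor_pair, collapse = "|"),
                  session$dilution_exponent, session$group)
  con <- file(trial_path, "w")
  writeLines(meta, con)
  write.csv(tr, con, row.names = FALSE)
  close(con)
  beam <- data.frame(trial = seq_len(nrow(session$beam$traces)),
                     session$beam$traces * 1L)
  names(beam)[-1] <- paste0("t", session$beam$times_ms)
  write.csv(beam, beam_path, row.names = FALSE)
  invisible(c(trial_path, beam_path))
}

#' Read a behavioural session written by \code{\link{write_session_csv}}
#'
#' @param stem path stem used when writing.
#' @return a \code{glom_session}.
#' @export
read_session_csv <- function(stem) {
  trial_path <- paste0(stem, ".csv")
  header <- readLines(trial_path, n = 1L)
  kv <- regmatches(header, gregexpr("[a-z_]+=[^ ]+", header))[[1]]
  meta <- setNames(sub("^[a-z_]+=", "", kv), sub("=.*$", "", kv))
  tr <- read.csv(trial_path, skip = 1L, stringsAsFactors = FALSE)
  for (b in c("bin1", "bin2", "bin3", "bin4"))
    tr[[b]] <- as.logical(tr[[b]])
  beam <- read.csv(paste0(stem, "_beam.csv"), check.names = FALSE)
  times <- as.numeric(sub("^t", "", names(beam)[-1]))
  traces <- as.matrix(beam[, -1, drop = FALSE]) > 0
  dimnames(traces) <- NULL
  structure(list(mouse_id = unname(meta["mouse"]),
                 odor_pair = strsplit(unname(meta["odor_pair"]), "|",
                                      fixed = TRUE)[[1]],
                 dilution_exponent = as.integer(meta["dilution_exponent"]),
                 group = unname(meta["group"]),
                 trials = tr,
                 beam = list(times_ms = times, traces = traces)),
            class = "glom_session")
}

#' Write a performance curve to CSV and JSON
#'
#' @param curve a \code{performance_curve}.
#' @param stem output path without extension; writes \code{<stem>.csv}
#'   (dilution_exponent, accuracy_pct) and \code{<stem>.json} (including
#'   block accuracies).
#' @return invisibly, the file paths.
#' @export
write_performance_curve <- function(curve, stem) {
  csv <- paste0(stem, ".csv"); js <- paste0(stem, ".json")
  write.csv(data.frame(dilution_exponent = curve$dilution_exponents,
                       accuracy_pct = curve$accuracy_pct),
            csv, row.names = FALSE)
  jsonlite::write_json(unclass(curve), js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}

#' Write a respiration trace to CSV
#' @param trace an \code{airflow_trace}.
#' @param path output CSV path (columns \code{time_s}, \code{signal}).
#' @return invisibly, the path.
#' @export
write_respiration_csv <- function(trace, path) {
  write.csv(data.frame(time_s = trace$times_s, signal = trace$signal),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a respiration trace from CSV
#' @param path CSV with columns \code{time_s}, \code{signal}.
#' @param odor_window_s analysis window metadata.
#' @return an \code{airflow_trace}.
#' @export
read_respiration_csv <- function(path, odor_window_s = c(2, 4)) {
  d <- read.csv(path)
  structure(list(times_s = d$time_s, signal = d$signal,
                 odor_window_s = odor_window_s, cycle_times_s = NULL),
            class = "airflow_trace")
}

#' Write a trial stack as plain text (long CSV + JSON sidecar)
#'
#' Stacks are exchanged as a long-format CSV (\code{frame}, \code{row},
#' \code{col}, \code{value}) plus a JSON sidecar holding frame rate, odor
#' window and stimulus metadata.
#'
#' @param stack a \code{glom_stack}.
#' @param stem path stem; writes \code{<stem>_frames.csv} and
#'   \code{<stem>.json}.
#' @return invisibly, the file paths.
#' @export
write_stack_csv <- function(stack, stem) {
  d <- dim(stack$frames)
  frames_path <- paste0(stem, "_frames.csv")
  grid <- expand.grid(frame = seq_len(d[1]), row = seq_len(d[2]),
                      col = seq_len(d[3]))
  grid$value <- as.numeric(stack$frames)
  write.csv(grid, frames_path, row.names = FALSE)
  side <- stack[c("frame_rate_hz", "odor_window_s", "odorant",
                  "dilution_exponent", "repetition", "group")]
  side$dim <- d
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(frames_path, paste0(stem, ".json")))
}

#' Read a trial stack written by \code{\link{write_stack_csv}}
#' @param stem path stem used when writing.
#' @return a \code{glom_stack} (without ground truth).
#' @export
read_stack_csv <- function(stem) {
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  d <- read.csv(paste0(stem, "_frames.csv"))
  frames <- array(0, dim = side$dim)
  frames[cbind(d$frame, d$row, d$col)] <- d$value
  structure(list(frames = frames, frame_rate_hz = side$frame_rate_hz,
                 odor_window_s = side$odor_window_s, odorant = side$odorant,
                 dilution_exponent = side$dilution_exponent,
                 repetition = side$repetition, group = side$group,
                 truth = NULL),
            class = "glom_stack")
}

#' Write an amplitude table to CSV
#' @param amps data frame (mouse, group, odorant, dilution_exponent,
#'   roi_id, rep, amplitude_permil).
#' @param path CSV path.
#' @return invisibly, the path.
#' @export
write_amplitude_table <- function(amps, path) {
  write.csv(amps, path, row.names = FALSE)
  invisible(path)
}
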