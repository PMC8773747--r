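#' Build the two-session emotional stimulus-response schedule
#'
#' Constructs the timed event list of one experimental session: 20 trials,
#' each consisting of a 1 s trial-number display, five stimulus-response
#' repetitions (0.5 s warning face, 2 s anticipation without display, 2 s
#' target image plus response, 0.5 s feedback), and a 35 s inter-task rest.
#' A session therefore spans exactly 20 x (1 + 25 + 35) = 1220 s and contains
#' 100 target events. In session 1 the warning face is positive and exactly
#' 30 of the 100 target images are positive; in session 2 the warning face is
#' negative and exactly 30 target images are negative. Which repetitions carry
#' the minority valence is a seeded random permutation, so the 30/70 split is
#' exact by design, not binomial.
#'
#' @param session_id 1 or 2.
#' @param seed Integer seed controlling only the valence permutation.
#'
#' @return A `stim_schedule`: a data frame of events with columns
#'   `onset`, `duration` (seconds), `kind` (one of `trial_number`, `warning`,
#'   `anticipation`, `target`, `feedback`, `rest`), `valence` (`positive`,
#'   `negative`, `none`), `trial` (1-20) and `rep` (1-5 or `NA`), plus
#'   attributes `session_id` and `seed`.
#' @export
#' @examples
#' sched <- build_session_schedule(1, seed = 0)
#' table(subset(sched, kind == "target")$valence)
build_session_schedule <- function(session_id, seed = 0L) {
  assert_that(is_scalar_number(session_id) && session_id %in% c(1, 2),
              "session_id must be 1 or 2")
  assert_that(is_scalar_number(seed), "seed must be a single integer")
  n_trials <- 20L
  n_reps <- 5L
  durs <- c(warning = 0.5, anticipation = 2, target = 2, feedback = 0.5)
  trial_len <- 1 + n_reps * sum(durs) + 35

  minority <- if (session_id == 1) "positive" else "negative"
  majority <- if (session_id == 1) "negative" else "positive"
  n_targets <- n_trials * n_reps
  valences <- rep(majority, n_targets)
  idx <- withr_seed(seed, sample.int(n_targets, round(0.3 * n_targets)))
  valences[idx] <- minority

  rows <- vector("list", n_trials)
  tgt <- 0L
  for (tr in seq_len(n_trials)) {
    t0 <- (tr - 1) * trial_len
    ev <- list(data.frame(onset = t0, duration = 1, kind = "trial_number",
                          valence = "none", trial = tr, rep = NA_integer_))
    t <- t0 + 1
    for (rp in seq_len(n_reps)) {
      tgt_val <- valences[tgt + rp]
      ev[[length(ev) + 1L]] <- data.frame(
        onset = t + cumsum(c(0, durs))[1:4],
        duration = unname(durs),
        kind = names(durs),
        valence = c("none", "none", tgt_val, "none"),
        trial = tr, rep = rp)
      t <- t + sum(durs)
    }
    tgt <- tgt + n_reps
    ev[[length(ev) + 1L]] <- data.frame(onset = t, duration = 35, kind = "rest",
                                        valence = "none", trial = tr,
                                        rep = NA_integer_)
    rows[[tr]] <- do.call(rbind, ev)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, session_id = as.integer(session_id), seed = as.integer(seed),
            class = c("stim_schedule", "data.frame"))
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Session span in seconds
#' @param schedule A `stim_schedule`.
#' @return Scalar end time of the last event (1220 for the standard design).
#' @export
schedule_span <- function(schedule) {
  n <- nrow(schedule)
  schedule$onset[n] + schedule$duration[n]
}

#' Task onsets used for epoching
#'
#' The task onset of a trial is the start of its first warning stimulus,
#' i.e. 1 s after the trial-number display begins, so that the 61 s epoch
#' window spans the 25 s stimulus-response block plus the 35 s rest.
#'
#' @param schedule A `stim_schedule`.
#' @return Strictly increasing numeric vector of 20 onset times in seconds.
#' @export
#' @examples
#' trial_onsets(build_session_schedule(1, 0))[1:3]  # 1, 62, 123
trial_onsets <- function(schedule) {
  assert_that(inherits(schedule, "stim_schedule"),
              "schedule must be a stim_schedule")
  w <- schedule[schedule$kind == "warning" & schedule$rep == 1L, ]
  w <- w[order(w$trial), ]
  w$onset
}

#' Write / read a schedule as a tab-separated events file
#'
#' The dialect mirrors BIDS `events.tsv`: columns `onset`, `duration`,
#' `kind`, `valence`, `trial`, `rep`, tab-separated with a header row.
#'
#' @param schedule A `stim_schedule`.
#' @param path Output file path.
#' @return `write_events` returns `path` invisibly; `read_events` returns a
#'   `stim_schedule` (with `session_id`/`seed` attributes restored from the
#'   header comment when present).
#' @export
write_events <- function(schedule, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# session_id=%d seed=%d",
                     attr(schedule, "session_id"), attr(schedule, "seed")), con)
  write.table(as.data.frame(schedule), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- c(session_id = NA_integer_, seed = NA_integer_)
  if (startsWith(hdr, "#")) {
    m <- regmatches(hdr, gregexpr("[a-z_]+=-?[0-9]+", hdr))[[1]]
    for (kv in m) {
      kv <- strsplit(kv, "=", fixed = TRUE)[[1]]
      meta[kv[1]] <- as.integer(kv[2])
    }
  }
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  structure(df, session_id = meta[["session_id"]], seed = meta[["seed"]],
            class = c("stim_schedule", "data.frame"))
}
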