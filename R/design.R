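## Stimulus schedules and their convolution into volume-sampled
## regressors. All schedules are padded with trailing blank so the run
## length is an integer multiple of the TR.

padToTR <- function(duration, tr) ceiling(duration / tr - 1e-9) * tr

#' Alternating two-condition fast-switch design
#'
#' Two conditions presented in strict alternation, each lasting
#' \code{switchEvery} seconds with no gaps, covering the full run. With
#' the default 2 s switch the design has a 4 s fundamental period
#' (0.25 Hz), the fastest contrast a TR of 2 s can carry.
#'
#' @param switchEvery seconds per condition epoch.
#' @param totalDuration run length in seconds; must be a multiple of
#'   \code{2 * switchEvery}.
#' @param tr volume repetition time in seconds.
#' @return an [EventSchedule-class] with conditions 0 and 1.
#' @export
alternatingDesign <- function(switchEvery = 2, totalDuration = 480, tr = 2) {
  stopIfNot(switchEvery > 0, "invalid parameter: switchEvery must be positive")
  if (!isMultiple(totalDuration, 2 * switchEvery))
    stop("invalid parameter: totalDuration must be a multiple of 2 * switchEvery",
         call. = FALSE)
  onsets <- seq(0, totalDuration - switchEvery, by = switchEvery)
  ev <- data.frame(onset = onsets, duration = switchEvery,
                   condition = rep_len(c(0L, 1L), length(onsets)))
  newEventSchedule(ev, tr, padToTR(totalDuration, tr))
}

#' Rapid event-related schedule
#'
#' One trial per stimulus condition plus interleaved null trials, in a
#' seeded random order. Each stimulus slot is \code{stimDuration} of
#' stimulus followed by \code{isi} of blank; each null slot is
#' \code{nullSlot} seconds of blank (condition -1). Every condition
#' label 0..nStimuli-1 appears exactly once. The defaults (48 images of
#' 0.5 s with 2.5 s ISI, 30 null slots of 3 s, TR 2 s) give a run of
#' 234 s = 117 volumes.
#'
#' @param nStimuli number of distinct stimulus conditions.
#' @param stimDuration stimulus presentation time in seconds.
#' @param isi inter-stimulus blank in seconds.
#' @param nNull number of null trials.
#' @param nullSlot seconds occupied by one null trial.
#' @param tr volume repetition time in seconds.
#' @param seed integer seed; required, the slot permutation is random.
#' @return an [EventSchedule-class].
#' @examples
#' s <- rapidERSchedule(seed = 7)
#' nVolumes(s)  # 117
#' @export
rapidERSchedule <- function(nStimuli = 48, stimDuration = 0.5, isi = 2.5,
                            nNull = 30, nullSlot = 3.0, tr = 2, seed) {
  if (missing(seed))
    stop("seed is required: the trial order is a seeded random permutation",
         call. = FALSE)
  stopIfNot(nStimuli >= 1, "invalid parameter: nStimuli must be >= 1")
  stopIfNot(stimDuration + isi > 0,
            "invalid parameter: stimDuration + isi must be positive")
  slotDur <- c(rep(stimDuration + isi, nStimuli), rep(nullSlot, nNull))
  slotCond <- c(seq_len(nStimuli) - 1L, rep(-1L, nNull))
  ord <- withSeed(seed, sample.int(nStimuli + nNull))
  slotDur <- slotDur[ord]
  slotCond <- slotCond[ord]
  onsets <- cumsum(c(0, slotDur[-length(slotDur)]))
  ev <- data.frame(
    onset = onsets,
    duration = ifelse(slotCond >= 0, stimDuration, slotDur),
    condition = slotCond)
  newEventSchedule(ev, tr, padToTR(sum(slotDur), tr))
}

#' Block design schedule
#'
#' Alternating ON/OFF blocks. Within each ON block, stimulus events are
#' packed as full (stimDuration + isi) cycles while they fit, plus one
#' final stimulus if the stimulus alone still fits before the block
#' ends. All stimulus events carry condition 0; OFF blocks are blank.
#'
#' @param onDuration ON block length in seconds (multiple of tr).
#' @param offDuration OFF block length in seconds (multiple of tr).
#' @param stimDuration single stimulus presentation in seconds.
#' @param isi inter-stimulus blank within a block, in seconds.
#' @param nCycles number of ON+OFF cycles.
#' @param tr volume repetition time in seconds.
#' @return an [EventSchedule-class].
#' @export
blockSchedule <- function(onDuration = 32, offDuration = 16,
                          stimDuration = 0.4, isi = 0.5, nCycles = 5, tr = 2) {
  stopIfNot(isMultiple(onDuration, tr) && isMultiple(offDuration, tr),
            "invalid parameter: block durations must be multiples of tr")
  if (stimDuration + isi > onDuration)
    stop("invalid parameter: one stimulus cycle exceeds the ON block",
         call. = FALSE)
  cyc <- stimDuration + isi
  nFull <- floor(onDuration / cyc + 1e-9)
  withinOn <- (seq_len(nFull) - 1L) * cyc
  if (nFull * cyc + stimDuration <= onDuration + 1e-9)
    withinOn <- c(withinOn, nFull * cyc)
  blockStarts <- (seq_len(nCycles) - 1L) * (onDuration + offDuration)
  onsets <- as.vector(outer(withinOn, blockStarts, `+`))
  ev <- data.frame(onset = sort(onsets), duration = stimDuration,
                   condition = 0L)
  newEventSchedule(ev, tr, nCycles * (onDuration + offDuration))
}

#' Convolve a schedule with an impulse response
#'
#' Builds a stimulus indicator on the impulse response's fine time grid,
#' convolves it with the response, and samples at the end of each TR
#' (t = tr, 2 tr, ...). \code{condition} selects what is convolved:
#' a single integer label gives that condition's boxcar; a named numeric
#' vector gives a weighted contrast boxcar (names are condition labels);
#' the string \code{"contrast"} is shorthand for +1 on condition 0 and
#' -1 on condition 1; \code{"all"} is the indicator of every stimulus
#' event. Null events (condition -1) never enter the boxcar.
#'
#' @param schedule an [EventSchedule-class].
#' @param irf an [ImpulseResponse-class] whose dt divides the TR.
#' @param condition condition selector (see Details).
#' @return a [SampledRegressor-class] with one value per volume.
#' @export
convolveSchedule <- function(schedule, irf, condition = "all") {
  ev <- events(schedule)
  stopIfNot(nrow(ev) > 0, "schedule has no events")
  dt <- timeStep(irf)
  tr <- trTime(schedule)
  if (!isMultiple(tr, dt))
    stop("grid mismatch: irf dt must divide the schedule TR", call. = FALSE)
  if (is.character(condition) && length(condition) == 1L &&
      condition == "contrast") {
    condition <- c("0" = 1, "1" = -1)
  }
  if (is.numeric(condition) && is.null(names(condition)) &&
      length(condition) == 1L) {
    weights <- stats::setNames(1, as.character(condition))
    label <- paste0("condition_", condition)
  } else if (is.numeric(condition)) {
    weights <- condition
    label <- paste(names(condition), condition, sep = "*", collapse = " + ")
  } else if (identical(condition, "all")) {
    labs <- unique(ev$condition[ev$condition >= 0])
    weights <- stats::setNames(rep(1, length(labs)), as.character(labs))
    label <- "all"
  } else stop("invalid condition selector", call. = FALSE)

  nFine <- as.integer(round(totalDuration(schedule) / dt)) + 1L
  box <- numeric(nFine)
  for (i in seq_len(nrow(ev))) {
    cnd <- as.character(ev$condition[i])
    if (ev$condition[i] < 0 || !(cnd %in% names(weights))) next
    i0 <- as.integer(round(ev$onset[i] / dt)) + 1L
    i1 <- min(nFine, as.integer(round((ev$onset[i] + ev$duration[i]) / dt)))
    if (i1 >= i0) box[i0:i1] <- box[i0:i1] + weights[[cnd]]
  }
  h <- samples(irf)
  y <- stats::convolve(c(box, numeric(length(h))), rev(h), type = "open")
  y <- y[seq_len(nFine)]
  step <- as.integer(round(tr / dt))
  vol <- seq_len(nVolumes(schedule)) * step + 1L
  vol <- vol[vol <= nFine]
  vals <- numeric(nVolumes(schedule))
  vals[seq_along(vol)] <- y[vol]
  new("SampledRegressor", values = vals, tr = tr, condition = label)
}

#' Write / read schedules and regressors as CSV
#'
#' Schedules serialize as (onset_s, duration_s, condition) with a
#' comment header carrying tr and total duration; regressors as
#' (volume_index, time_s, value). Both round-trip without loss.
#'
#' @param schedule an [EventSchedule-class].
#' @param regressor a [SampledRegressor-class].
#' @param path file path.
#' @return readers return the reconstructed object; writers return
#'   \code{path} invisibly.
#' @export
writeSchedule <- function(schedule, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tr=%s, total_duration=%s",
                     format(trTime(schedule), digits = 17),
                     format(totalDuration(schedule), digits = 17)), con)
  ev <- events(schedule)
  writeLines("onset_s,duration_s,condition", con)
  writeLines(paste(format(ev$onset, digits = 17, trim = TRUE),
                   format(ev$duration, digits = 17, trim = TRUE),
                   ev$condition, sep = ","), con)
  invisible(path)
}

#' @rdname writeSchedule
#' @export
readSchedule <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^# ", "", lines[[1L]]), ", ")[[1L]]
  kv <- vapply(strsplit(hdr, "="), `[`, character(1), 2)
  names(kv) <- vapply(strsplit(hdr, "="), `[`, character(1), 1)
  tab <- utils::read.csv(text = lines[-1L])
  ev <- data.frame(onset = tab$onset_s, duration = tab$duration_s,
                   condition = as.integer(tab$condition))
  newEventSchedule(ev, as.numeric(kv[["tr"]]),
                   as.numeric(kv[["total_duration"]]))
}

#' @rdname writeSchedule
#' @export
writeRegressor <- function(regressor, path) {
  v <- values(regressor)
  tab <- data.frame(volume_index = seq_along(v),
                    time_s = seq_along(v) * trTime(regressor),
                    value = v)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tr=%s, condition=%s",
                     format(trTime(regressor), digits = 17),
                     regressor@condition), con)
  writeLines("volume_index,time_s,value", con)
  writeLines(paste(tab$volume_index,
                   format(tab$time_s, digits = 17, trim = TRUE),
                   format(tab$value, digits = 17, trim = TRUE), sep = ","),
             con)
  invisible(path)
}
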