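#' Beat frequencies of the stimulation protocol
#'
#' The binaural-beat frequencies used by the protocol: 1 Hz steps from
#' 1 to 20 Hz and 2 Hz steps from 20 to 48 Hz. The boundary value 20 Hz
#' belongs to both ranges and is emitted once, giving 34 distinct
#' frequencies, one per stimulation block.
#'
#' @return Sorted numeric vector of beat frequencies in Hz.
#' @examples
#' length(generate_beat_frequencies())  # 34
#' @export
generate_beat_frequencies <- function() {
  sort(unique(c(seq(1, 20, by = 1), seq(20, 48, by = 2))))
}

#' Build the block schedule of a stimulation session
#'
#' Each of the 34 blocks lasts 140 s: 20 s silence, 60 s of the
#' non-binaural (NB) condition in which both ears receive the carrier
#' tone, then 60 s of the binaural (BB) condition in which the right ear
#' receives the carrier shifted by the block's beat frequency. Every
#' beat frequency appears in exactly one block.
#'
#' @param order_seed Integer seed controlling the block permutation, or
#'   `NULL` to keep blocks in ascending beat-frequency order.
#' @param f_b Carrier ("base") frequency in Hz.
#' @param silence_s,nb_s,bb_s Durations of the three block segments in
#'   seconds.
#' @return A data frame of class `bb_schedule` with one row per block:
#'   `block_index`, `f_b`, `f_bb`, `band`, `t_silence`, `t_nb`, `t_bb`.
#' @examples
#' sched <- build_schedule(order_seed = 1)
#' table(sched$band)
#' @export
build_schedule <- function(order_seed = NULL, f_b = 200,
                           silence_s = 20, nb_s = 60, bb_s = 60) {
  f_bb <- generate_beat_frequencies()
  if (!is.null(order_seed)) {
    f_bb <- withr_seed(order_seed, sample(f_bb))
  }
  out <- data.frame(
    block_index = seq_along(f_bb),
    f_b = f_b,
    f_bb = f_bb,
    band = band_of(f_bb, bb_bands("BB")),
    t_silence = silence_s,
    t_nb = nb_s,
    t_bb = bb_s,
    stringsAsFactors = FALSE
  )
  class(out) <- c("bb_schedule", "data.frame")
  out
}

#' @export
print.bb_schedule <- function(x, ...) {
  cat(sprintf(
    "Binaural-beat schedule: %d blocks of %g s (%g s silence + %g s NB + %g s BB)\n",
    nrow(x), x$t_silence[1] + x$t_nb[1] + x$t_bb[1],
    x$t_silence[1], x$t_nb[1], x$t_bb[1]))
  cat(sprintf("carrier %g Hz; beat frequencies %g-%g Hz\n",
              x$f_b[1], min(x$f_bb), max(x$f_bb)))
  print(table(factor(x$band, levels = band_levels)))
  invisible(x)
}

#' Total duration of one schedule block in seconds
#' @param schedule A `bb_schedule`.
#' @export
block_duration <- function(schedule) {
  unname(schedule$t_silence[1] + schedule$t_nb[1] + schedule$t_bb[1])
}

#' Synthesize the dichotic audio of one block segment
#'
#' During BB the left ear receives a pure tone at `f_b` and the right
#' ear a pure tone at `f_b + f_bb`; their superposition waxes and wanes
#' at the beat frequency, which is the percept the protocol elicits.
#' With `f_bb = 0` the two channels are identical (NB condition).
#'
#' @param f_b Carrier frequency, Hz.
#' @param f_bb Beat frequency, Hz (0 for the NB condition).
#' @param duration_s Segment duration in seconds.
#' @param sr Audio sample rate in Hz; must be at least four times the
#'   highest tone frequency so the carrier is far below Nyquist.
#' @param amplitude Tone amplitude, fraction of full scale per ear.
#' @return Matrix with `duration_s * sr` rows and columns `left`,
#'   `right`.
#' @examples
#' w <- synthesize_dichotic_audio(200, 10, duration_s = 1)
#' @export
synthesize_dichotic_audio <- function(f_b = 200, f_bb = 0, duration_s = 60,
                                      sr = 8000, amplitude = 0.5) {
  f_hi <- f_b + f_bb
  if (sr < 4 * f_hi) {
    stop("sample rate ", sr, " Hz too low for a ", f_hi,
         " Hz tone (need >= ", 4 * f_hi, " Hz)", call. = FALSE)
  }
  t <- seq(0, duration_s - 1 / sr, by = 1 / sr)
  cbind(left = amplitude * sin(2 * pi * f_b * t),
        right = amplitude * sin(2 * pi * f_hi * t))
}

#' Write a schedule as a tab-separated table
#' @param schedule A `bb_schedule`.
#' @param path Output path.
#' @export
write_schedule_tsv <- function(schedule, path) {
  utils::write.table(as.data.frame(schedule), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a schedule written by [write_schedule_tsv()]
#' @param path Input path.
#' @export
read_schedule_tsv <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  class(out) <- c("bb_schedule", "data.frame")
  out
}

# Evaluate `expr` under a local RNG seed without disturbing the
# caller's RNG state.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
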