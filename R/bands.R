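#' Frequency band definitions
#'
#' The five classical EEG frequency bands and the matching grouping of
#' binaural-beat (BB) frequencies. Both contexts use the same edges:
#' delta 1-4 Hz, theta 5-8 Hz, alpha 9-12 Hz, beta 13-30 Hz and gamma
#' 32-48 Hz. Edges are inclusive on both sides; the gap at 31 Hz is
#' intentional (no stimulus or analysis bin falls there on the grids
#' used).
#'
#' @param context `"BB"` for beat-frequency grouping or `"EEG"` for
#'   analysis bands. The edges coincide, but the two uses are kept
#'   distinct so a schedule band and an analysis band are never
#'   silently interchanged.
#' @return A data frame with columns `name`, `f_lo`, `f_hi`, `context`.
#' @examples
#' bb_bands("EEG")
#' @export
bb_bands <- function(context = c("BB", "EEG")) {
  context <- match.arg(context)
  out <- data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    f_lo = c(1, 5, 9, 13, 32),
    f_hi = c(4, 8, 12, 30, 48),
    context = context,
    stringsAsFactors = FALSE
  )
  out
}

#' Map a frequency to its band
#'
#' @param f Frequency in Hz (vectorized).
#' @param bands Band definition table, as returned by [bb_bands()].
#' @return Character vector of band names.
#' @examples
#' band_of(c(4, 12, 32))
#' @export
band_of <- function(f, bands = bb_bands("BB")) {
  stopifnot(is.numeric(f), length(f) >= 1)
  idx <- vapply(f, function(fi) {
    hit <- which(bands$f_lo <= fi & fi <= bands$f_hi)
    if (length(hit) == 0L) {
      stop("frequency ", fi, " Hz falls in no ", bands$context[1L],
           " band", call. = FALSE)
    }
    if (length(hit) > 1L) {
      stop("frequency ", fi, " Hz falls in more than one band",
           call. = FALSE)
    }
    hit
  }, integer(1))
  bands$name[idx]
}

band_levels <- c("delta", "theta", "alpha", "beta", "gamma")
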