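#' Per-strand 5'-end count track
#'
#' A `fp_track` stores, for one sequencing library, the number of read 5'
#' ends observed at every genome position, separately for the plus and the
#' minus strand. Coordinates are 0-based: the count for genome position `p`
#' lives at vector index `p + 1`. Counts may be non-integer after
#' normalization (e.g. counts per million) or for noise-free expected
#' tracks produced by the simulators.
#'
#' @param plus,minus Numeric vectors of identical length, per-position
#'   5'-end counts on each strand.
#' @param library Optional library identifier (sample name).
#' @return An object of class `fp_track`.
#' @export
fp_track <- function(plus, minus, library = NA_character_) {
  if (length(plus) != length(minus)) {
    stop2("plus and minus strand vectors must have the same length")
  }
  if (any(plus < 0) || any(minus < 0)) stop2("track counts must be non-negative")
  structure(
    list(plus = as.numeric(plus), minus = as.numeric(minus),
         genome_length = length(plus), library = library),
    class = "fp_track"
  )
}

#' @export
print.fp_track <- function(x, ...) {
  cat(sprintf("<fp_track> library=%s genome_length=%d total=%.1f (plus %.1f / minus %.1f)\n",
              x$library, x$genome_length, track_total(x), sum(x$plus), sum(x$minus)))
  invisible(x)
}

#' Total 5'-end count of a track
#'
#' @param track An [fp_track()].
#' @return The realized library size (sum of all per-position counts).
#' @export
track_total <- function(track) {
  stopifnot(inherits(track, "fp_track"))
  sum(track$plus) + sum(track$minus)
}

#' Shift a Ribo-Seq 5'-end track to ribosome A-site positions
#'
#' Ribosome-protected fragments are recorded by their 5' ends; the A-site
#' of the translating ribosome sits a fixed distance downstream. On the
#' plus strand a 5' end at position `p` maps to A-site `p + offset`; on the
#' minus strand (where 3' is toward smaller coordinates) to `p - offset`.
#' Counts shifted past the contig ends are dropped and reported via the
#' `"dropped"` attribute.
#'
#' @param track An [fp_track()] of RPF 5'-end counts.
#' @param offset Non-negative integer shift in nt (default 17).
#' @return An `fp_track` of A-site counts with attribute `"dropped"`.
#' @export
asite_track <- function(track, offset = 17L) {
  stopifnot(inherits(track, "fp_track"))
  offset <- as.integer(offset)
  if (is.na(offset) || offset < 0) stop2("offset must be a non-negative integer")
  L <- track$genome_length
  plus <- numeric(L)
  minus <- numeric(L)
  dropped <- 0
  if (offset == 0) {
    plus <- track$plus
    minus <- track$minus
  } else {
    keep <- seq_len(L - offset)
    plus[keep + offset] <- track$plus[keep]
    minus[keep] <- track$minus[keep + offset]
    dropped <- sum(track$plus[(L - offset + 1):L]) + sum(track$minus[seq_len(offset)])
  }
  out <- fp_track(plus, minus, library = track$library)
  attr(out, "dropped") <- dropped
  out
}

# Sum of counts over the half-open interval [start, end) on one strand.
track_window_sum <- function(track, start, end, strand) {
  if (start < 0 || end > track$genome_length) stop2("window outside track bounds")
  if (end <= start) return(0)
  v <- if (strand == "+") track$plus else track$minus
  sum(v[(start + 1):end])
}

# Add `count` read 5' ends at 0-based positions `pos` (vector) on `strand`,
# wrapping circularly. Used by the simulators.
track_add <- function(vec, pos, L) {
  pos <- pos %% L
  tab <- tabulate(pos + 1L, nbins = L)
  vec + tab
}
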