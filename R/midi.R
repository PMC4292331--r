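# Minimal Standard MIDI File support: enough of the format (header and
# track chunks, variable-length deltas, note-on/off, one tempo meta) to
# exchange keystroke streams with sequencer software. Timing uses 500
# ticks per quarter at 500000 us per quarter, so one tick is exactly one
# millisecond. This is deliberately not a general SMF implementation;
# delimited keystroke tables are the primary interchange format.

.vlq_encode <- function(x) {
  x <- as.integer(x)
  bytes <- x %% 128L
  x <- x %/% 128L
  while (x > 0L) {
    bytes <- c((x %% 128L) + 128L, bytes)
    x <- x %/% 128L
  }
  as.raw(bytes)
}

.u32 <- function(x) as.raw(c(x %/% 16777216, x %/% 65536, x %/% 256, x) %% 256)
.u16 <- function(x) as.raw(c(x %/% 256, x) %% 256)

#' Write a performance as a Standard MIDI File
#'
#' Emits a format-0 file with one track: a tempo meta event followed by
#' note-on/note-off pairs (100 ms nominal note length). The right hand
#' goes to channel 0, the left hand to channel 1; velocities are
#' preserved.
#'
#' @param performance A `performance`.
#' @param path Destination `.mid` file.
#' @return `path`, invisibly.
#' @export
write_midi <- function(performance, path) {
  stopifnot(inherits(performance, "performance"))
  ks <- performance$keystrokes
  chan <- ifelse(ks$hand == "R", 0L, 1L)
  ev <- rbind(
    data.frame(tick = round(ks$onset_ms), kind = 0x90, chan = chan,
               pitch = ks$pitch, vel = round(ks$velocity)),
    data.frame(tick = round(ks$onset_ms) + 100L, kind = 0x80, chan = chan,
               pitch = ks$pitch, vel = 0L)
  )
  ev <- ev[order(ev$tick, ev$kind), ]
  body <- c(
    .vlq_encode(0L), as.raw(c(0xFF, 0x51, 0x03)), .u32(500000L)[2:4],
    unlist(lapply(seq_len(nrow(ev)), function(k) {
      delta <- ev$tick[k] - if (k == 1L) 0L else ev$tick[k - 1L]
      c(.vlq_encode(delta),
        as.raw(bitwOr(ev$kind[k], ev$chan[k])),
        as.raw(ev$pitch[k]), as.raw(ev$vel[k]))
    })),
    .vlq_encode(0L), as.raw(c(0xFF, 0x2F, 0x00))   # end of track
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("MThd"), .u32(6L), .u16(0L), .u16(1L), .u16(500L),
             charToRaw("MTrk"), .u32(length(body)), body), con)
  invisible(path)
}

#' Read keystrokes from a Standard MIDI File
#'
#' Parses format 0 or 1 files; note-on events with nonzero velocity
#' become keystrokes (a note-on with velocity 0 is a note-off, per the
#' MIDI standard, and is ignored). Channel 0 maps to the right hand and
#' all other channels to the left; tick times are converted to
#' milliseconds with the file's division and first tempo meta event
#' (default 500000 us per quarter).
#'
#' @param path A `.mid` file.
#' @param meta Trial metadata passed to [new_performance()].
#' @return A `performance`.
#' @export
read_midi <- function(path, meta = list()) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 14 || rawToChar(raw[1:4]) != "MThd") {
    stop("parse error in ", path, ": not a Standard MIDI File (no MThd)",
         call. = FALSE)
  }
  int_at <- function(i, n) sum(as.integer(raw[i:(i + n - 1L)]) *
                                 256^((n - 1L):0))
  division <- int_at(13L, 2L)
  if (division >= 32768L) {
    stop("SMPTE time division is not supported", call. = FALSE)
  }
  n_tracks <- int_at(11L, 2L)
  pos <- 15L
  tempo_us <- 500000
  rows <- list()
  for (trk in seq_len(n_tracks)) {
    if (rawToChar(raw[pos:(pos + 3L)]) != "MTrk") {
      stop("parse error at byte ", pos, ": expected MTrk chunk", call. = FALSE)
    }
    len <- int_at(pos + 4L, 4L)
    p <- pos + 8L
    end <- p + len
    tick <- 0
    status <- 0L
    while (p < end) {
      delta <- 0
      repeat {
        b <- as.integer(raw[p]); p <- p + 1L
        delta <- delta * 128 + (b %% 128L)
        if (b < 128L) break
      }
      tick <- tick + delta
      b <- as.integer(raw[p])
      if (b >= 128L) { status <- b; p <- p + 1L }
      hi <- status %/% 16L
      if (status == 255L) {                      # meta event
        type <- as.integer(raw[p]); p <- p + 1L
        mlen <- 0
        repeat {
          bb <- as.integer(raw[p]); p <- p + 1L
          mlen <- mlen * 128 + (bb %% 128L)
          if (bb < 128L) break
        }
        if (type == 0x51 && mlen == 3L) {
          tempo_us <- sum(as.integer(raw[p:(p + 2L)]) * 256^(2:0))
        }
        p <- p + mlen
      } else if (status %in% 240:247) {          # sysex
        slen <- 0
        repeat {
          bb <- as.integer(raw[p]); p <- p + 1L
          slen <- slen * 128 + (bb %% 128L)
          if (bb < 128L) break
        }
        p <- p + slen
      } else if (hi %in% c(12L, 13L)) {          # 1-byte data
        p <- p + 1L
      } else {                                   # 2-byte data
        d1 <- as.integer(raw[p]); d2 <- as.integer(raw[p + 1L])
        p <- p + 2L
        if (hi == 9L && d2 > 0L) {
          rows[[length(rows) + 1L]] <-
            c(tick = tick, pitch = d1, vel = d2, chan = status %% 16L)
        }
      }
    }
    pos <- end
  }
  if (!length(rows)) stop("no note events in ", path, call. = FALSE)
  m <- do.call(rbind, rows)
  ms_per_tick <- tempo_us / division / 1000
  ks <- data.frame(
    onset_ms = m[, "tick"] * ms_per_tick,
    pitch = as.integer(m[, "pitch"]),
    velocity = as.numeric(m[, "vel"]),
    hand = ifelse(m[, "chan"] == 0L, "R", "L")
  )
  do.call(new_performance, c(list(keystrokes = ks), meta))
}
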