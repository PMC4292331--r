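#' Nominal tempo table
#'
#' Prescribed sixteenth-note interonset intervals: fast 187.5 ms
#' (80 quarter-note beats per minute), medium 225 ms (67 bpm), and the
#' slow learning-phase tempo 429 ms (35 bpm).
#'
#' @return Named numeric vector of IOIs in milliseconds.
#' @export
tempo_table <- function() {
  c(fast = 187.5, medium = 225, slow = 429)
}

#' Convert a sixteenth-note IOI to quarter-note beats per minute
#'
#' @param ioi_ms Sixteenth-note interonset interval in milliseconds.
#' @return Beats per minute at the quarter-note level.
#' @examples
#' ioi_to_bpm(187.5)  # 80
#' @export
ioi_to_bpm <- function(ioi_ms) 60000 / (4 * ioi_ms)

#' Convert quarter-note beats per minute to a sixteenth-note IOI
#'
#' @param bpm Beats per minute at the quarter-note level.
#' @return IOI in milliseconds.
#' @export
bpm_to_ioi <- function(bpm) 60000 / (4 * bpm)

#' Enumerate the test-phase trial roster
#'
#' Builds the within-subject design: each participant performs 8 stimuli
#' (4 excerpts in long context, 4 in short, counterbalanced across
#' participants), half at the medium tempo and half fast (also
#' counterbalanced), twice per block over 4 test blocks -- 4 excerpts x
#' 2 tempi x 4 blocks x 2 repetitions = 64 performances per participant.
#' Within a block the pieces are grouped by context; which context comes
#' first follows a Latin-square rotation over blocks and participants,
#' medium and fast tempi alternate from trial to trial, and the starting
#' tempo is counterbalanced across participants.
#'
#' @param n_participants Number of participants (default 26).
#' @return A tibble with one row per performance: `participant`, `block`,
#'   `trial_in_block`, `rep`, `trial_index`, `stimulus_id`, `context`,
#'   `tempo`, `ioi_ms`.
#' @export
generate_design <- function(n_participants = 26L) {
  stopifnot(n_participants >= 1)
  tempi <- tempo_table()
  rows <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    long_ids <- if (p %% 2L == 1L) 1:4 else 5:8
    short_ids <- setdiff(1:8, long_ids)
    # tempo of each piece: 2 medium + 2 fast per context group, which
    # pieces get which tempo flips over participant pairs
    assign_tempo <- function(ids) {
      lab <- rep(c("medium", "fast"), 2L)
      if ((p %% 4L) %in% c(2L, 3L)) lab <- rev(lab)
      stats::setNames(lab, ids)
    }
    piece_tempo <- c(assign_tempo(long_ids), assign_tempo(short_ids))
    first_tempo <- if (p %% 2L == 1L) "medium" else "fast"
    blocks <- lapply(1:4, function(b) {
      long_first <- ((p + b) %% 2L) == 0L
      groups <- if (long_first) list(long_ids, short_ids)
                else list(short_ids, long_ids)
      ids <- unlist(lapply(groups, function(g) {
        first <- g[piece_tempo[as.character(g)] == first_tempo]
        second <- g[piece_tempo[as.character(g)] != first_tempo]
        c(rbind(first, second))        # interleave -> tempi alternate
      }))
      data.frame(
        participant = p, block = b,
        trial_in_block = rep(seq_along(ids), each = 2L),
        rep = rep(1:2, times = length(ids)),
        stimulus_id = rep(as.integer(ids), each = 2L),
        context = rep(ifelse(ids %in% long_ids, "long", "short"), each = 2L),
        tempo = rep(unname(piece_tempo[as.character(ids)]), each = 2L)
      )
    })
    rows[[p]] <- do.call(rbind, blocks)
  }
  out <- do.call(rbind, rows)
  out$ioi_ms <- unname(tempi[out$tempo])
  out$trial_index <- stats::ave(seq_len(nrow(out)), out$participant,
                                FUN = seq_along)
  tibble::as_tibble(out)
}
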