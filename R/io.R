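#' Write a score to a delimited text file
#'
#' Scores serialize to a tab-separated table with `#`-prefixed header
#' lines carrying the metadata (key, context, meter), so a written score
#' reads back losslessly.
#'
#' @param score A `score`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_score <- function(score, path) {
  stopifnot(inherits(score, "score"))
  hdr <- c(
    "# rangeplan score v1",
    paste0("# key: ", score$key$tonic, " ", score$key$mode),
    paste0("# context: ", score$context),
    paste0("# stimulus_id: ", score$stimulus_id),
    paste0("# meter_cycle: ", score$grid$cycle_length),
    paste0("# n_levels: ", score$grid$n_levels),
    paste0("# tactus_level: ", score$grid$tactus_level),
    paste0("# grid_offset: ", score$grid$offset)
  )
  ev <- score$events[, c("position", "hand", "pitch", "onset_units",
                         "finger", "in_excerpt", "is_final")]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(ev, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_header <- function(path, magic) {
  lines <- readLines(path, n = 50)
  if (!length(lines) || !startsWith(lines[1], magic)) {
    stop("parse error in ", path, ": expected header '", magic,
         "' on line 1", call. = FALSE)
  }
  hdr <- grep("^# [a-z_]+: ", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^# ([a-z_]+): (.*)$", hdr))
  stats::setNames(lapply(kv, `[[`, 3), vapply(kv, `[[`, character(1), 2))
}

#' Read a score written by [write_score()]
#'
#' @param path Source file.
#' @return A `score`.
#' @export
read_score <- function(path) {
  meta <- .read_header(path, "# rangeplan score")
  key_parts <- strsplit(meta$key, " ")[[1]]
  ev <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE)
  for (col in c("position", "pitch", "onset_units", "finger")) {
    ev[[col]] <- as.integer(ev[[col]])
  }
  new_score(ev, key_spec(key_parts[1], key_parts[2]),
            context = meta$context,
            stimulus_id = as.integer(meta$stimulus_id),
            meter_cycle = as.integer(meta$meter_cycle),
            n_levels = as.integer(meta$n_levels),
            tactus_level = as.integer(meta$tactus_level),
            grid_offset = as.integer(meta$grid_offset))
}

#' Write a performance keystroke table
#'
#' @param performance A `performance`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_performance <- function(performance, path) {
  stopifnot(inherits(performance, "performance"))
  m <- performance$meta
  hdr <- c("# rangeplan performance v1",
           vapply(names(m), function(k) paste0("# ", k, ": ", m[[k]]),
                  character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(performance$keystrokes, con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a performance keystroke table
#'
#' @param path Source file.
#' @return A `performance`.
#' @export
read_performance <- function(path) {
  meta <- .read_header(path, "# rangeplan performance")
  ks <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE)
  new_performance(ks,
                  participant = as.integer(meta$participant),
                  stimulus_id = as.integer(meta$stimulus_id),
                  context = meta$context, tempo = meta$tempo,
                  ioi_ms = as.numeric(meta$ioi_ms),
                  block = as.integer(meta$block),
                  rep = as.integer(meta$rep),
                  trial_index = as.integer(meta$trial_index))
}

#' Default run configuration
#'
#' All pipeline settings with their defaults: tempo table, source
#' window, chord window, model bounds, and the toggles for every
#' documented coding decision. Serializes to YAML and round-trips
#' losslessly.
#'
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    n_participants = 26L,
    window = 8L,
    chord_window_ms = 94,
    tempo_ms = as.list(tempo_table()),
    a_bounds = c(0.801, 1.0),
    w2_bounds = c(0.25, 0.99),
    t_bounds = c(0.101, 2.0),
    grid_step = 1e-3,
    tie_prefer_anticipatory = TRUE,
    chance_multiset = TRUE,
    chance_filter_exclusions = FALSE,
    include_deletions_in_rates = TRUE,
    exclude_clipped_positions = FALSE,
    n_chance_sims = 1000L,
    p_error_chance = 0.10
  ), class = "run_config")
}

#' Write a run configuration as YAML
#'
#' @param config A `run_config` list.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a run configuration
#'
#' @param path YAML file written by [write_run_config()].
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

#' Write error records or summary tables
#'
#' Thin wrappers with a stable column contract: tab-separated, header
#' row, no quoting.
#'
#' @param x A data frame.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
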