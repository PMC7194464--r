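# Plain-text key = value pipeline configuration. Defaults match the
# protocol's printed parameters where printed (min_len 18, mincov 15,
# foldsize 340, one mapping mismatch, 21-nt period).

#' Default pipeline configuration
#'
#' @return named list of scalar parameters.
#' @export
default_config <- function() {
  list(
    adapter      = ADAPTER_SEQ,
    min_len      = 18L,
    mincov       = 15,
    foldsize     = 340L,
    max_mismatch = 1L,
    period       = 21L,
    n_cycles     = 8L,
    penalty_max  = 7,
    category_max = 4L,
    score_min    = 4,
    p_mono_U     = 0.93,
    depth        = 1,
    noise_reads  = 200L,
    seed         = 42L
  )
}

#' Read a key = value configuration file
#'
#' Lines are `key = value`; blank lines and `#` comments are ignored.
#' Values parseable as numbers are numeric; everything else stays a
#' string. Unknown keys are kept. The result round-trips unchanged
#' through [write_config()].
#'
#' @param path config file path.
#' @return named list merged over [default_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file '%s' not found", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- default_config()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop(sprintf("malformed config line: '%s'", ln), call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num else val
  }
  validate_config(cfg)
}

#' Write a configuration as key = value lines
#'
#' @param cfg named list.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_config <- function(cfg, path) {
  writeLines(sprintf("%s = %s", names(cfg),
                     vapply(cfg, function(v) format(v, scientific = FALSE),
                            character(1))),
             path)
  invisible(path)
}

validate_config <- function(cfg) {
  num_keys <- c("min_len", "mincov", "foldsize", "max_mismatch", "period",
                "n_cycles", "penalty_max", "category_max", "score_min",
                "p_mono_U", "depth", "noise_reads", "seed")
  for (k in num_keys) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L) {
      stop(sprintf("config error: '%s' must be a single number", k),
           call. = FALSE)
    }
  }
  if (cfg$p_mono_U < 0 || cfg$p_mono_U > 1) {
    stop("config error: p_mono_U must lie in [0, 1]", call. = FALSE)
  }
  assert_dna(cfg$adapter, "adapter")
  cfg
}
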