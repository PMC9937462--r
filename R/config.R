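#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line; `#` comments and blank lines ignored.
#' Values that parse as numbers are returned numeric, `true`/`false` as
#' logical, everything else as character. Recognized keys (all optional):
#' gains and delays (`alpha_ff`, `alpha_fb_aud`, `alpha_fb_som`,
#' `lambda_learn`, `lambda_reg`, `tau_aud`, `tau_som`), audio settings
#' (`sample_rate`, `jitter_sigma`, `noise_floor`, `format`, `bandwidth1..3`),
#' `forward_fit_path`, `seed`, `deterministic`.
#'
#' @param path configuration file path.
#' @return named list of parsed values.
#' @export
read_config <- function(path) {
  raw <- sub("#.*$", "", readLines(path, warn = FALSE))
  raw <- raw[grepl("=", raw, fixed = TRUE)]
  out <- list()
  for (line in raw) {
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <-
      if (!is.na(num)) num
      else if (tolower(val) %in% c("true", "false")) tolower(val) == "true"
      else val
  }
  out
}

#' Build a run configuration from parsed config values
#'
#' Applies the recognized keys of [read_config()] on top of the package
#' defaults; unrecognized keys are ignored. Explicit arguments (e.g. a seed
#' from a command-line flag) override file values.
#'
#' @param conf named list from [read_config()] (or an empty list).
#' @param seed optional seed override.
#' @param deterministic optional deterministic-mode override.
#' @return a [run_config()].
#' @export
config_to_run <- function(conf = list(), seed = NULL, deterministic = NULL) {
  pick <- function(key, default) if (!is.null(conf[[key]])) conf[[key]] else default
  g <- control_gains(
    alpha_ff = pick("alpha_ff", 1.0),
    alpha_fb_aud = pick("alpha_fb_aud", 1.0),
    alpha_fb_som = pick("alpha_fb_som", 0.5),
    lambda_learn = pick("lambda_learn", 1.0),
    lambda_reg = pick("lambda_reg", 1e-4),
    tau_aud = pick("tau_aud", 100), tau_som = pick("tau_som", 50))
  a <- audio_config(
    sample_rate = pick("sample_rate", 11025),
    bandwidths = c(pick("bandwidth1", 80), pick("bandwidth2", 100),
                   pick("bandwidth3", 120)),
    jitter_sigma = pick("jitter_sigma", 0.01),
    noise_floor = pick("noise_floor", 0.02),
    format = pick("format", "pcm16"))
  fit <- if (!is.null(conf$forward_fit_path))
    read_forward_fit(conf$forward_fit_path) else default_forward_fit()
  run_config(gains = g, audio = a, fit = fit,
             deterministic = if (!is.null(deterministic)) deterministic
                             else isTRUE(pick("deterministic", FALSE)),
             seed = if (!is.null(seed)) seed else pick("seed", 1L))
}
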