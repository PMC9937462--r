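#' Create a speech target segment
#'
#' A segment holds the target region over one time span: elementwise
#' \[min, max\] bounds on the four auditory dimensions (F0-F3, Hz) and the
#' eight somatosensory dimensions (six place-of-articulation coordinates,
#' pressure, voicing; all unitless in \[0, 1\]). Sensory error is zero while
#' the produced value lies inside the bounds.
#'
#' @param t_start,t_end segment span in ms; `t_end > t_start`.
#' @param aud_min,aud_max length-4 numeric bounds (Hz), `aud_min <= aud_max`.
#' @param som_min,som_max length-8 numeric bounds in \[0, 1\].
#' @return an object of class `target_segment`.
#' @export
target_segment <- function(t_start, t_end,
                           aud_min = rep(.AUD_FULL[1], 4),
                           aud_max = rep(.AUD_FULL[2], 4),
                           som_min = rep(.SOM_FULL[1], 8),
                           som_max = rep(.SOM_FULL[2], 8)) {
  seg <- structure(
    list(t_start = as.numeric(t_start), t_end = as.numeric(t_end),
         aud_min = as.numeric(aud_min), aud_max = as.numeric(aud_max),
         som_min = as.numeric(som_min), som_max = as.numeric(som_max)),
    class = "target_segment")
  validate_segment(seg)
  seg
}

validate_segment <- function(seg) {
  if (!is.finite(seg$t_start) || !is.finite(seg$t_end) ||
      seg$t_end <= seg$t_start)
    stop("target segment requires t_end > t_start", call. = FALSE)
  if (length(seg$aud_min) != 4 || length(seg$aud_max) != 4)
    stop("auditory bounds must have length 4 (F0-F3)", call. = FALSE)
  if (length(seg$som_min) != 8 || length(seg$som_max) != 8)
    stop("somatosensory bounds must have length 8", call. = FALSE)
  if (any(seg$aud_min > seg$aud_max) || any(seg$som_min > seg$som_max))
    stop("target bounds violated: min > max on some dimension", call. = FALSE)
  if (any(seg$aud_min < 0))
    stop("auditory bounds must be >= 0 Hz", call. = FALSE)
  if (any(seg$som_min < 0) || any(seg$som_max > 1))
    stop("somatosensory bounds must lie in [0, 1]", call. = FALSE)
  invisible(seg)
}

#' Create a speech target
#'
#' A speech target is an ordered, non-overlapping list of
#' [target_segment()]s, defining what the expected acoustic and somatosensory
#' state of the model is across the time course of a production. Gaps between
#' segments are filled by interpolation (see [target_trajectory()]).
#'
#' @param name target label.
#' @param segments list of [target_segment()], sorted, non-overlapping.
#' @param control_dt control step in ms (default 5).
#' @param interp gap interpolation mode, `"linear"` (default) or `"hold"`.
#' @return an object of class `speech_target`.
#' @export
speech_target <- function(name, segments, control_dt = 5,
                          interp = c("linear", "hold")) {
  interp <- match.arg(interp)
  tg <- structure(
    list(name = as.character(name), segments = segments,
         control_dt = as.numeric(control_dt), interp = interp),
    class = "speech_target")
  validate_target(tg)
  tg
}

validate_target <- function(tg) {
  if (length(tg$segments) == 0)
    stop("speech target must contain at least one segment (duration 0 ",
         "violates the duration > 0 invariant)", call. = FALSE)
  lapply(tg$segments, validate_segment)
  starts <- vapply(tg$segments, `[[`, numeric(1), "t_start")
  ends <- vapply(tg$segments, `[[`, numeric(1), "t_end")
  if (is.unsorted(starts, strictly = TRUE) && length(starts) > 1)
    stop("segments must be sorted by t_start", call. = FALSE)
  if (length(starts) > 1 && any(starts[-1] < ends[-length(ends)]))
    stop("segments overlap", call. = FALSE)
  if (tg$control_dt <= 0) stop("control_dt must be positive", call. = FALSE)
  invisible(tg)
}

#' Target duration in ms
#'
#' Total duration is the end time of the last segment.
#'
#' @param target a [speech_target()].
#' @return duration in ms.
#' @export
target_duration <- function(target) {
  target$segments[[length(target$segments)]]$t_end
}

.seg_bounds <- function(seg) {
  list(aud_min = seg$aud_min, aud_max = seg$aud_max,
       som_min = seg$som_min, som_max = seg$som_max)
}

#' Target region bounds at a time point
#'
#' Inside a segment the segment's bounds are returned unchanged ("hold").
#' In a gap between two segments, `"linear"` interpolation returns the linear
#' blend of the flanking segments' bounds (continuous across the whole
#' production), while `"hold"` returns the preceding segment's bounds. Times
#' before the first segment's start take the first segment's bounds.
#'
#' @param target a [speech_target()].
#' @param t time in ms, `0 <= t <= target_duration(target)`.
#' @return list with `aud_min`, `aud_max` (length 4) and `som_min`, `som_max`
#'   (length 8).
#' @export
target_trajectory <- function(target, t) {
  dur <- target_duration(target)
  if (!is.finite(t) || t < 0 || t > dur)
    stop(sprintf("time %g ms outside production range [0, %g]", t, dur),
         call. = FALSE)
  segs <- target$segments
  for (i in seq_along(segs)) {
    if (t >= segs[[i]]$t_start && t <= segs[[i]]$t_end)
      return(.seg_bounds(segs[[i]]))
  }
  if (t < segs[[1]]$t_start) return(.seg_bounds(segs[[1]]))
  # t lies in a gap: find flanking segments
  prev_i <- max(which(vapply(segs, `[[`, numeric(1), "t_end") < t))
  prev <- segs[[prev_i]]; nxt <- segs[[prev_i + 1]]
  if (target$interp == "hold") return(.seg_bounds(prev))
  w <- (t - prev$t_end) / (nxt$t_start - prev$t_end)
  blend <- function(field) (1 - w) * prev[[field]] + w * nxt[[field]]
  list(aud_min = blend("aud_min"), aud_max = blend("aud_max"),
       som_min = blend("som_min"), som_max = blend("som_max"))
}

# ---------------------------------------------------------------------------
# Plain-text target file dialect
#
#   name <label>
#   control_dt_ms <float>
#   interp hold|linear
#   segment <t_start_ms> <t_end_ms>
#     aud F0|F1|F2|F3 <min> <max>        (Hz)
#     som <k in 0..7> <min> <max>        (unitless)
#
# '#' starts a comment; tokens are whitespace-separated; dimensions not
# listed in a segment default to the full (unconstrained) range.
# ---------------------------------------------------------------------------

#' Parse a target file
#'
#' Reads the plain-text target dialect (see Details) into a
#' [speech_target()]. Malformed lines raise an error naming the line number;
#' bound or ordering violations raise validation errors.
#'
#' @details File layout: a `name <label>` line, a `control_dt_ms <float>`
#'   line, an `interp hold|linear` line, then one or more blocks starting
#'   with `segment <t_start_ms> <t_end_ms>` followed by
#'   `aud F0|F1|F2|F3 <min> <max>` and `som <k:0..7> <min> <max>` lines.
#'   `#` comments and blank lines are ignored. Unlisted dimensions default to
#'   the full configured range (unconstrained).
#'
#' @param text target file content: a single string or a character vector of
#'   lines.
#' @return a [speech_target()].
#' @seealso [write_target()], [read_target_file()]
#' @export
parse_target <- function(text) {
  if (length(text) == 1 && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  raw <- sub("#.*$", "", text)
  keep <- which(nzchar(trimws(raw)))
  toks <- lapply(raw[keep], function(l) strsplit(trimws(l), "\\s+")[[1]])
  lineno <- keep

  perr <- function(i, msg)
    stop(sprintf("target parse error at line %d: %s", lineno[i], msg),
         call. = FALSE)
  num <- function(i, s) {
    v <- suppressWarnings(as.numeric(s))
    if (any(is.na(v))) perr(i, sprintf("expected a number, got '%s'",
                                       paste(s, collapse = " ")))
    v
  }
  if (length(toks) < 3) stop("target file too short", call. = FALSE)
  if (toks[[1]][1] != "name" || length(toks[[1]]) != 2)
    perr(1, "expected 'name <label>'")
  if (toks[[2]][1] != "control_dt_ms" || length(toks[[2]]) != 2)
    perr(2, "expected 'control_dt_ms <float>'")
  if (toks[[3]][1] != "interp" || !toks[[3]][2] %in% c("hold", "linear"))
    perr(3, "expected 'interp hold|linear'")
  name <- toks[[1]][2]
  dt <- num(2, toks[[2]][2])
  interp <- toks[[3]][2]

  segs <- list()
  cur <- NULL
  flush_seg <- function(cur) {
    do.call(target_segment, cur)
  }
  i <- 4
  while (i <= length(toks)) {
    tk <- toks[[i]]
    if (tk[1] == "segment") {
      if (length(tk) != 3) perr(i, "expected 'segment <t_start> <t_end>'")
      if (!is.null(cur)) segs[[length(segs) + 1]] <- flush_seg(cur)
      cur <- list(t_start = num(i, tk[2]), t_end = num(i, tk[3]),
                  aud_min = rep(.AUD_FULL[1], 4),
                  aud_max = rep(.AUD_FULL[2], 4),
                  som_min = rep(.SOM_FULL[1], 8),
                  som_max = rep(.SOM_FULL[2], 8))
    } else if (tk[1] == "aud") {
      if (is.null(cur)) perr(i, "'aud' line before any 'segment'")
      if (length(tk) != 4) perr(i, "expected 'aud F0|F1|F2|F3 <min> <max>'")
      k <- match(tk[2], c("F0", "F1", "F2", "F3"))
      if (is.na(k)) perr(i, sprintf("unknown auditory dim '%s'", tk[2]))
      lo <- num(i, tk[3]); hi <- num(i, tk[4])
      if (lo > hi) perr(i, sprintf("aud %s min %g > max %g", tk[2], lo, hi))
      cur$aud_min[k] <- lo; cur$aud_max[k] <- hi
    } else if (tk[1] == "som") {
      if (is.null(cur)) perr(i, "'som' line before any 'segment'")
      if (length(tk) != 4) perr(i, "expected 'som <k:0..7> <min> <max>'")
      k <- suppressWarnings(as.integer(tk[2]))
      if (is.na(k) || k < 0 || k > 7) perr(i, "som index must be in 0..7")
      lo <- num(i, tk[3]); hi <- num(i, tk[4])
      if (lo > hi) perr(i, sprintf("som %d min %g > max %g", k, lo, hi))
      cur$som_min[k + 1] <- lo; cur$som_max[k + 1] <- hi
    } else {
      perr(i, sprintf("unknown directive '%s'", tk[1]))
    }
    i <- i + 1
  }
  if (!is.null(cur)) segs[[length(segs) + 1]] <- flush_seg(cur)
  speech_target(name, segs, control_dt = dt, interp = interp)
}

#' Serialize a speech target to the target-file dialect
#'
#' All dimensions are written explicitly (including unconstrained ones) at 17
#' significant digits, so `parse_target(write_target(t))` reproduces `t`
#' field-exactly.
#'
#' @param target a [speech_target()].
#' @return a single string (target-file content).
#' @export
write_target <- function(target) {
  validate_target(target)
  out <- c(paste("name", target$name),
           paste("control_dt_ms", fmt_num(target$control_dt)),
           paste("interp", target$interp))
  aud_names <- c("F0", "F1", "F2", "F3")
  for (seg in target$segments) {
    out <- c(out, sprintf("segment %s %s",
                          fmt_num(seg$t_start), fmt_num(seg$t_end)))
    for (k in 1:4)
      out <- c(out, sprintf("aud %s %s %s", aud_names[k],
                            fmt_num(seg$aud_min[k]), fmt_num(seg$aud_max[k])))
    for (k in 1:8)
      out <- c(out, sprintf("som %d %s %s", k - 1L,
                            fmt_num(seg$som_min[k]), fmt_num(seg$som_max[k])))
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Read / write target files on disk
#'
#' Thin file wrappers around [parse_target()] and [write_target()].
#'
#' @param path file path.
#' @param target a [speech_target()].
#' @return `read_target_file` returns a [speech_target()];
#'   `write_target_file` invisibly returns `path`.
#' @export
read_target_file <- function(path) {
  parse_target(readLines(path, warn = FALSE))
}

#' @rdname read_target_file
#' @export
write_target_file <- function(target, path) {
  writeLines(sub("\n$", "", write_target(target)), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Built-in and generated ("reachable fixture") targets
# ---------------------------------------------------------------------------

#' Build a target guaranteed reachable under the forward fit
#'
#' Constructs a single-segment target whose bounds enclose, with a relative
#' margin, the sensory image of a given articulatory configuration under the
#' forward fit. Because the bounds contain a point of the forward map's image,
#' the region is attainable by the controller; such targets are the package's
#' test and demonstration fixtures.
#'
#' @param name target label.
#' @param shape length-10 vocal-tract shape vector in \[-1, 1\].
#' @param f0_ctrl fundamental-frequency control in \[0, 1\].
#' @param duration_ms segment duration (default 1200 ms, a sustained vowel).
#' @param margin relative half-width of the formant bounds (default 0.06).
#' @param f0_margin relative half-width of the F0 bounds (default 0.08).
#' @param fit a [forward_fit()]; default [default_forward_fit()].
#' @param control_dt control step in ms.
#' @return a [speech_target()] with pressure and voicing constrained to
#'   \[0.55, 1\] and place dimensions unconstrained.
#' @export
make_reachable_target <- function(name, shape, f0_ctrl = 0.5,
                                  duration_ms = 1200, margin = 0.06,
                                  f0_margin = 0.08,
                                  fit = default_forward_fit(),
                                  control_dt = 5) {
  seg <- reachable_segment(0, duration_ms, shape, f0_ctrl, margin, f0_margin,
                           fit)
  speech_target(name, list(seg), control_dt = control_dt, interp = "linear")
}

# Segment whose auditory bounds bracket the forward-fit image of `shape`.
reachable_segment <- function(t_start, t_end, shape, f0_ctrl, margin,
                              f0_margin, fit) {
  x <- c(shape, f0_ctrl, 0.8, 0.9)
  fr <- synth_sample(x, fit)
  rel <- c(f0_margin, rep(margin, 3))
  target_segment(t_start, t_end,
                 aud_min = fr$aud * (1 - rel),
                 aud_max = fr$aud * (1 + rel),
                 som_min = c(rep(0, 6), 0.55, 0.55),
                 som_max = rep(1, 8))
}

# Prototype articulatory configurations behind the shipped targets. These are
# stand-in fixtures (stylized vowel postures under the default forward fit),
# not measurements.
.BUILTIN_SHAPES <- list(
  i       = list(shape = c(-0.8, 0.7, 0.9, 0.6, 0.3, 0.1, 0, 0, 0, 0),
                 f0 = 0.45),
  u       = list(shape = c(-0.5, -0.6, -0.8, -0.3, 0.4, -0.2, 0, 0, 0, 0),
                 f0 = 0.40),
  e       = list(shape = c(-0.2, 0.4, 0.5, 0.3, 0.1, 0, 0, 0, 0, 0),
                 f0 = 0.50),
  ae      = list(shape = c(0.9, 0.5, -0.3, 0.2, -0.4, 0.1, 0, 0, 0, 0),
                 f0 = 0.55),
  example = list(shape = c(0.3, -0.2, 0.4, -0.5, 0.6, 0.2, 0, 0, 0, 0),
                 f0 = 0.50))

#' Built-in speech targets
#'
#' Returns the six shipped targets: the sustained vowels `i`, `u`, `e`, `ae`,
#' the multi-segment word `happy`, and the single-segment `example`. The
#' vowels and `example` are 1200 ms single-segment regions; `happy` has three
#' segments with linearly interpolated gaps. `example` ships with no
#' pretrained motor program (see [builtin_program()]). Bounds are generated
#' from fixed prototype articulatory configurations under the forward fit, so
#' every built-in is reachable by the controller.
#'
#' @param fit a [forward_fit()]; default [default_forward_fit()].
#' @return named list of [speech_target()]s.
#' @export
builtin_targets <- function(fit = default_forward_fit()) {
  vowels <- lapply(names(.BUILTIN_SHAPES), function(nm) {
    p <- .BUILTIN_SHAPES[[nm]]
    make_reachable_target(nm, p$shape, p$f0, fit = fit)
  })
  names(vowels) <- names(.BUILTIN_SHAPES)
  # 'happy': open vowel, transition gap, closing vowel
  ae <- .BUILTIN_SHAPES$ae; ii <- .BUILTIN_SHAPES$i
  happy <- speech_target("happy", list(
    reachable_segment(0, 350, ae$shape, ae$f0, 0.08, 0.10, fit),
    reachable_segment(500, 700, 0.5 * (ae$shape + ii$shape),
                      0.5 * (ae$f0 + ii$f0), 0.10, 0.12, fit),
    reachable_segment(850, 1200, ii$shape, ii$f0, 0.08, 0.10, fit)),
    control_dt = 5, interp = "linear")
  c(vowels[c("i", "u", "e", "ae")], list(happy = happy),
    vowels["example"])
}

#' @rdname builtin_targets
#' @param name one of `"i"`, `"u"`, `"e"`, `"ae"`, `"happy"`, `"example"`.
#' @export
builtin_target <- function(name, fit = default_forward_fit()) {
  tg <- builtin_targets(fit)
  if (!name %in% names(tg))
    stop(sprintf("unknown built-in target '%s' (available: %s)", name,
                 paste(names(tg), collapse = ", ")), call. = FALSE)
  tg[[name]]
}
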