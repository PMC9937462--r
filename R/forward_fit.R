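#' Static forward fit of the vocal tract
#'
#' The forward fit is a smooth static map from the articulatory state to the
#' sensory outputs. Formants F1-F3 and the place coordinates are squashed
#' affine functions of the 10 shape parameters,
#' `lo + (hi - lo) * sigmoid(w . shape + b)`, which keeps every output inside
#' its declared range for any state; F0, pressure and voicing pass through
#' from their dedicated source controls. This preserves the modelling
#' contract of a statically defined, differentiable vocal-tract fit whose
#' Jacobian drives the pseudoinverse feedback map.
#'
#' @param aud_weights 4 x 10 coefficient matrix (row 1, F0, is ignored by the
#'   map since F0 comes from the `f0_ctrl` source control).
#' @param aud_bias length-4 bias vector.
#' @param aud_lo,aud_hi length-4 output ranges in Hz, ordered so that the F0
#'   range lies below the F1 range, F1 below F2, and F2 below F3.
#' @param som_weights 6 x 10 coefficient matrix for the place dimensions.
#' @param som_bias length-6 bias vector.
#' @return an object of class `forward_fit`.
#' @export
forward_fit <- function(aud_weights, aud_bias, aud_lo, aud_hi,
                        som_weights, som_bias) {
  fit <- structure(
    list(aud_weights = as.matrix(aud_weights), aud_bias = as.numeric(aud_bias),
         aud_lo = as.numeric(aud_lo), aud_hi = as.numeric(aud_hi),
         som_weights = as.matrix(som_weights), som_bias = as.numeric(som_bias),
         n_shape = ncol(aud_weights), n_place = nrow(som_weights)),
    class = "forward_fit")
  validate_fit(fit)
  fit
}

validate_fit <- function(fit) {
  if (nrow(fit$aud_weights) != 4 || length(fit$aud_bias) != 4 ||
      length(fit$aud_lo) != 4 || length(fit$aud_hi) != 4)
    stop("forward fit: auditory block must have 4 rows (F0-F3)",
         call. = FALSE)
  if (ncol(fit$som_weights) != fit$n_shape ||
      length(fit$som_bias) != fit$n_place)
    stop("forward fit: somatosensory block dimensions inconsistent",
         call. = FALSE)
  if (any(fit$aud_lo >= fit$aud_hi))
    stop("forward fit requires aud_lo < aud_hi elementwise", call. = FALSE)
  if (any(diff(fit$aud_lo) <= 0) || any(diff(fit$aud_hi) <= 0) ||
      any(fit$aud_hi[-4] >= fit$aud_lo[-1]))
    stop("forward fit ranges must be physiologically ordered ",
         "(F0 below F1 below F2 below F3)", call. = FALSE)
  invisible(fit)
}

#' Default forward fit
#'
#' Fixed coefficients chosen so that each formant responds to a distinct
#' small set of shape parameters (giving a well-conditioned Jacobian) and the
#' neutral posture (`shape = 0`, zero biases) sits at each range midpoint.
#' The output ranges are F0 75-240 Hz, F1 250-900 Hz, F2 950-2800 Hz, F3
#' 2850-4200 Hz.
#'
#' @return a [forward_fit()].
#' @export
default_forward_fit <- function() {
  aw <- rbind(
    rep(0, 10),                                              # F0: pass-through
    c(1.2, 0.8, -0.4, 0.0, 0.3, 0.0, 0, 0, 0, 0),            # F1
    c(-0.3, 0.5, 1.3, 0.7, 0.0, -0.2, 0, 0, 0, 0),           # F2
    c(0.0, -0.2, 0.4, 1.1, 0.9, 0.3, 0, 0, 0, 0))            # F3
  sw <- matrix(0, 6, 10)
  for (i in 1:6) {
    sw[i, i] <- 1.0
    sw[i, i + 4] <- 0.4
  }
  forward_fit(aud_weights = aw, aud_bias = rep(0, 4),
              aud_lo = c(75, 250, 950, 2850), aud_hi = c(240, 900, 2800, 4200),
              som_weights = sw, som_bias = rep(0, 6))
}

#' Read / write forward-fit coefficient files
#'
#' Plain-text row-major matrix format with `#` comments: a `ranges` block
#' (`aud_lo`, `aud_hi` lines), an `aud_bias` line, a `som_bias` line, then
#' one `aud_w` line per auditory row and one `som_w` line per place row.
#' Values are written at 17 significant digits (exact round trip).
#'
#' @param fit a [forward_fit()].
#' @param path file path (set via config key `forward_fit_path`).
#' @return `read_forward_fit` returns a [forward_fit()];
#'   `write_forward_fit` invisibly returns `path`.
#' @export
write_forward_fit <- function(fit, path) {
  row <- function(tag, v) paste(tag, paste(fmt_num(v), collapse = " "))
  lines <- c("# vocal-tract forward fit coefficients",
             row("aud_lo", fit$aud_lo), row("aud_hi", fit$aud_hi),
             row("aud_bias", fit$aud_bias), row("som_bias", fit$som_bias),
             vapply(1:4, function(i) row("aud_w", fit$aud_weights[i, ]), ""),
             vapply(seq_len(fit$n_place),
                    function(i) row("som_w", fit$som_weights[i, ]), ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_forward_fit
#' @export
read_forward_fit <- function(path) {
  raw <- sub("#.*$", "", readLines(path, warn = FALSE))
  raw <- raw[nzchar(trimws(raw))]
  toks <- lapply(raw, function(l) strsplit(trimws(l), "\\s+")[[1]])
  tags <- vapply(toks, `[[`, "", 1)
  vals <- lapply(toks, function(tk) as.numeric(tk[-1]))
  pick1 <- function(tag) vals[[which(tags == tag)[1]]]
  pickm <- function(tag) do.call(rbind, vals[tags == tag])
  forward_fit(aud_weights = pickm("aud_w"), aud_bias = pick1("aud_bias"),
              aud_lo = pick1("aud_lo"), aud_hi = pick1("aud_hi"),
              som_weights = pickm("som_w"), som_bias = pick1("som_bias"))
}
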