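#' Drop the burn-in prefix of a signal
#'
#' The Kalman iteration needs time to converge, so a fraction of the filtered
#' signal's prefix is removed before frequency-domain filtering:
#' `floor(cut * length)` leading frames are dropped, the rest is unchanged.
#'
#' @param signal An [angle_signal()].
#' @param cut Fraction in \[0, 1).
#' @return The trimmed [angle_signal()].
#' @export
apply_cut <- function(signal, cut) {
  assert_angle_signal(signal)
  if (!is.numeric(cut) || length(cut) != 1L || cut < 0 || cut >= 1) {
    rlang::abort("`cut` must lie in [0, 1)", class = "posegait_validation_error")
  }
  n <- nrow(signal)
  drop <- floor(cut * n)
  if (n - drop < 2L) {
    rlang::abort("signal too short after cut (< 2 frames)",
                 class = "posegait_validation_error")
  }
  rewrap_signal(tibble::as_tibble(signal)[(drop + 1L):n, ], signal)
}

#' Least-RMSE selection of DFT components
#'
#' Selects the `N` nonnegative-frequency DFT components (DC eligible; each
#' conjugate pair counts as one component) whose retention reconstructs the
#' series with the lowest RMSE. By Parseval's theorem that is exactly the `N`
#' components of largest combined magnitude (a pair's two bins counted
#' together); ties are broken deterministically toward the lower frequency
#' index.
#'
#' @param theta Finite numeric series.
#' @param N Number of components to keep (>= 1). If `N` exceeds the number of
#'   distinct components, all are returned with a warning.
#' @param fs Sampling rate in Hz, stored for frequency conversion.
#' @return Object of class `spectrum_selection` with fields `m` (series
#'   length), `selected` (0-based nonnegative frequency indices),
#'   `coefficients` (their complex DFT values), `energy` (combined squared
#'   magnitudes) and `fs`.
#' @export
lrmse_select <- function(theta, N, fs = 30) {
  if (anyNA(theta) || !all(is.finite(theta))) {
    rlang::abort("series must be finite with no missing values",
                 class = "posegait_validation_error")
  }
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N)) {
    rlang::abort("`N` must be a positive integer", class = "posegait_validation_error")
  }
  m <- length(theta)
  X <- stats::fft(theta)
  kmax <- floor(m / 2)
  k <- 0:kmax
  # combined energy of component k: own bin plus its conjugate bin when distinct
  paired <- k > 0 & !(m %% 2 == 0 & k == kmax)
  energy <- Mod(X[k + 1])^2 * ifelse(paired, 2, 1)
  if (N > length(k)) {
    rlang::warn(sprintf("N = %d exceeds the %d available components; keeping all",
                        N, length(k)))
    N <- length(k)
  }
  ord <- order(-energy, k)
  sel <- sort(k[ord[seq_len(N)]])
  structure(list(m = m,
                 selected = sel,
                 coefficients = X[sel + 1],
                 energy = energy[match(sel, k)],
                 fs = fs),
            class = "spectrum_selection")
}

#' Reconstruct the time-domain signal of a spectrum selection
#'
#' Inverse DFT of only the selected components, with conjugate bins restored
#' so the reconstruction is real; the residual imaginary part (below 1e-9
#' relative) is discarded.
#'
#' @param selection A `spectrum_selection` from [lrmse_select()].
#' @return Real numeric vector of length `selection$m`.
#' @export
reconstruct_selection <- function(selection) {
  m <- selection$m
  X <- complex(m)
  X[selection$selected + 1] <- selection$coefficients
  mirror <- selection$selected[selection$selected > 0 &
                                 selection$selected != m - selection$selected]
  X[m - mirror + 1] <- Conj(selection$coefficients[match(mirror, selection$selected)])
  rec <- stats::fft(X, inverse = TRUE) / m
  Re(rec)
}

#' Frequency-domain filter (DFT component selection)
#'
#' Applies the burn-in cut, selects the `n_components` least-RMSE DFT
#' components of the remaining series and reconstructs it from those
#' components alone. The input must already be gap-free (i.e. Kalman
#' filtered). The selection is attached as attribute `"selection"` for
#' downstream frequency readout.
#'
#' @param signal An [angle_signal()] with no missing samples.
#' @param config A [gait_config()] supplying `cut` and `n_components`.
#' @return The filtered [angle_signal()] (length = input length after cut).
#' @export
fdf_filter <- function(signal, config = gait_config()) {
  assert_angle_signal(signal)
  if (anyNA(signal$theta)) {
    rlang::abort("signal has missing samples; Kalman-filter it first",
                 class = "posegait_validation_error")
  }
  cutsig <- apply_cut(signal, config$cut)
  sel <- lrmse_select(cutsig$theta, config$n_components, fs = signal_fps(signal))
  rec <- reconstruct_selection(sel)
  out <- tibble::as_tibble(cutsig)
  out$theta <- rec
  rewrap_signal(out, cutsig, selection = sel)
}

#' Dominant frequency of a spectrum selection
#'
#' Frequency (in Hz, `index * fs / m`) of the largest-magnitude non-DC
#' component in the selection; ties go to the lower frequency.
#'
#' @param selection A `spectrum_selection`.
#' @return Frequency in Hz.
#' @export
dominant_frequency <- function(selection) {
  nondc <- selection$selected > 0
  k <- selection$selected[nondc]
  e <- selection$energy[nondc]
  # non-DC bins admitted purely by tie-breaking carry no periodicity either
  if (!any(nondc) || max(e) <= 1e-12 * sum(selection$energy)) {
    rlang::abort("selection carries no non-DC energy; no periodicity",
                 class = "posegait_noperiod_error")
  }
  best <- k[order(-e, k)][1]
  best * selection$fs / selection$m
}

#' @export
print.spectrum_selection <- function(x, ...) {
  cat(sprintf("<spectrum_selection> m=%d fs=%g selected k: %s\n",
              x$m, x$fs, paste(x$selected, collapse = ", ")))
  invisible(x)
}
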