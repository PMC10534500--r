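#' Preprocessing configuration
#'
#' Defaults follow the standard chemometric recipe for this formulation:
#' Savitzky-Golay with a 15-point window and 2nd-order polynomial, Whittaker
#' baseline with lambda = 10,000 and asymmetry p = 0.001, and total-area
#' normalization for Raman spectra; NIR spectra get only the SG first
#' derivative.
#'
#' @param sg_window odd SG window length (points).
#' @param sg_polyorder SG polynomial order, `< sg_window`.
#' @param deriv_order 0 (smoothing) or 1 (first derivative).
#' @param whittaker_lambda smoothness penalty of the baseline.
#' @param whittaker_p asymmetry weight in (0, 1).
#' @param normalization `"area"`, `"vector"` or `"none"`.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(sg_window = 15, sg_polyorder = 2,
                              deriv_order = 0, whittaker_lambda = 10000,
                              whittaker_p = 0.001, normalization = "area") {
  normalization <- match.arg(normalization, c("area", "vector", "none"))
  if (sg_window %% 2 != 1 || sg_window <= sg_polyorder) {
    stop("sg_window must be odd and greater than sg_polyorder", call. = FALSE)
  }
  if (!deriv_order %in% c(0, 1)) stop("deriv_order must be 0 or 1",
                                      call. = FALSE)
  if (whittaker_lambda <= 0) stop("whittaker_lambda must be positive",
                                  call. = FALSE)
  if (whittaker_p <= 0 || whittaker_p >= 1) {
    stop("whittaker_p must lie in (0, 1)", call. = FALSE)
  }
  structure(list(sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 deriv_order = as.integer(deriv_order),
                 whittaker_lambda = whittaker_lambda,
                 whittaker_p = whittaker_p,
                 normalization = normalization),
            class = "preprocess_config")
}

# n x n Savitzky-Golay operator matrix. Interior rows carry the usual
# symmetric convolution kernel; rows near the ends fit the same-order
# polynomial on the window truncated to available points (no padding, so no
# fabricated intensity at the spectrum ends).
sg_operator <- function(n, window, polyorder, deriv = 0) {
  if (window %% 2 != 1) stop("SG window must be odd", call. = FALSE)
  if (window > n) stop("SG window exceeds spectrum length", call. = FALSE)
  if (polyorder >= window) stop("SG polyorder must be < window",
                                call. = FALSE)
  if (!deriv %in% c(0, 1)) stop("deriv must be 0 or 1", call. = FALSE)
  h <- (window - 1L) %/% 2L
  kernel_for <- function(x, ord, d) {
    V <- outer(x, 0:ord, `^`)
    A <- solve(crossprod(V), t(V)) # (ord+1) x npts
    A[d + 1L, ] * factorial(d)
  }
  C <- matrix(0, n, n)
  interior <- kernel_for((-h):h, polyorder, deriv)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    if (lo == i - h && hi == i + h) {
      C[i, lo:hi] <- interior
    } else {
      npts <- hi - lo + 1L
      ord <- min(polyorder, npts - 1L)
      if (deriv > ord) stop("window too short for derivative at the edge",
                            call. = FALSE)
      C[i, lo:hi] <- kernel_for((lo:hi) - i, ord, deriv)
    }
  }
  C
}

#' Savitzky-Golay smoothing / differentiation
#'
#' Local least-squares polynomial filter. `deriv = 1` returns the first
#' derivative per band index (no division by physical band spacing; CLS is
#' invariant to the scale as long as the pure library receives the same
#' treatment). Edges use a shrink-window polynomial fit instead of padding.
#'
#' @param spectrum numeric intensity series (or a matrix with spectra in
#'   rows).
#' @param window odd window length, at most the series length.
#' @param polyorder polynomial order.
#' @param deriv 0 or 1.
#' @return filtered series (same shape as the input).
#' @export
savitzky_golay <- function(spectrum, window = 15, polyorder = 2, deriv = 0) {
  if (is.matrix(spectrum)) {
    C <- sg_operator(ncol(spectrum), window, polyorder, deriv)
    return(spectrum %*% t(C))
  }
  C <- sg_operator(length(spectrum), window, polyorder, deriv)
  as.numeric(C %*% spectrum)
}

#' Whittaker baseline by asymmetric least squares
#'
#' Eilers-style AsLS: a penalized least-squares smoother with a
#' second-difference penalty `lambda`, iteratively reweighted with weight `p`
#' for points above the current baseline and `1 - p` below, so the smooth
#' curve hugs the lower envelope of the spectrum. The corrected spectrum is
#' `spectrum - baseline`.
#'
#' @param spectrum numeric intensity series of length >= 10.
#' @param lambda smoothness penalty (default 10,000).
#' @param p asymmetry weight in (0, 1) (default 0.001).
#' @param max_iter maximum reweighting iterations.
#' @param tol convergence tolerance on the weight change.
#' @return the estimated baseline, with attributes `iterations` and
#'   `converged`. A warning is raised (and the last iterate returned) if the
#'   weights have not settled within `max_iter`.
#' @export
whittaker_baseline <- function(spectrum, lambda = 10000, p = 0.001,
                               max_iter = 50, tol = 1e-6) {
  stopifnot(is.numeric(spectrum))
  if (length(spectrum) < 10) {
    stop("spectrum too short for baseline estimation (need >= 10 points)",
         call. = FALSE)
  }
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)", call. = FALSE)
  if (lambda <= 0) stop("lambda must be positive", call. = FALSE)
  res <- asls_baseline_cpp(as.numeric(spectrum), lambda, p,
                           as.integer(max_iter), tol)
  if (!res$converged) {
    warning("Whittaker baseline did not converge within ", max_iter,
            " iterations; returning last iterate", call. = FALSE)
  }
  structure(res$baseline, iterations = res$iterations,
            converged = res$converged)
}

# Matrix version used on cubes: spectra in rows.
whittaker_baseline_rows <- function(spectra, lambda, p, max_iter = 50,
                                    tol = 1e-6) {
  res <- asls_baseline_matrix_cpp(t(spectra), lambda, p,
                                  as.integer(max_iter), tol)
  if (!all(res$converged)) {
    warning(sum(!res$converged),
            " spectra: Whittaker baseline not converged; last iterate used",
            call. = FALSE)
  }
  t(res$baseline)
}

#' Normalize a spectrum
#'
#' `"area"` divides by the total absolute intensity `sum(|x|)` (the common
#' Raman chemometrics choice; preserves CLS linearity up to a per-pixel
#' scale); `"vector"` divides by the Euclidean norm.
#'
#' @param spectrum numeric intensity series.
#' @param mode `"area"` or `"vector"`.
#' @param tol degeneracy threshold on the norm: below it the spectrum is
#'   considered all-zero (e.g. a flat spectrum after baseline removal, where
#'   only solver noise at the 1e-11 level remains).
#' @return normalized series with unit area / unit norm.
#' @export
normalize_spectrum <- function(spectrum, mode = c("area", "vector"),
                               tol = 1e-8) {
  mode <- match.arg(mode)
  nrm <- switch(mode, area = sum(abs(spectrum)),
                vector = sqrt(sum(spectrum^2)))
  if (!is.finite(nrm) || nrm < tol) {
    stop("degenerate-input: cannot normalize an (almost) all-zero spectrum",
         call. = FALSE)
  }
  spectrum / nrm
}

# Coerce cube / matrix / vector to a (spectra x bands) matrix plus a restorer.
as_spectra_matrix <- function(x) {
  if (inherits(x, "hyper_cube")) {
    d <- dim(x$values)
    list(mat = matrix(x$values, d[1] * d[2], d[3]),
         restore = function(m) {
           out <- x
           out$values <- array(m, d)
           out
         })
  } else if (inherits(x, "pure_library")) {
    list(mat = x$spectra,
         restore = function(m) {
           out <- x
           out$spectra <- m
           out
         })
  } else if (is.matrix(x)) {
    list(mat = x, restore = identity)
  } else {
    list(mat = matrix(x, 1), restore = function(m) as.numeric(m[1, ]))
  }
}

#' Raman preprocessing recipe
#'
#' Smoothing (Savitzky-Golay), baseline correction (asymmetric Whittaker) and
#' total-area normalization, applied per spectrum, in that order. The pure
#' component library must be treated identically for CLS to be consistent.
#'
#' @param spectra a `hyper_cube`, `pure_library`, matrix (spectra in rows) or
#'   numeric vector.
#' @param cfg a [preprocess_config()] with `deriv_order = 0`.
#' @return object of the same shape, preprocessed.
#' @export
preprocess_raman <- function(spectra, cfg = preprocess_config()) {
  stopifnot(inherits(cfg, "preprocess_config"))
  if (cfg$deriv_order != 0) {
    stop("the Raman recipe smooths (deriv_order must be 0)", call. = FALSE)
  }
  sm <- as_spectra_matrix(spectra)
  m <- savitzky_golay(sm$mat, cfg$sg_window, cfg$sg_polyorder, deriv = 0)
  base <- whittaker_baseline_rows(m, cfg$whittaker_lambda, cfg$whittaker_p)
  m <- m - base
  if (cfg$normalization != "none") {
    m <- t(apply(m, 1, normalize_spectrum, mode = cfg$normalization))
  }
  sm$restore(m)
}

#' NIR preprocessing recipe
#'
#' Savitzky-Golay first derivative per spectrum; no baseline correction and
#' no normalization. A linear operator, so additive offsets vanish and
#' mixtures of spectra map to mixtures of derivatives.
#'
#' @param spectra a `hyper_cube`, `pure_library`, matrix (spectra in rows) or
#'   numeric vector.
#' @param cfg a [preprocess_config()] with `deriv_order = 1`.
#' @return object of the same shape, differentiated.
#' @export
preprocess_nir <- function(spectra,
                           cfg = preprocess_config(deriv_order = 1,
                                                   normalization = "none")) {
  stopifnot(inherits(cfg, "preprocess_config"))
  if (cfg$deriv_order != 1) {
    stop("the NIR recipe is a first derivative (deriv_order must be 1)",
         call. = FALSE)
  }
  sm <- as_spectra_matrix(spectra)
  m <- savitzky_golay(sm$mat, cfg$sg_window, cfg$sg_polyorder, deriv = 1)
  sm$restore(m)
}

#' Apply the modality-appropriate preprocessing recipe
#'
#' @param spectra cube, library, matrix or vector.
#' @param modality `"raman"` or `"nir"`.
#' @param cfg optional [preprocess_config()]; if omitted, the modality
#'   default is used.
#' @return preprocessed object.
#' @export
preprocess_modality <- function(spectra, modality, cfg = NULL) {
  modality <- match.arg(modality, c("raman", "nir"))
  if (modality == "raman") {
    preprocess_raman(spectra, cfg %||% preprocess_config())
  } else {
    preprocess_nir(spectra, cfg %||% preprocess_config(deriv_order = 1,
                                                       normalization = "none"))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
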