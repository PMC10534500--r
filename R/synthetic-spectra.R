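#' Generate a synthetic pure-component spectral library
#'
#' Builds Gaussian-peak spectra for the five tablet components on a shared
#' band axis. Raman-like spectra carry several narrow, well-separated peaks;
#' NIR-like spectra have fewer, much broader, strongly overlapping bands
#' (width ratio configurable). Because distinguishing the matrix polymer
#' HPMC from the cellulose binder MCC is the crux of the unmixing problem,
#' the generator imposes a target Pearson correlation between the two by
#' blending the MCC spectrum toward (or away from) the HPMC spectrum until
#' the correlation is within 0.05 of `similarity_target`.
#'
#' All spectra are scaled to equal total area (equal spectral response), so
#' CLS abundances of area-normalized spectra correspond directly to w/w
#' fractions.
#'
#' @param modality `"raman"` or `"nir"`.
#' @param n_bands number of spectral bands (>= 50).
#' @param similarity_target HPMC-MCC Pearson correlation in `[0, 1)`.
#' @param seed integer seed; the library is deterministic given
#'   `(modality, n_bands, similarity_target, seed)`.
#' @param width_ratio NIR / Raman median peak-width ratio (default 6).
#' @return a `pure_library`: list with `spectra` (5 x n_bands matrix, rows
#'   named by component), `band_axis`, `modality`, `peaks` metadata.
#' @export
generate_pure_spectra <- function(modality, n_bands = 300,
                                  similarity_target = NULL, seed = 1,
                                  width_ratio = 6) {
  modality <- match.arg(modality, c("raman", "nir"))
  if (n_bands < 50) {
    stop("invalid-configuration: n_bands must be at least 50", call. = FALSE)
  }
  if (is.null(similarity_target)) {
    similarity_target <- if (modality == "raman") 0.6 else 0.92
  }
  if (similarity_target < 0 || similarity_target >= 1) {
    stop("invalid-configuration: similarity_target must lie in [0, 1)",
         call. = FALSE)
  }
  set.seed(seed)
  comps <- component_names()
  axis <- seq_len(n_bands)
  # Median peak width in band units; Raman narrow, NIR broad.
  base_width <- if (modality == "raman") n_bands / 90 else
    n_bands * width_ratio / 90
  n_peak_range <- if (modality == "raman") 4:7 else 3:5
  min_gap <- if (modality == "raman") max(4, n_bands * 0.05) else
    max(4, n_bands * 0.08)
  if (3 * base_width > n_bands / 2) {
    stop("invalid-configuration: n_bands too small for the configured peak widths",
         call. = FALSE)
  }

  draw_component <- function() {
    n_pk <- sample(n_peak_range, 1)
    centers <- numeric(0)
    tries <- 0
    while (length(centers) < n_pk && tries < 2000) {
      cand <- runif(1, 0.08 * n_bands, 0.92 * n_bands)
      if (all(abs(cand - centers) >= min_gap)) centers <- c(centers, cand)
      tries <- tries + 1
    }
    widths <- base_width * exp(rnorm(length(centers), 0, 0.25))
    amps <- runif(length(centers), 0.8, 1.5)
    s <- rep(0, n_bands)
    for (j in seq_along(centers)) {
      s <- s + amps[j] * exp(-0.5 * ((axis - centers[j]) / widths[j])^2)
    }
    list(spectrum = s,
         peaks = data.frame(center = centers, width = widths,
                            amplitude = amps))
  }

  drawn <- lapply(comps, function(nm) draw_component())
  names(drawn) <- comps
  S <- do.call(rbind, lapply(drawn, `[[`, "spectrum"))
  rownames(S) <- comps

  # Impose the HPMC-MCC similarity by blending MCC with HPMC (to raise the
  # correlation) or with its HPMC-orthogonal residual (to lower it), clipped
  # at zero to keep intensities nonnegative.
  hp <- S["HPMC", ]
  mc <- S["MCC", ]
  blend_cor <- function(theta, target_up) {
    if (target_up) {
      cand <- (1 - theta) * mc + theta * hp
    } else {
      resid <- mc - hp * sum(mc * hp) / sum(hp * hp)
      cand <- pmax((1 - theta) * mc + theta * resid, 0)
    }
    cand
  }
  base_cor <- cor(hp, mc)
  target_up <- base_cor <= similarity_target
  fobj <- function(theta) cor(hp, blend_cor(theta, target_up)) -
    similarity_target
  if (abs(base_cor - similarity_target) > 1e-6) {
    f1 <- fobj(1)
    if (sign(fobj(0)) == sign(f1)) {
      # Lowering can bottom out above the target for extreme cases.
      theta <- 1
    } else {
      theta <- uniroot(fobj, c(0, 1), tol = 1e-9)$root
    }
    S["MCC", ] <- blend_cor(theta, target_up)
  }

  # Equal total area per component (equal spectral response assumption).
  S <- S / rowSums(S) * n_bands
  structure(list(spectra = S, band_axis = axis, modality = modality,
                 similarity_target = similarity_target,
                 peaks = lapply(drawn, `[[`, "peaks"), seed = seed),
            class = "pure_library")
}

#' @export
print.pure_library <- function(x, ...) {
  cat(sprintf("<pure_library> %s, %d components x %d bands, HPMC-MCC cor %.3f\n",
              x$modality, nrow(x$spectra), ncol(x$spectra),
              cor(x$spectra["HPMC", ], x$spectra["MCC", ])))
  invisible(x)
}

# Count local maxima above half the global maximum of a spectrum.
count_peaks <- function(s, rel_height = 0.5) {
  n <- length(s)
  thr <- rel_height * max(s)
  idx <- which(s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n]) + 1L
  sum(s[idx] > thr)
}
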