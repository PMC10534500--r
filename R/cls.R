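#' Fit a classical least squares unmixing operator
#'
#' CLS models every pixel spectrum as a linear combination of the (already
#' preprocessed) pure-component spectra; the unmixing operator is the
#' Moore-Penrose pseudo-inverse of the library, `(S S')^{-1} S`, applied to a
#' spectrum to yield K abundances. The operator's condition number is
#' reported as a collinearity diagnostic (HPMC vs MCC similarity is what
#' inflates it).
#'
#' @param library a `pure_library` (preprocessed) or a K x B numeric matrix
#'   with component spectra in rows.
#' @param condition_warn warn if the condition number exceeds this
#'   (default 1e6).
#' @return a `cls_operator`: `matrix` (K x B), `component_names`,
#'   `condition_number`.
#' @export
fit_cls <- function(library, condition_warn = 1e6) {
  S <- if (inherits(library, "pure_library")) library$spectra else library
  stopifnot(is.matrix(S), nrow(S) >= 2, ncol(S) >= nrow(S))
  sv <- svd(S)
  rank_tol <- max(sv$d) * max(dim(S)) * .Machine$double.eps * 1e4
  if (min(sv$d) < rank_tol) {
    stop("unmixing-infeasible: pure component library is rank deficient",
         call. = FALSE)
  }
  cond <- max(sv$d) / min(sv$d)
  if (cond > condition_warn) {
    warning(sprintf("CLS library is ill-conditioned (condition number %.3g)",
                    cond), call. = FALSE)
  }
  op <- sv$v %*% (t(sv$u) / sv$d)  # B x K; pseudo-inverse transpose
  structure(list(matrix = t(op),
                 component_names = rownames(S) %||% paste0("C", seq_len(nrow(S))),
                 condition_number = cond),
            class = "cls_operator")
}

#' @export
print.cls_operator <- function(x, ...) {
  cat(sprintf("<cls_operator> %d components x %d bands, condition number %.3g\n",
              nrow(x$matrix), ncol(x$matrix), x$condition_number))
  invisible(x)
}

#' Unmix a single spectrum
#'
#' Unconstrained least squares followed by clamping negative abundances to
#' zero; no sum-to-one closure is imposed (the systematic CLS bias is
#' handled, for reporting, by [mean_shift_correction()]).
#'
#' @param op a [fit_cls()] operator.
#' @param spectrum numeric series preprocessed identically to the library.
#' @return named K-vector of abundances.
#' @export
unmix_pixel <- function(op, spectrum) {
  stopifnot(inherits(op, "cls_operator"))
  if (length(spectrum) != ncol(op$matrix)) {
    stop("spectrum length does not match the unmixing operator",
         call. = FALSE)
  }
  a <- as.numeric(op$matrix %*% spectrum)
  names(a) <- op$component_names
  pmax(a, 0)
}

#' Concentration map of one component
#'
#' Unmixes every pixel of a preprocessed cube and scales the chosen
#' component's abundance to w/w % (factor 100 under the equal-response
#' assumption of the synthetic libraries).
#'
#' @param op a [fit_cls()] operator.
#' @param cube a preprocessed `hyper_cube`.
#' @param component component label (default `"HPMC"`).
#' @return a `conc_map`: `values` H x W matrix in w/w %, `component`,
#'   `pixel_pitch`.
#' @export
concentration_map <- function(op, cube, component = "HPMC") {
  stopifnot(inherits(op, "cls_operator"), inherits(cube, "hyper_cube"))
  k <- match(component, op$component_names)
  if (is.na(k)) stop("unknown component: ", component, call. = FALSE)
  d <- dim(cube$values)
  if (d[3] != ncol(op$matrix)) {
    stop("cube band count does not match the unmixing operator",
         call. = FALSE)
  }
  spec <- matrix(cube$values, d[1] * d[2], d[3])
  ab <- spec %*% t(op$matrix)
  ab <- pmax(ab, 0)
  structure(list(values = matrix(100 * ab[, k], d[1], d[2]),
                 component = component, pixel_pitch = cube$pixel_pitch),
            class = "conc_map")
}

#' @export
print.conc_map <- function(x, ...) {
  cat(sprintf("<conc_map> %s, %dx%d pixels, mean %.2f w/w%%\n",
              x$component, nrow(x$values), ncol(x$values),
              mean(x$values)))
  invisible(x)
}

#' Mean concentration of a map
#'
#' The scalar image feature used by the dissolution network: the arithmetic
#' mean over all pixels of the concentration map.
#'
#' @param map a [concentration_map()] result (or a numeric matrix in w/w %).
#' @return mean concentration in w/w %.
#' @export
mean_concentration <- function(map) {
  v <- if (inherits(map, "conc_map")) map$values else map
  if (length(v) == 0) stop("empty concentration map", call. = FALSE)
  mean(v)
}
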