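#' HPMC sieve fractions
#'
#' The four particle-size fractions of HPMC obtained with 45, 63, 100 and
#' 150 um sieves. The lowest fraction has no lower sieve bound and is treated
#' as (0, 45) um.
#'
#' @return character vector of the four size-fraction labels.
#' @export
hpmc_size_levels <- function() c("<45", "45-63", "63-100", "100-150")

#' Sieve-fraction diameter bounds, midpoint and regression label
#'
#' `sieve_bounds()` returns the `[lower, upper)` diameter interval in um;
#' `sieve_midpoint()` its midpoint (22.5 um for the "<45" fraction);
#' `sieve_upper()` the upper sieve pore size, which is the CNN regression
#' target (the smallest pore the particles passed through).
#'
#' @param fraction one of [hpmc_size_levels()].
#' @return numeric bounds / midpoint / upper label in um.
#' @export
sieve_bounds <- function(fraction) {
  fraction <- match.arg(fraction, hpmc_size_levels())
  switch(fraction,
    "<45" = c(0, 45),
    "45-63" = c(45, 63),
    "63-100" = c(63, 100),
    "100-150" = c(100, 150))
}

#' @rdname sieve_bounds
#' @export
sieve_midpoint <- function(fraction) mean(sieve_bounds(fraction))

#' @rdname sieve_bounds
#' @export
sieve_upper <- function(fraction) sieve_bounds(fraction)[2]

new_tablet_design <- function(name, dr_frac, hpmc_frac, mcc_frac,
                              lactose_frac, mgst_frac, size_fraction, role) {
  structure(list(
    name = name, dr_frac = dr_frac, hpmc_frac = hpmc_frac,
    mcc_frac = mcc_frac, lactose_frac = lactose_frac, mgst_frac = mgst_frac,
    size_fraction = size_fraction, role = role
  ), class = "tablet_design")
}

#' Define a tablet composition
#'
#' A five-component sustained-release formulation: drug (DR), matrix polymer
#' HPMC (the component whose level and particle size control release), binder
#' MCC, lactose filler (balance) and magnesium stearate lubricant. Fractions
#' are w/w and must sum to 1; the nominal HPMC level lies in `[0.10, 0.30]`.
#'
#' @param name formulation id.
#' @param hpmc_frac HPMC w/w fraction in `[0.10, 0.30]`.
#' @param size_fraction HPMC sieve fraction, one of [hpmc_size_levels()].
#' @param dr_frac,mcc_frac,mgst_frac w/w fractions of the other fixed
#'   components (defaults 0.08, 0.20, 0.02).
#' @param lactose_frac lactose w/w fraction; if `NULL`, set to the balance.
#' @param role `"calibration"` or `"validation"`.
#' @return a `tablet_design` object.
#' @export
tablet_design <- function(name, hpmc_frac, size_fraction,
                          dr_frac = 0.08, mcc_frac = 0.20, mgst_frac = 0.02,
                          lactose_frac = NULL, role = "calibration") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  size_fraction <- match.arg(size_fraction, hpmc_size_levels())
  role <- match.arg(role, c("calibration", "validation"))
  if (!is.numeric(hpmc_frac) || hpmc_frac < 0.10 - 1e-12 ||
      hpmc_frac > 0.30 + 1e-12) {
    stop("hpmc_frac must lie in [0.10, 0.30]", call. = FALSE)
  }
  if (is.null(lactose_frac)) {
    lactose_frac <- 1 - dr_frac - hpmc_frac - mcc_frac - mgst_frac
  }
  fr <- c(dr_frac, hpmc_frac, mcc_frac, lactose_frac, mgst_frac)
  if (any(fr < -1e-12)) stop("component fractions must be nonnegative",
                             call. = FALSE)
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("component fractions must sum to 1 (got ", format(sum(fr)), ")",
         call. = FALSE)
  }
  new_tablet_design(name, dr_frac, hpmc_frac, mcc_frac, lactose_frac,
                    mgst_frac, size_fraction, role)
}

#' @export
print.tablet_design <- function(x, ...) {
  cat(sprintf("<tablet_design> %s (%s): HPMC %.2f%% (%s um), DR %.1f%%, MCC %.1f%%, lactose %.2f%%, MgSt %.1f%%\n",
              x$name, x$role, 100 * x$hpmc_frac, x$size_fraction,
              100 * x$dr_frac, 100 * x$mcc_frac, 100 * x$lactose_frac,
              100 * x$mgst_frac))
  invisible(x)
}

design_fractions <- function(design) {
  c(DR = design$dr_frac, HPMC = design$hpmc_frac, MCC = design$mcc_frac,
    lactose = design$lactose_frac, MgSt = design$mgst_frac)
}

#' The full experimental design: 36 formulations
#'
#' 28 calibration formulations (seven HPMC levels from 10 to 30 w/w% crossed
#' with the four sieve fractions) and 8 validation formulations at
#' intermediate HPMC levels. DR is 8%, MCC 20%, MgSt 2% throughout; lactose
#' is the balance.
#'
#' @param as_data_frame return a data frame summary instead of a list of
#'   [tablet_design()] objects.
#' @return list of 36 `tablet_design` objects (or a data frame).
#' @export
experiment_designs <- function(as_data_frame = FALSE) {
  cal_conc <- c(10, 13.33, 16.66, 20, 23.33, 26.66, 30) / 100
  sizes <- hpmc_size_levels()
  designs <- list()
  k <- 1L
  for (cc in cal_conc) {
    for (sz in sizes) {
      designs[[k]] <- tablet_design(sprintf("DR%02d", k), cc, sz,
                                    role = "calibration")
      k <- k + 1L
    }
  }
  val <- list(
    c(12, 1), c(12, 3), c(15, 2), c(15, 4),
    c(25, 1), c(25, 4), c(28, 2), c(28, 3))
  for (i in seq_along(val)) {
    designs[[k]] <- tablet_design(sprintf("DRV%02d", i), val[[i]][1] / 100,
                                  sizes[val[[i]][2]], role = "validation")
    k <- k + 1L
  }
  names(designs) <- vapply(designs, `[[`, character(1), "name")
  if (as_data_frame) {
    return(data.frame(
      name = names(designs),
      hpmc_pct = vapply(designs, function(d) 100 * d$hpmc_frac, numeric(1)),
      size_fraction = vapply(designs, `[[`, character(1), "size_fraction"),
      role = vapply(designs, `[[`, character(1), "role"),
      row.names = NULL))
  }
  designs
}

# Multiplicative jitter on the HPMC fraction (tablet-to-tablet variation),
# renormalized so fractions still sum to 1. Bypasses the nominal range check.
jitter_design <- function(design, sd_rel = 0.01, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fr <- design_fractions(design)
  fr["HPMC"] <- fr["HPMC"] * exp(rnorm(1, 0, sd_rel))
  fr <- fr / sum(fr)
  new_tablet_design(design$name, fr[["DR"]], fr[["HPMC"]], fr[["MCC"]],
                    fr[["lactose"]], fr[["MgSt"]], design$size_fraction,
                    design$role)
}
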