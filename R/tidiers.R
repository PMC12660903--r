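#' Tidy methods for fitted objects
#'
#' `tidy()` returns one row per parameter with estimates and standard
#' errors; `glance()` returns a one-row model summary, following the broom
#' convention.
#'
#' @param x a fitted object (`two_step_fit`, `mm_fit`, or `superposition`).
#' @param ... unused.
#' @name rnagate-tidiers
NULL

#' @rdname rnagate-tidiers
#' @export
tidy.two_step_fit <- function(x, ...) {
  tibble(term = c("k1", "k2"),
         estimate = c(x$k1, x$k2),
         std.error = c(x$k1_se, x$k2_se),
         unit = "1/min")
}

#' @rdname rnagate-tidiers
#' @export
glance.two_step_fit <- function(x, ...) {
  tibble(sigma = x$residual_sd,
         nobs = nrow(x$data),
         df.residual = stats::df.residual(x$fit),
         p0 = x$p0,
         exchange_ambiguous = x$exchange_ambiguous,
         intermediate_peak_time = intermediate_peak_time(x$k1, x$k2))
}

#' @rdname rnagate-tidiers
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble(term = c("vmax", "km"),
         estimate = c(x$vmax, x$km),
         std.error = c(x$vmax_se, x$km_se),
         lineweaver_burk = c(x$vmax_lb, x$km_lb))
}

#' @rdname rnagate-tidiers
#' @export
glance.mm_fit <- function(x, ...) {
  res <- stats::residuals(x$fit)
  tibble(sigma = sqrt(sum(res^2) / stats::df.residual(x$fit)),
         nobs = nrow(x$data),
         df.residual = stats::df.residual(x$fit))
}

#' @rdname rnagate-tidiers
#' @export
tidy.superposition <- function(x, ...) {
  tibble(term = c("rmsd", "rmsd_all", "n_atoms_used", "n_rejected"),
         estimate = c(x$rmsd, x$rmsd_all, x$n_atoms_used, x$n_rejected))
}

#' @rdname rnagate-tidiers
#' @export
glance.superposition <- function(x, ...) {
  tibble(rmsd = x$rmsd, rmsd_all = x$rmsd_all,
         n_atoms_used = x$n_atoms_used, n_rejected = x$n_rejected,
         rotation_det = det(x$rotation))
}
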