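# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a localization result
#'
#' @param x An `lfm_localization`.
#' @param ... Unused.
#' @return A tibble with one row per detected source (`source_id`, `x_um`,
#'   `y_um`, `z_um`, `w_h`, `w_v`, `atom_h`, `atom_v`).
#' @method tidy lfm_localization
#' @export
tidy.lfm_localization <- function(x, ...) x$sources

#' @rdname tidy.lfm_localization
#' @return For `glance()`: a one-row tibble with the source count, the
#'   reliability weights, final CSC objectives and iteration counts.
#' @method glance lfm_localization
#' @export
glance.lfm_localization <- function(x, ...) {
  tibble::tibble(
    n_sources = nrow(x$sources),
    w_h = x$sources$w_h[1], w_v = x$sources$w_v[1],
    objective_h = utils::tail(x$fit_h$objective, 1),
    objective_v = utils::tail(x$fit_v$objective, 1),
    iterations_h = x$fit_h$iterations, iterations_v = x$fit_v$iterations,
    beta_h = x$fit_h$beta, beta_v = x$fit_v$beta)
}

#' Tidy a calibration result
#'
#' @param x An `lfm_calibration`.
#' @param ... Unused.
#' @return A tibble with one row per lenslet (`k`, `l`, `row_px`, `col_px`).
#' @method tidy lfm_calibration
#' @export
tidy.lfm_calibration <- function(x, ...) {
  K <- nrow(x$centers$row); L <- ncol(x$centers$row)
  tibble::tibble(
    k = rep(seq_len(K), times = L), l = rep(seq_len(L), each = K),
    row_px = as.vector(x$centers$row), col_px = as.vector(x$centers$col))
}

#' @rdname tidy.lfm_calibration
#' @method glance lfm_calibration
#' @export
glance.lfm_calibration <- function(x, ...) {
  tibble::tibble(rotation_angle_deg = x$rotation_angle, pitch_px = x$pitch,
                 n_lenslets = length(x$centers$row))
}

#' Tidy an evaluation report
#'
#' @param x An `lfm_eval`.
#' @param ... Unused.
#' @return The per-source match table (tibble).
#' @method tidy lfm_eval
#' @export
tidy.lfm_eval <- function(x, ...) x$matches

#' @rdname tidy.lfm_eval
#' @method glance lfm_eval
#' @export
glance.lfm_eval <- function(x, ...) {
  tibble::tibble(
    rmse_x_um = x$rmse[["x"]], rmse_y_um = x$rmse[["y"]], rmse_z_um = x$rmse[["z"]],
    rmse_lateral_um = x$rmse[["lateral"]], rmse_overall_um = x$rmse[["overall"]],
    depth_accuracy = x$depth_accuracy, unmatched = x$unmatched)
}

#' Tidy a CSC fit
#'
#' @param x An `lfm_csc`.
#' @param ... Unused.
#' @return A tibble with one row per atom: `atom`, `energy` (over the valid
#'   region), `peak_value`, `nonzeros`.
#' @method tidy lfm_csc
#' @export
tidy.lfm_csc <- function(x, ...) {
  M <- dim(x$maps)[1]
  tibble::tibble(
    atom = seq_len(M),
    energy = vapply(seq_len(M), function(m) sum(x$maps[m, , ][x$valid]^2), numeric(1)),
    peak_value = vapply(seq_len(M), function(m) {
      v <- matrix(x$maps[m, , ], dim(x$maps)[2], dim(x$maps)[3])
      v[!x$valid] <- 0
      v[which.max(abs(v))]
    }, numeric(1)),
    nonzeros = vapply(seq_len(M), function(m) sum(x$T[m, , ] != 0), numeric(1)))
}

#' @rdname tidy.lfm_csc
#' @method glance lfm_csc
#' @export
glance.lfm_csc <- function(x, ...) {
  tibble::tibble(
    objective = utils::tail(x$objective, 1),
    primal_residual = utils::tail(x$primal_residual, 1),
    dual_residual = utils::tail(x$dual_residual, 1),
    iterations = x$iterations, beta = x$beta, mu = x$mu)
}
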