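#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a density of states
#'
#' @param x a `helix_dos` object.
#' @param ... unused.
#' @return A tibble with one row per energy bin: `E`, `log_g`, `support`,
#'   and the entropy `S = log_g` on the support.
#' @method tidy helix_dos
#' @export
tidy.helix_dos <- function(x, ...) {
  dplyr::mutate(x$table, S = ifelse(.data$support, .data$log_g, NA_real_))
}

#' @rdname tidy.helix_dos
#' @return `glance()`: a one-row tibble with `n_bins`, `n_support`,
#'   `e_bin`, `s_tau`, `iterations`, `converged`.
#' @method glance helix_dos
#' @export
glance.helix_dos <- function(x, ...) {
  tibble::tibble(n_bins = nrow(x$table), n_support = sum(x$table$support),
                 e_bin = x$e_bin, s_tau = x$s_tau[1],
                 iterations = x$iterations, converged = x$converged)
}

#' Tidy a replica-exchange run
#'
#' @param x a `helix_run` object.
#' @param ... unused.
#' @return A long tibble of per-sweep observables: `thread`, `temperature`,
#'   `s_tau`, `sweep`, `E`, `q`.
#' @method tidy helix_run
#' @export
tidy.helix_run <- function(x, ...) {
  th <- x$threads
  dplyr::bind_rows(lapply(th$thread, function(t) {
    tibble::tibble(thread = t, temperature = th$temperature[t],
                   s_tau = th$s_tau[t],
                   sweep = seq_len(nrow(x$e_trace)),
                   E = x$e_trace[, t], q = x$q_trace[, t])
  }))
}

#' @rdname tidy.helix_run
#' @return `glance()`: one row per thread with acceptance rates by move
#'   kind, replica-exchange acceptance, and the lowest sampled energy.
#' @method glance helix_run
#' @export
glance.helix_run <- function(x, ...) {
  acc <- x$moves |>
    dplyr::group_by(.data$thread) |>
    dplyr::summarise(move_acceptance = sum(.data$accepts) /
                       max(1, sum(.data$attempts)))
  ex <- dplyr::bind_rows(
    dplyr::transmute(x$exchange, thread = .data$thread_i,
                     att = .data$attempts, acc = .data$accepts),
    dplyr::transmute(x$exchange, thread = .data$thread_j,
                     att = .data$attempts, acc = .data$accepts)) |>
    dplyr::group_by(.data$thread) |>
    dplyr::summarise(exchange_acceptance = sum(.data$acc) /
                       max(1, sum(.data$att)))
  out <- dplyr::left_join(x$threads, acc, by = "thread")
  out <- dplyr::left_join(out, ex, by = "thread")
  dplyr::left_join(out,
                   dplyr::select(x$minima, "thread", "min_energy", "min_q"),
                   by = "thread")
}
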