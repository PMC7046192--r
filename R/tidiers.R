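# broom-style tidiers for the package's fitted/result objects.

#' @importFrom broom tidy glance
#' @export
broom::tidy

#' @export
broom::glance

#' @export
tidy.paco_test <- function(x, ...) {
  tibble::tibble(statistic = x$m2, p.value = x$p, n.perm = x$n_perm,
                 n.as.low = x$n_as_low)
}

#' @export
glance.paco_test <- function(x, ...) tidy.paco_test(x)

#' @export
tidy.divergence_test <- function(x, ...) x$windows

#' @export
glance.divergence_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p,
                 n.windows = x$n_windows)
}

#' @export
tidy.pnps_counts <- function(x, ...) x$by_class

#' @export
glance.pnps_counts <- function(x, ...) x$overall

#' @export
tidy.neow_sim <- function(x, ...) x$trajectory

#' @export
glance.neow_sim <- function(x, ...) {
  last <- x$trajectory[nrow(x$trajectory), ]
  tibble::tibble(generations = x$state$gen, extinct = x$extinct,
                 fused_freq = last$fused_freq,
                 infected_freq = last$infected_freq)
}

#' @export
tidy.painted_chromosome <- function(x, ...) x$painting

#' @export
glance.painted_chromosome <- function(x, ...) {
  tidyr::pivot_wider(x$genotype[, c("hap", "call")],
                     names_from = "hap", values_from = "call",
                     names_prefix = "hap")
}
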