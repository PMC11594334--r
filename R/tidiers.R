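#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and summarise fitted objects
#'
#' broom-style accessors: `tidy()` returns the per-feature (or per-node)
#' table as a plain tibble, `glance()` a one-row summary.
#'
#' @param x A `cerna_de`, `cerna_hubs`, `cerna_network` or `cerna_run`.
#' @param ... Unused.
#' @return A tibble.
#' @name spongenet-tidiers
NULL

#' @rdname spongenet-tidiers
#' @export
tidy.cerna_de <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "cerna_de")
  out
}

#' @rdname spongenet-tidiers
#' @export
glance.cerna_de <- function(x, ...) {
  tibble(n_features = nrow(x), method = attr(x, "method"),
         dispersion = attr(x, "dispersion"),
         n_p05 = sum(x$p_value < 0.05), n_fdr05 = sum(x$fdr < 0.05))
}

#' @rdname spongenet-tidiers
#' @export
tidy.cerna_network <- function(x, ...) x$axes

#' @rdname spongenet-tidiers
#' @export
glance.cerna_network <- function(x, ...) network_stats(x)

#' @rdname spongenet-tidiers
#' @export
tidy.cerna_hubs <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "cerna_hubs")
  out
}

#' @rdname spongenet-tidiers
#' @export
glance.cerna_run <- function(x, ...) {
  dplyr::bind_cols(
    tibble(model = x$model,
           n_de_circ = nrow(x$de_circ), n_de_mrna = nrow(x$de_mrna),
           n_pairs = nrow(x$pairs)),
    x$stats,
    tibble(n_subnetwork_axes = nrow(x$subnetwork$axes),
           fisher_p = x$fisher_p, n_flags = length(x$flags)))
}
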