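# Tidiers: every result type can be flattened to a tibble (tidy) or
# summarized in one row (glance), in the style of broom.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a reaction network into its reaction table
#'
#' @param x a `crn` object.
#' @param ... unused.
#' @return tibble with columns `source`, `target`, `rate`.
#' @export
tidy.crn <- function(x, ...) reactions(x)

#' One-row summary of a reaction network
#'
#' @param x a `crn` object.
#' @param ... unused.
#' @return tibble with species, complex and reaction counts.
#' @export
glance.crn <- function(x, ...) {
  tibble::tibble(n_species = length(x$species),
                 n_complexes = length(x$complexes),
                 n_reactions = nrow(reactions(x)))
}

#' Tidy a dense realization into its per-edge table
#'
#' One row per reaction of the dense realization: the rate in the assembled
#' dense Kirchhoff matrix, the maximal rate the reaction can take over all
#' equivalent realizations, and the lower bound used in the assembly.
#'
#' @param x a `dense_realization`.
#' @param ... unused.
#' @return tibble with columns `source`, `target`, `rate`, `max_rate`,
#'   `epsilon`.
#' @export
tidy.dense_realization <- function(x, ...) {
  rx <- reactions(x$network)
  em <- dplyr::inner_join(x$edge_max, x$epsilon, by = c("source", "target"))
  dplyr::left_join(rx, em, by = c("source", "target"))
}

#' @rdname tidy.dense_realization
#' @export
glance.dense_realization <- function(x, ...) {
  tibble::tibble(n_reactions = nrow(x$support),
                 n_complexes = length(x$network$complexes),
                 n_excluded = nrow(x$exclude),
                 ubound = x$ubound, tol_zero = x$tol_zero)
}

#' Tidy a sparse realization
#'
#' @param x a `sparse_realization`.
#' @param ... unused.
#' @return tibble of the minimal realization's reactions.
#' @export
tidy.sparse_realization <- function(x, ...) reactions(x$network)

#' @rdname tidy.sparse_realization
#' @export
glance.sparse_realization <- function(x, ...) {
  tibble::tibble(cardinality = x$cardinality,
                 n_dense = nrow(x$dense$support),
                 structure_unique = x$cardinality == nrow(x$dense$support))
}

#' Tidy a core-reaction report
#'
#' @param x a `core_report`.
#' @param ... unused.
#' @return tibble of the dense realization's reactions with a logical
#'   `core` column.
#' @export
tidy.core_report <- function(x, ...) {
  dplyr::arrange(
    dplyr::bind_rows(dplyr::mutate(x$core, core = TRUE),
                     dplyr::mutate(x$non_core, core = FALSE)),
    .data$source, .data$target)
}

#' @rdname tidy.core_report
#' @export
glance.core_report <- function(x, ...) {
  tibble::tibble(n_core = nrow(x$core),
                 n_non_core = nrow(x$non_core),
                 n_dense = nrow(x$core) + nrow(x$non_core))
}

#' Tidy a structural-uniqueness test
#'
#' @param x a `uniqueness_test`.
#' @param ... unused.
#' @return tibble of dense-realization reactions flagged by whether each is
#'   also part of the minimal realization found.
#' @export
tidy.uniqueness_test <- function(x, ...) {
  keys <- paste(x$sparse_support$source, "->", x$sparse_support$target)
  dplyr::mutate(x$dense_support,
                in_sparse = paste(.data$source, "->", .data$target) %in% keys)
}

#' @rdname tidy.uniqueness_test
#' @export
glance.uniqueness_test <- function(x, ...) {
  tibble::tibble(unique = x$unique,
                 n_dense = nrow(x$dense_support),
                 cardinality = x$cardinality)
}

#' Tidy a Monte Carlo identifiability result
#'
#' @param x an `mc_result`.
#' @param ... unused.
#' @return tibble with one row per possible reachable-set size and the
#'   number of draws attaining it (the histogram content).
#' @export
tidy.mc_result <- function(x, ...) {
  tibble::tibble(reachable = as.integer(names(x$reachable_counts)),
                 count = as.integer(x$reachable_counts))
}

#' @rdname tidy.mc_result
#' @export
glance.mc_result <- function(x, ...) {
  tibble::tibble(n = x$n, k = x$k, trials = x$trials, seed = x$seed,
                 non_identifiable = x$non_identifiable,
                 fraction = x$fraction, std_error = x$std_error)
}

#' Histogram of reachable-set sizes from a Monte Carlo run
#'
#' Bars count the Monte Carlo draws by the number of nodes reachable from
#' the perturbed node; only the right-most bar (all nodes reachable)
#' corresponds to structurally identifiable models.
#'
#' @param object an `mc_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mc_result <- function(object, ...) {
  d <- tidy.mc_result(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$reachable, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_x_continuous(breaks = d$reachable) +
    ggplot2::labs(
      x = "nodes reachable from the perturbed node",
      y = "models",
      title = sprintf("n = %d, k = %d: %.2f%% non-identifiable",
                      object$n, object$k, 100 * object$fraction)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
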