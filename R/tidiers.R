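#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy methods for strategies, simulations and scenario batches
#'
#' `tidy()` returns the observation-level table (support points and
#' weights for a strategy; the round-by-species trajectory for a
#' simulation; per-replicate final counts for a scenario batch) and
#' `glance()` a one-row summary.
#'
#' @param x A `discrete_strategy`, `continuous_strategy`,
#'   `competition_sim` or `scenario_batch` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.discrete_strategy <- function(x, ...) {
  tibble::tibble(
    species = x$label,
    ability = x$support,
    weight = x$weights,
    probability = as_probabilities(x)
  )
}

#' @rdname tidiers
#' @export
glance.discrete_strategy <- function(x, ...) {
  tibble::tibble(
    species = x$label,
    n_support = length(x$support),
    abundance = total_abundance(x),
    mca = mca(x)
  )
}

#' @rdname tidiers
#' @param n Number of evaluation points for a continuous density.
#' @export
tidy.continuous_strategy <- function(x, n = 101, ...) {
  grid <- seq(0, 1, length.out = n)
  tibble::tibble(species = x$label, ability = grid, density = x$density(grid))
}

#' @rdname tidiers
#' @export
glance.continuous_strategy <- function(x, ...) {
  tibble::tibble(
    species = x$label,
    abundance = total_abundance(x),
    mca = mca(x),
    exact = !is.null(x$pieces)
  )
}

#' @rdname tidiers
#' @export
tidy.competition_sim <- function(x, ...) x$trajectory

#' @rdname tidiers
#' @export
glance.competition_sim <- function(x, ...) {
  tibble::tibble(
    n_species = length(x$final_counts),
    rounds = x$rounds,
    n_extinct = nrow(x$extinctions),
    total_count = sum(x$final_counts),
    seed = if (is.null(x$seed)) NA_integer_ else as.integer(x$seed)
  )
}

#' @rdname tidiers
#' @export
tidy.scenario_batch <- function(x, ...) x$finals

#' @rdname tidiers
#' @export
glance.scenario_batch <- function(x, ...) {
  tibble::tibble(
    name = x$name,
    seed = x$seed,
    replicates = x$replicates,
    rounds = x$rounds,
    statistic = x$criterion$statistic,
    value = x$criterion$value[1],
    pass = x$criterion$pass
  )
}

#' Plot methods
#'
#' `autoplot()` draws a strategy's ability distribution, a simulation's
#' abundance trajectories, or a scenario batch's final-abundance
#' distributions.
#'
#' @param object A strategy, `competition_sim` or `scenario_batch`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-heterogame
NULL

#' @rdname autoplot-heterogame
#' @export
autoplot.discrete_strategy <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ability, y = .data$probability)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$ability, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(
      x = "competitive ability", y = "probability",
      title = object$label,
      subtitle = sprintf("abundance %.4g, MCA %.4g",
        total_abundance(object), mca(object))
    )
}

#' @rdname autoplot-heterogame
#' @export
autoplot.continuous_strategy <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ability, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "competitive ability", y = "density", title = object$label)
}

#' @rdname autoplot-heterogame
#' @export
autoplot.competition_sim <- function(object, ...) {
  ggplot2::ggplot(
    object$trajectory,
    ggplot2::aes(x = .data$round, y = .data$count, colour = .data$species)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "round", y = "head-count", colour = "species")
}

#' @rdname autoplot-heterogame
#' @export
autoplot.scenario_batch <- function(object, ...) {
  ggplot2::ggplot(
    object$finals,
    ggplot2::aes(x = .data$species, y = .data$final_count)
  ) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(
      x = NULL, y = "final head-count",
      title = sprintf("scenario %s", object$name),
      subtitle = object$criterion$statistic
    )
}
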