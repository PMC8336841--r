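#' Communities of competing species
#'
#' A community is an ordered collection of labelled strategies that
#' compete simultaneously. Labels must be unique; duplicated labels are
#' disambiguated with a numeric suffix so payoff tables and trajectories
#' stay keyed by label.
#'
#' @param ... Strategy objects, or a single list of them.
#' @return An object of class `community`: a named list of strategies.
#' @examples
#' comm <- community(make_uniform(10, 1000), make_invariant(0.5, 1000))
#' length(comm)
#' @export
community <- function(...) {
  strategies <- rlang::list2(...)
  if (length(strategies) == 1 && is.list(strategies[[1]]) &&
      !inherits(strategies[[1]], c("discrete_strategy", "continuous_strategy"))) {
    strategies <- strategies[[1]]
  }
  if (length(strategies) == 0) {
    rlang::abort("a community needs at least one species",
      class = "heterogame_error_validation")
  }
  ok <- vapply(
    strategies,
    function(s) inherits(s, c("discrete_strategy", "continuous_strategy")),
    logical(1)
  )
  if (!all(ok)) {
    rlang::abort("all community members must be strategy objects",
      class = "heterogame_error_validation")
  }
  labels <- vapply(strategies, function(s) s$label, character(1))
  dup <- duplicated(labels)
  if (any(dup)) {
    labels[dup] <- paste0(labels[dup], "_", cumsum(dup)[dup] + 1)
    strategies <- purrr::map2(strategies, labels, function(s, l) {
      s$label <- l
      s
    })
  }
  names(strategies) <- labels
  structure(strategies, class = "community")
}

#' @export
print.community <- function(x, ...) {
  cat(sprintf("<community> %d species\n", length(x)))
  for (s in x) print(s)
  invisible(x)
}

is_discrete_community <- function(comm) {
  all(vapply(comm, inherits, logical(1), "discrete_strategy"))
}

# Re-express finite-support strategies on the union of their supports
# (zero-padding absent atoms). Returns list(support, W) where W is a
# species-by-atom weight matrix.
merge_supports <- function(comm) {
  support <- sort(unique(unlist(lapply(comm, function(s) s$support))))
  W <- matrix(0, nrow = length(comm), ncol = length(support),
    dimnames = list(names(comm), NULL))
  for (k in seq_along(comm)) {
    idx <- match(comm[[k]]$support, support)
    W[k, idx] <- comm[[k]]$weights
  }
  list(support = support, W = W)
}
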