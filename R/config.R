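#' Build strategies and communities from config specifications
#'
#' A strategy specification is a named list (typically one block of a
#' YAML or JSON run config):
#' `{label, kind, abundance, <shape parameters>}` with `kind` one of
#' `uniform` (`M`), `invariant` (`value`), `lake_wobegon`
#' (`n`, `target_mca`), `bimodal` (`M`, `low_frac`, `high_frac`),
#' `gaussian` (`M`, `mean`, `sd`), or `custom` (explicit `support` and
#' `weights` lists).
#'
#' @param spec A named list as above.
#' @return A [discrete_strategy()].
#' @examples
#' strategy_from_spec(list(kind = "uniform", M = 10, abundance = 100, label = "u"))
#' @export
strategy_from_spec <- function(spec) {
  if (is.null(spec$kind)) {
    rlang::abort("strategy spec needs a `kind` field",
      class = "heterogame_error_config")
  }
  label <- spec$label %||% spec$kind
  abundance <- spec$abundance %||% 1
  need <- function(spec, fields, kind) {
    missing <- setdiff(fields, names(spec))
    if (length(missing)) {
      rlang::abort(
        sprintf("strategy kind '%s' requires field(s): %s",
          kind, paste(missing, collapse = ", ")),
        class = "heterogame_error_config"
      )
    }
  }
  switch(spec$kind,
    uniform = {
      need(spec, "M", "uniform")
      make_uniform(spec$M, abundance, label)
    },
    invariant = {
      need(spec, "value", "invariant")
      make_invariant(spec$value, abundance, label)
    },
    lake_wobegon = {
      need(spec, "n", "lake_wobegon")
      make_lake_wobegon(spec$n, spec$target_mca %||% 0.5, abundance, label)
    },
    bimodal = {
      need(spec, "M", "bimodal")
      make_bimodal(spec$M, spec$low_frac %||% 0.5, spec$high_frac %||% 0.5,
        abundance, label)
    },
    gaussian = {
      need(spec, c("M", "mean", "sd"), "gaussian")
      make_truncated_gaussian(spec$M, spec$mean, spec$sd, abundance, label)
    },
    custom = {
      need(spec, c("support", "weights"), "custom")
      w <- unlist(spec$weights)
      if (!is.null(spec$abundance)) w <- w / sum(w) * abundance
      discrete_strategy(unlist(spec$support), w, label)
    },
    rlang::abort(
      sprintf("unknown strategy kind '%s'", spec$kind),
      class = "heterogame_error_config"
    )
  )
}

#' @rdname strategy_from_spec
#' @param path Path to a YAML (`.yaml`/`.yml`) or JSON (`.json`) file
#'   holding either a list of strategy blocks or a mapping with a
#'   `species` list.
#' @export
read_community_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("config file not found: %s", path),
      class = "heterogame_error_config")
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  blocks <- if (!is.null(cfg$species)) cfg$species else cfg
  if (!length(blocks)) {
    rlang::abort("config defines no species", class = "heterogame_error_config")
  }
  community(lapply(blocks, strategy_from_spec))
}

#' @rdname strategy_from_spec
#' @param strategy A [discrete_strategy()] to serialize as a `custom`
#'   spec block (round-trips through [strategy_from_spec()]).
#' @export
strategy_to_spec <- function(strategy) {
  stopifnot(inherits(strategy, "discrete_strategy"))
  list(
    label = strategy$label,
    kind = "custom",
    support = strategy$support,
    weights = strategy$weights,
    abundance = total_abundance(strategy)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
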