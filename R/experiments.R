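#' Registered figure-level competition scenarios
#'
#' Each scenario is a named, fully seeded experiment: a community
#' builder, round count, replicate count, and a success criterion
#' computable from trajectories alone. The registry covers the canonical
#' qualitative results of the model:
#'
#' * `fig4` — the invariant strategy is eliminated by Lake Wobegon.
#' * `fig5` — Lake Wobegon coexists with an equilibrium (uniform)
#'   strategy.
#' * `fig6` — the uniform strategy coexists with the invariant strategy.
#' * `fig7` — the uniform strategy coexists with several equal-MCA
#'   competitors simultaneously.
#' * `fig8` — a rare uniform population (1% of each competitor's
#'   abundance) persists while the abundant invariant strategy is
#'   replaced by Lake Wobegon.
#' * `fig9` — many equilibrium-strategy species coexist with few
#'   extinctions (scaled to 25 species x 200 individuals x 50 rounds).
#' * `s1` — competitive exclusion: a competitor with strictly lower MCA
#'   is eliminated.
#' * `s2` — very small populations cannot reproduce the uniform
#'   distribution faithfully: its extinction frequency falls as the
#'   population grows (n = 10, 100, 1000).
#'
#' @return `scenario_registry()` returns the named list of scenario
#'   definitions; `list_scenarios()` a tibble summary.
#' @export
scenario_registry <- function() {
  M <- 10L  # grid resolution used by the experiment suite
  reg <- list(
    fig4 = list(
      description = "invariant eliminated by Lake Wobegon",
      build = function() community(
        make_invariant(0.5, 1000, label = "invariant"),
        make_lake_wobegon(1000, 0.5, 1000, label = "lake_wobegon")
      ),
      rounds = 100, replicates = 100,
      criterion = list(
        statistic = "extinction frequency of 'invariant'",
        threshold = 0.90,
        fn = function(finals) mean(finals$final_count[finals$species == "invariant"] == 0),
        pass = function(value) value >= 0.90
      )
    ),
    fig5 = list(
      description = "Lake Wobegon coexists with the uniform equilibrium strategy",
      build = function() community(
        continuous_constant(1000, label = "uniform"),
        make_lake_wobegon(1000, 0.5, 1000, label = "lake_wobegon")
      ),
      rounds = 50, replicates = 100,
      criterion = list(
        statistic = "frequency of both species extant",
        threshold = 0.90,
        fn = function(finals) {
          both <- tapply(finals$final_count > 0, finals$replicate, all)
          mean(both)
        },
        pass = function(value) value >= 0.90
      )
    ),
    fig6 = list(
      description = "uniform coexists with the invariant strategy",
      build = function() community(
        continuous_constant(1000, label = "uniform"),
        make_invariant(0.5, 1000, label = "invariant")
      ),
      rounds = 50, replicates = 100,
      criterion = list(
        statistic = "frequency of both species extant",
        threshold = 0.90,
        fn = function(finals) {
          both <- tapply(finals$final_count > 0, finals$replicate, all)
          mean(both)
        },
        pass = function(value) value >= 0.90
      )
    ),
    fig7 = list(
      description = "uniform coexists with every equal-MCA competitor at once",
      build = function() community(
        continuous_constant(1000, label = "uniform"),
        make_invariant(0.5, 1000, label = "invariant"),
        make_lake_wobegon(1000, 0.5, 1000, label = "lake_wobegon"),
        make_bimodal(M, 0.5, 0.5, 1000, label = "bimodal"),
        make_truncated_gaussian(M, 0.5, 0.15, 1000, label = "gaussian")
      ),
      rounds = 50, replicates = 50,
      criterion = list(
        statistic = "frequency of 'uniform' extant",
        threshold = 0.90,
        fn = function(finals) mean(finals$final_count[finals$species == "uniform"] > 0),
        pass = function(value) value >= 0.90
      )
    ),
    fig8 = list(
      description = "rare uniform persists; abundant invariant is replaced",
      build = function() community(
        continuous_constant(200, label = "uniform"),
        make_invariant(0.5, 20000, label = "invariant"),
        make_lake_wobegon(20000, 0.5, 20000, label = "lake_wobegon")
      ),
      rounds = 30, replicates = 100,
      criterion = list(
        statistic = "frequency of rare 'uniform' extant",
        threshold = 0.90,
        fn = function(finals) mean(finals$final_count[finals$species == "uniform"] > 0),
        pass = function(value) value >= 0.90
      )
    ),
    fig9 = list(
      description = "many equilibrium species coexist with few extinctions",
      build = function() {
        community(lapply(1:25, function(i) {
          continuous_constant(200, label = sprintf("eq_%02d", i))
        }))
      },
      rounds = 50, replicates = 20,
      criterion = list(
        statistic = "mean fraction of species extant at the final round",
        threshold = 0.90,
        fn = function(finals) mean(finals$final_count > 0),
        pass = function(value) value >= 0.90
      )
    ),
    s1 = list(
      description = "competitive exclusion of a lower-MCA competitor",
      build = function() community(
        continuous_constant(1000, label = "uniform"),
        make_invariant(0.3, 1000, label = "invariant_low")
      ),
      rounds = 100, replicates = 100,
      criterion = list(
        statistic = "extinction frequency of the lower-MCA species",
        threshold = 0.95,
        fn = function(finals) mean(finals$final_count[finals$species == "invariant_low"] == 0),
        pass = function(value) value >= 0.95
      )
    ),
    s2 = list(
      description = "small populations poorly reproduce the uniform strategy",
      sweep = list(n = c(10L, 100L, 1000L)),
      build = function(n) community(
        continuous_constant(n, label = "uniform"),
        make_lake_wobegon(max(n, 2), 0.5, n, label = "lake_wobegon")
      ),
      rounds = 100, replicates = 100,
      criterion = list(
        statistic = "uniform extinction frequency by n (10, 100, 1000)",
        threshold = NA_real_,
        fn = function(finals) {
          freq <- tapply(
            finals$final_count[finals$species == "uniform"] == 0,
            finals$n[finals$species == "uniform"], mean
          )
          freq[order(as.numeric(names(freq)))]
        },
        pass = function(value) all(diff(value) < 0)
      )
    )
  )
  reg
}

#' @rdname scenario_registry
#' @export
list_scenarios <- function() {
  reg <- scenario_registry()
  tibble::tibble(
    name = names(reg),
    description = vapply(reg, `[[`, character(1), "description"),
    rounds = vapply(reg, `[[`, numeric(1), "rounds"),
    replicates = vapply(reg, `[[`, numeric(1), "replicates"),
    criterion = vapply(reg, function(s) s$criterion$statistic, character(1))
  )
}

# seeds for replicate streams, derived reproducibly from the batch seed
derive_seeds <- function(seed, n) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run a registered scenario
#'
#' Executes the replicate batch for one scenario, evaluates its success
#' criterion, and optionally writes per-replicate trajectories and a
#' JSON summary. Replicate seeds are derived from `seed`, so a batch is
#' reproducible bit-exactly from `(name, seed)`.
#'
#' @param name Scenario name (see [list_scenarios()]).
#' @param seed Integer batch seed.
#' @param replicates,rounds Optional overrides of the registered
#'   defaults.
#' @param out_dir Optional directory for `traj_<replicate>.csv` files
#'   and `summary.json`.
#' @return A list of class `scenario_batch`: `name`, `seed`, `finals`
#'   (tibble of final counts per replicate and species, plus sweep
#'   variables if any), `summary` (per-species extinction frequency and
#'   final-abundance quartiles), and `criterion` (statistic, value(s),
#'   pass flag).
#' @examples
#' \donttest{
#' batch <- run_scenario("s1", seed = 1, replicates = 10)
#' batch$criterion$pass
#' }
#' @export
run_scenario <- function(name, seed = 1L, replicates = NULL, rounds = NULL,
                         out_dir = NULL) {
  reg <- scenario_registry()
  if (!name %in% names(reg)) {
    rlang::abort(
      sprintf("unknown scenario '%s'; see list_scenarios()", name),
      class = "heterogame_error_scenario"
    )
  }
  sc <- reg[[name]]
  if (is.null(replicates)) replicates <- sc$replicates
  if (is.null(rounds)) rounds <- sc$rounds
  cells <- if (is.null(sc$sweep)) {
    list(list())
  } else {
    purrr::transpose(as.list(expand.grid(sc$sweep)))
  }
  seeds <- derive_seeds(seed, replicates * length(cells))
  finals <- list()
  idx <- 0L
  for (ci in seq_along(cells)) {
    cell <- cells[[ci]]
    comm <- do.call(sc$build, cell)
    for (r in seq_len(replicates)) {
      idx <- idx + 1L
      sim <- run_simulation(comm, rounds = rounds, seed = seeds[idx])
      row <- tibble::tibble(
        replicate = idx,
        species = names(sim$final_counts),
        final_count = as.integer(sim$final_counts),
        extinct = as.integer(sim$final_counts) == 0L
      )
      for (nm in names(cell)) row[[nm]] <- cell[[nm]]
      finals[[idx]] <- row
      if (!is.null(out_dir)) {
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(sim$trajectory,
          file.path(out_dir, sprintf("traj_%04d.csv", idx)),
          row.names = FALSE
        )
      }
    }
  }
  finals <- dplyr::bind_rows(finals)
  summary_tbl <- finals |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("species", names(sc$sweep))))) |>
    dplyr::summarise(
      extinction_freq = mean(.data$extinct),
      q25 = stats::quantile(.data$final_count, 0.25),
      median = stats::median(.data$final_count),
      q75 = stats::quantile(.data$final_count, 0.75),
      .groups = "drop"
    )
  value <- sc$criterion$fn(finals)
  criterion <- list(
    statistic = sc$criterion$statistic,
    threshold = sc$criterion$threshold,
    value = value,
    pass = isTRUE(sc$criterion$pass(value))
  )
  batch <- structure(
    list(
      name = name, seed = seed, rounds = rounds, replicates = replicates,
      finals = finals, summary = summary_tbl, criterion = criterion
    ),
    class = "scenario_batch"
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(
        name = name, seed = seed, rounds = rounds, replicates = replicates,
        criterion = criterion, summary = summary_tbl
      ),
      file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  batch
}

#' @export
print.scenario_batch <- function(x, ...) {
  cat(sprintf("<scenario_batch> %s (seed %d, %d replicates x %d rounds)\n",
    x$name, x$seed, x$replicates, x$rounds))
  cat(sprintf("criterion: %s\n", x$criterion$statistic))
  cat("value:", format(x$criterion$value, digits = 4),
    "| pass:", x$criterion$pass, "\n")
  invisible(x)
}

#' Sweep a parameter grid of pairwise competitions
#'
#' Runs a full factorial grid of two-species tournaments and returns a
#' long results table, one row per grid cell, replicate and species.
#' Used for population-size and duration robustness checks.
#'
#' @param grid A data frame whose rows are grid cells; recognized
#'   columns: `n` (per-species head-count), `rounds`. Extra columns are
#'   carried through. An empty grid yields an empty table.
#' @param build Function called with one grid row (as a list) returning
#'   the [community()] for that cell; the default pits a uniform
#'   strategy against Lake Wobegon at matched abundance `n`.
#' @param replicates Replicates per cell.
#' @param seed Batch seed; per-run seeds are derived from it.
#' @return A tibble: grid columns + `replicate`, `species`,
#'   `final_count`, `extinct`.
#' @examples
#' \donttest{
#' run_sweep(data.frame(n = c(10, 100)), replicates = 5, seed = 1)
#' }
#' @export
run_sweep <- function(grid, build = NULL, replicates = 20, seed = 1L) {
  grid <- tibble::as_tibble(grid)
  if (nrow(grid) == 0) {
    return(tibble::tibble(
      replicate = integer(), species = character(),
      final_count = integer(), extinct = logical()
    ))
  }
  if (is.null(build)) {
    build <- function(cell) community(
      continuous_constant(cell$n, label = "uniform"),
      make_lake_wobegon(max(cell$n, 2), 0.5, cell$n, label = "lake_wobegon")
    )
  }
  seeds <- derive_seeds(seed, nrow(grid) * replicates)
  out <- list()
  idx <- 0L
  for (ci in seq_len(nrow(grid))) {
    cell <- as.list(grid[ci, ])
    comm <- build(cell)
    rounds <- if (!is.null(cell$rounds)) cell$rounds else 100
    for (r in seq_len(replicates)) {
      idx <- idx + 1L
      sim <- run_simulation(comm, rounds = rounds, seed = seeds[idx])
      row <- tibble::tibble(
        replicate = r,
        species = names(sim$final_counts),
        final_count = as.integer(sim$final_counts),
        extinct = as.integer(sim$final_counts) == 0L
      )
      for (nm in names(cell)) row[[nm]] <- cell[[nm]]
      out[[idx]] <- row
    }
  }
  dplyr::bind_rows(out) |>
    dplyr::relocate(dplyr::any_of(names(grid)))
}
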