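#' Load and validate a run configuration
#'
#' Reads a scenario configuration from a YAML file (JSON is accepted
#' interchangeably: `.json` files are parsed with jsonlite). The
#' configuration names the archetypes (each with a prior and, for fixed
#' streams, its per-trial likelihood ratio), the evidence-stream
#' specification, the bias policy, an optional output directory and a seed.
#' Unknown keys and out-of-range values are rejected with errors naming the
#' offending field.
#'
#' Recognised top-level keys: `name`, `seed`, `out_dir`, `archetypes`,
#' `stream`, `policy`. Stream modes: `fixed` (`n_trials`, `lr` at stream or
#' archetype level), `mixed` (`n_favoring_a`, `n_favoring_b`,
#' `lr_magnitude`), `binomial` (`n_trials`, `true_hypothesis`, `design` with
#' `n_per_arm`, `rates_ha`, `rates_hb`).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A validated `run_config` object.
#' @seealso [run_scenario()], [write_outputs()]. The canonical archetype
#'   comparison ships as
#'   `system.file("extdata", "archetype-comparison.yaml", package = "beliefsim")`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  validate_config(raw, source = path)
}

#' @rdname load_config
#' @param config A named list with the same structure as the file contents.
#' @param source Label used in error messages.
#' @export
validate_config <- function(config, source = "config") {
  if (!is.list(config)) abort(sprintf("%s: configuration must be a mapping.", source))
  allowed <- c("name", "seed", "out_dir", "archetypes", "stream", "policy")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0) {
    abort(sprintf("%s: unknown key(s): %s.", source, paste(unknown, collapse = ", ")))
  }

  name <- config$name %||% "scenario"
  seed <- config$seed %||% 1L
  if (!is.numeric(seed) || length(seed) != 1 || seed != as.integer(seed)) {
    abort(sprintf("%s: `seed` must be a single integer.", source))
  }

  arch_raw <- config$archetypes
  if (is.null(arch_raw)) {
    arch <- dplyr::mutate(archetypes(), lr = unname(default_archetype_lr()[.data$name]))
  } else {
    if (!is.list(arch_raw) || length(arch_raw) == 0) {
      abort(sprintf("%s: `archetypes` must be a non-empty list.", source))
    }
    arch <- purrr::map_dfr(arch_raw, function(a) {
      unknown <- setdiff(names(a), c("name", "prior", "lr"))
      if (length(unknown) > 0) {
        abort(sprintf("%s: unknown archetype key(s): %s.", source,
                      paste(unknown, collapse = ", ")))
      }
      if (is.null(a$name) || is.null(a$prior)) {
        abort(sprintf("%s: each archetype needs `name` and `prior`.", source))
      }
      check_probability(a$prior, sprintf("prior (archetype %s)", a$name), open = TRUE)
      tibble::tibble(name = as.character(a$name), prior = as.numeric(a$prior),
                     lr = as.numeric(a$lr %||% NA_real_))
    })
  }

  stream <- validate_stream_spec(config$stream, arch, source)

  pol_raw <- config$policy %||% list()
  unknown <- setdiff(names(pol_raw), c("w_confirming", "w_disconfirming", "threshold"))
  if (length(unknown) > 0) {
    abort(sprintf("%s: unknown policy key(s): %s.", source, paste(unknown, collapse = ", ")))
  }
  policy <- bias_policy(
    w_confirming = pol_raw$w_confirming %||% 1,
    w_disconfirming = pol_raw$w_disconfirming %||% 0.5,
    threshold = pol_raw$threshold %||% 0.5
  )

  structure(
    list(
      name = as.character(name),
      seed = as.integer(seed),
      out_dir = config$out_dir %||% ".",
      archetypes = arch,
      stream = stream,
      policy = policy
    ),
    class = "run_config"
  )
}

validate_stream_spec <- function(spec, arch, source) {
  spec <- spec %||% list(mode = "fixed", n_trials = 10)
  allowed <- c("mode", "n_trials", "lr", "n_favoring_a", "n_favoring_b",
               "lr_magnitude", "true_hypothesis", "design")
  unknown <- setdiff(names(spec), allowed)
  if (length(unknown) > 0) {
    abort(sprintf("%s: unknown stream key(s): %s.", source, paste(unknown, collapse = ", ")))
  }
  mode <- spec$mode %||% "fixed"
  if (!mode %in% c("fixed", "mixed", "binomial")) {
    abort(sprintf("%s: stream `mode` must be fixed, mixed or binomial.", source))
  }
  if (mode == "fixed") {
    n_trials <- spec$n_trials %||% 10
    check_count(n_trials, "stream.n_trials")
    has_archetype_lr <- all(!is.na(arch$lr))
    if (!has_archetype_lr && is.null(spec$lr)) {
      abort(sprintf(
        "%s: fixed mode needs `lr` at stream level or on every archetype.", source))
    }
    if (!is.null(spec$lr)) check_lr(spec$lr, "stream.lr")
    list(mode = "fixed", n_trials = as.integer(n_trials), lr = spec$lr)
  } else if (mode == "mixed") {
    if (is.null(spec$n_favoring_a) || is.null(spec$n_favoring_b) ||
        is.null(spec$lr_magnitude)) {
      abort(sprintf(
        "%s: mixed mode needs `n_favoring_a`, `n_favoring_b`, `lr_magnitude`.", source))
    }
    check_count(spec$n_favoring_a, "stream.n_favoring_a", min = 0)
    check_count(spec$n_favoring_b, "stream.n_favoring_b", min = 0)
    check_lr(spec$lr_magnitude, "stream.lr_magnitude")
    list(mode = "mixed",
         n_favoring_a = as.integer(spec$n_favoring_a),
         n_favoring_b = as.integer(spec$n_favoring_b),
         lr_magnitude = as.numeric(spec$lr_magnitude))
  } else {
    d <- spec$design
    if (is.null(d)) abort(sprintf("%s: binomial mode needs a `design` mapping.", source))
    n_trials <- spec$n_trials %||% 10
    check_count(n_trials, "stream.n_trials")
    design <- trial_design(d$n_per_arm, unlist(d$rates_ha), unlist(d$rates_hb))
    hyp <- spec$true_hypothesis %||% "HB"
    if (!hyp %in% c("HA", "HB")) {
      abort(sprintf("%s: `true_hypothesis` must be HA or HB.", source))
    }
    list(mode = "binomial", n_trials = as.integer(n_trials),
         design = design, true_hypothesis = hyp)
  }
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config: %s> seed %d, stream mode %s, policy %s\n",
              x$name, x$seed, x$stream$mode, format(x$policy)))
  print(x$archetypes)
  invisible(x)
}

#' Build the evidence stream a configuration describes
#'
#' @param config A `run_config`.
#' @param archetype_lr Likelihood ratio to use for a fixed-mode stream when
#'   the archetype carries its own (fixed streams may differ per archetype;
#'   mixed and binomial streams are shared).
#' @return An evidence-stream tibble.
#' @export
build_stream <- function(config, archetype_lr = NULL) {
  s <- config$stream
  switch(s$mode,
    fixed = fixed_stream(s$n_trials, archetype_lr %||% s$lr),
    mixed = mixed_stream(s$n_favoring_a, s$n_favoring_b, s$lr_magnitude,
                         seed = config$seed),
    binomial = binomial_stream(s$design, s$n_trials, s$true_hypothesis,
                               seed = config$seed)
  )
}

#' Run the scenario a configuration describes
#'
#' Every archetype reviews its evidence stream under two conditions — the
#' configured (typically biased) policy and the unbiased reference — and the
#' per-trial records and endpoints are collected into tables ready for
#' [write_outputs()].
#'
#' @param config A `run_config` from [load_config()] or [validate_config()].
#' @return A `scenario_run` object with `trajectories` (one row per
#'   archetype x condition x trial), `endpoints` (one row per archetype x
#'   condition, with reported percentages), and the config.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "run_config"))
  arch <- config$archetypes

  rows <- purrr::pmap(
    list(arch$name, arch$prior, arch$lr),
    function(nm, prior, alr) {
      stream <- build_stream(config, if (!is.na(alr)) alr else NULL)
      purrr::map(
        c(unbiased = "unbiased", biased = "biased"),
        function(cond) {
          pol <- if (cond == "unbiased") {
            unbiased_policy(config$policy$threshold)
          } else {
            config$policy
          }
          run_sequence(prior, stream, pol)
        }
      )
    }
  )
  names(rows) <- arch$name

  trajectories <- purrr::imap_dfr(rows, function(conds, nm) {
    purrr::imap_dfr(conds, function(tr, cond) {
      dplyr::bind_cols(
        tibble::tibble(scenario = nm, condition = cond),
        tidy(tr)
      )
    })
  })
  endpoints <- purrr::imap_dfr(rows, function(conds, nm) {
    purrr::imap_dfr(conds, function(tr, cond) {
      dplyr::bind_cols(
        tibble::tibble(scenario = nm, condition = cond),
        glance(tr)
      )
    })
  })

  structure(
    list(trajectories = trajectories, endpoints = endpoints, config = config,
         runs = rows),
    class = "scenario_run"
  )
}

#' @export
print.scenario_run <- function(x, ...) {
  cat(sprintf("<scenario_run: %s> %d archetype(s), %d trajectory rows\n",
              x$config$name, nrow(x$config$archetypes), nrow(x$trajectories)))
  print(x$endpoints[, c("scenario", "condition", "initial_belief",
                        "final_belief", "final_percent")])
  invisible(x)
}

#' @export
tidy.scenario_run <- function(x, ...) x$trajectories

#' @export
glance.scenario_run <- function(x, ...) x$endpoints
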